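# Shared small synthetic cohort: 3+3 subjects, 32 channels, 30 s, snr 4.
fix_cfg <- simulation_config(n_per_group = 3, n_channels = 32, duration = 30,
                             seed = 101)
fix_cohort <- simulate_cohort(fix_cfg)
fix_prepped <- lapply(fix_cohort$recordings, bandpass_and_reref)

# Group model built directly from the planted templates (bypasses
# clustering so back-fitting tests have an exact reference).
truth_model <- function(cohort) {
  structure(list(k_star = nrow(cohort$templates),
                 templates = cohort$templates,
                 labels = rownames(cohort$templates),
                 montage = cohort$montage),
            class = "ms_group_model")
}
fix_model <- truth_model(fix_cohort)

# Random average-referenced unit-GFP maps.
rand_maps <- function(n, p, seed = 1) {
  set.seed(seed)
  normalize_map(matrix(rnorm(n * p), n, p))
}

# Feature table simulated directly at the feature level (no EEG): Gaussian
# subject random intercepts plus class-specific group effects on mean
# duration; occurrence derived proportionally.
simulate_feature_table <- function(n_per_group, effects = rep(0, 5),
                                   sd_between = 6, sd_within = 8, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  subj <- sprintf("S%02d", seq_len(n))
  group <- rep(c("control", "patient"), each = n_per_group)
  age <- round(runif(n, 25, 70))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  u <- rnorm(n, 0, sd_between)
  rows <- expand.grid(subject = subj, label = LETTERS[1:5],
                      stringsAsFactors = FALSE)
  i <- match(rows$subject, subj)
  base <- 55 + 3 * match(rows$label, LETTERS)
  rows$group <- group[i]; rows$age <- age[i]; rows$sex <- sex[i]
  rows$mean_duration_ms <- base + u[i] +
    ifelse(rows$group == "patient", effects[match(rows$label, LETTERS)], 0) +
    rnorm(nrow(rows), 0, sd_within)
  rows$occurrence_per_s <- rows$mean_duration_ms / 15
  rows
}

# Brute-force feature arithmetic on a segment table, independent of
# microstate_features() internals.
brute_features <- function(segments, classes) {
  segs <- segments[segments$valid, ]
  dur <- segs$end_s - segs$start_s
  tot <- sum(dur)
  do.call(rbind, lapply(seq_along(classes), function(cl) {
    sel <- segs$class == cl
    data.frame(class = cl,
               mean_duration_ms = if (any(sel)) mean(dur[sel]) * 1000 else NA_real_,
               occurrence_per_s = sum(sel) / tot,
               coverage_pct = 100 * sum(dur[sel]) / tot)
  }))
}
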