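#' Per-subject class mean topographies
#'
#' For every subject, the mean of its (unit-GFP) GFP-peak maps assigned to
#' each class, with every map sign-aligned to the class template before
#' averaging (maps carry arbitrary polarity, so unaligned averaging would
#' cancel).
#'
#' @param recordings list of average-referenced `ms_recording`s.
#' @param group_model an `ms_group_model`.
#' @return list with one element per class: matrix `n_subjects x
#'   n_channels` (rownames = subject ids; subjects with no peak of that
#'   class are omitted).
#' @export
class_mean_maps <- function(recordings, group_model) {
  tpl <- normalize_map(group_model$templates)
  k <- nrow(tpl)
  per_class <- lapply(seq_len(k), function(j) NULL)
  for (rec in recordings) {
    g <- compute_gfp(rec)
    peaks <- find_gfp_peaks(g)
    maps <- gfp_peak_maps(rec, peaks)
    C <- corr_cross(maps, tpl)
    lab <- max.col(abs(C), ties.method = "first")
    for (j in seq_len(k)) {
      sel <- lab == j
      if (!any(sel)) next
      aligned <- maps[sel, , drop = FALSE] * sign(C[sel, j])
      mm <- colMeans(aligned)
      per_class[[j]] <- rbind(per_class[[j]],
                              stats::setNames(matrix(mm, 1), NULL))
      rownames(per_class[[j]])[nrow(per_class[[j]])] <- rec$subject
    }
  }
  names(per_class) <- if (!is.null(group_model$labels)) group_model$labels else
    as.character(seq_len(k))
  per_class
}

stage_log <- function(verbose, stage, t0) {
  if (verbose) {
    message(sprintf("[%s] done in %.1f s", stage,
                    as.numeric(Sys.time()) - t0))
  }
}

#' Run the full microstate analysis pipeline
#'
#' Executes, in order: band-pass filtering and common-average referencing;
#' subject-level clustering with Krzanowski-Lai selection; constrained
#' group-level clustering and canonical labeling; per-subject global
#' explained variance; competitive back-fitting, segmentation, and feature
#' extraction; and two-group statistics (Cohen's d, TANOVA per class with
#' electrode-wise follow-up t-tests for flagged classes, linear
#' mixed-effects contrasts for duration and occurrence, Dirichlet
#' regression for coverage, FWER threshold).
#'
#' @param input a cohort directory path (see [read_cohort_dir()]) or a list
#'   with `recordings`, `sample_sheet`, `montage`.
#' @param out_dir optional results directory; when given, the feature
#'   table, model, topographies, statistics, and a run manifest are
#'   written there.
#' @param band band-pass edges in Hz (default `c(1, 40)`).
#' @param candidate_range candidate class counts (default `3:11`).
#' @param n_restarts k-means restarts (default 20).
#' @param n_perm TANOVA permutations (default 4999).
#' @param seed master seed.
#' @param at_peaks_only back-fitting mode (default peaks).
#' @param denominator feature denominator, `"valid"` or `"usable"`.
#' @param verbose log one line per stage.
#' @return list of class `ms_results`: `group_model`, `subject_models`,
#'   `features`, `stats`, `gev`, `sample_sheet`, `params`.
#' @export
run_pipeline <- function(input, out_dir = NULL, band = c(1, 40),
                         candidate_range = 3:11, n_restarts = 20L,
                         n_perm = 4999L, seed = 1L, at_peaks_only = TRUE,
                         denominator = c("valid", "usable"),
                         verbose = FALSE) {
  denominator <- match.arg(denominator)
  cohort <- if (is.character(input)) read_cohort_dir(input) else input
  sheet <- cohort$sample_sheet
  if (length(unique(sheet$group)) < 2 || any(table(sheet$group) < 2)) {
    stop("statistics require at least 2 subjects in each of two groups")
  }
  t0 <- as.numeric(Sys.time())
  prepped <- lapply(cohort$recordings, function(rec) {
    tryCatch(bandpass_and_reref(rec, band[1], band[2]),
             error = function(e) stop("signal preparation failed for subject ",
                                      rec$subject, ": ", conditionMessage(e)))
  })
  stage_log(verbose, "signal_prep", t0)

  t0 <- as.numeric(Sys.time())
  subject_models <- lapply(prepped, function(rec) {
    tryCatch(cluster_subject(rec, candidate_range, n_restarts,
                             seed = restart_seed(seed, match(rec$subject, sheet$subject))),
             error = function(e) stop("subject clustering failed for ",
                                      rec$subject, ": ", conditionMessage(e)))
  })
  stage_log(verbose, "subject_clustering", t0)

  t0 <- as.numeric(Sys.time())
  group_model <- cluster_group(subject_models, candidate_range, n_restarts,
                               seed = seed)
  group_model <- canonical_labeling(group_model)
  group_model$gev_per_subject <- vapply(prepped, global_explained_variance,
                                        numeric(1), group_model = group_model)
  stage_log(verbose, "group_clustering", t0)

  t0 <- as.numeric(Sys.time())
  features <- feature_table(prepped, group_model, sheet,
                            at_peaks_only = at_peaks_only,
                            denominator = denominator)
  stage_log(verbose, "features", t0)

  t0 <- as.numeric(Sys.time())
  stats_out <- group_statistics(prepped, group_model, features, sheet,
                                n_perm = n_perm, seed = seed)
  stage_log(verbose, "stats", t0)

  results <- structure(list(
    group_model = group_model, subject_models = subject_models,
    features = features, stats = stats_out,
    gev = group_model$gev_per_subject, sample_sheet = sheet,
    params = list(band = band, candidate_range = candidate_range,
                  n_restarts = n_restarts, n_perm = n_perm, seed = seed,
                  at_peaks_only = at_peaks_only, denominator = denominator)
  ), class = "ms_results")
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

# Two-group statistics stage on fitted features and topographies.
group_statistics <- function(prepped, group_model, features, sheet,
                             n_perm = 4999L, seed = 1L) {
  labels <- group_model$labels
  ctrl_ids <- sheet$subject[sheet$group == "control"]
  pat_ids <- sheet$subject[sheet$group == "patient"]

  # per class x feature summary and Cohen's d
  feats <- c("mean_duration_ms", "occurrence_per_s", "coverage_pct")
  summary_rows <- list()
  for (lb in labels) {
    for (fe in feats) {
      x1 <- features[features$label == lb & features$subject %in% ctrl_ids, fe]
      x2 <- features[features$label == lb & features$subject %in% pat_ids, fe]
      x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
      d <- if (length(x1) >= 2 && length(x2) >= 2) {
        cohens_d(mean(x1), stats::sd(x1), length(x1),
                 mean(x2), stats::sd(x2), length(x2))
      } else NA_real_
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        label = lb, feature = fe,
        mean_control = mean(x1), sd_control = stats::sd(x1),
        mean_patient = mean(x2), sd_patient = stats::sd(x2),
        cohens_d = d)
    }
  }
  summary_tab <- do.call(rbind, summary_rows)

  # TANOVA per class on subject mean maps, electrode-wise follow-up
  mean_maps <- class_mean_maps(prepped, group_model)
  tanova_tab <- data.frame(label = labels, p = NA_real_, statistic = NA_real_)
  t_maps <- list()
  for (i in seq_along(labels)) {
    mm <- mean_maps[[labels[i]]]
    if (is.null(mm)) next
    g1 <- mm[rownames(mm) %in% ctrl_ids, , drop = FALSE]
    g2 <- mm[rownames(mm) %in% pat_ids, , drop = FALSE]
    if (nrow(g1) < 2 || nrow(g2) < 2) next
    tv <- tanova(g1, g2, n_perm = n_perm, seed = restart_seed(seed, 3000L + i))
    tanova_tab$p[i] <- tv$p
    tanova_tab$statistic[i] <- tv$statistic
    if (tv$p < 0.05) t_maps[[labels[i]]] <- electrodewise_t(g1, g2)
  }

  lmm_dur <- lmm_contrasts(features, "mean_duration")
  lmm_occ <- lmm_contrasts(features, "occurrence")

  # Dirichlet regression of coverage on group + age + sex
  cov_wide <- stats::reshape(
    features[, c("subject", "label", "coverage_pct")],
    idvar = "subject", timevar = "label", direction = "wide")
  y <- as.matrix(cov_wide[, -1, drop = FALSE]) / 100
  colnames(y) <- sub("^coverage_pct\\.", "", colnames(y))
  meta <- sheet[match(cov_wide$subject, sheet$subject), ]
  x <- cbind(`(Intercept)` = 1,
             grouppatient = as.numeric(meta$group == "patient"),
             age = as.numeric(scale(meta$age)),
             sexM = as.numeric(meta$sex == "M"))
  diri <- dirichlet_regression(y, x)
  diri_tab <- data.frame(label = colnames(y),
                         estimate = diri$coefficients["grouppatient", ],
                         se = diri$se["grouppatient", ],
                         z = diri$z["grouppatient", ],
                         p = diri$p["grouppatient", ])

  list(summary = summary_tab, tanova = tanova_tab,
       electrodewise_t = t_maps,
       lmm_mean_duration = lmm_dur, lmm_occurrence = lmm_occ,
       dirichlet_coverage = diri_tab, dirichlet_fit = diri,
       fwer = fwer_threshold(group_model$k_star))
}

#' Write pipeline results to a directory
#'
#' Delimited tables (`features.tsv`, `summary.tsv`, `effects.tsv`,
#' `tanova.tsv`, `topographies.tsv`), the group model as JSON, and a run
#' manifest.
#'
#' @param results an `ms_results`.
#' @param out_dir destination directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(results$features[, c("subject", "group", "age", "sex", "label",
                          "mean_duration_ms", "occurrence_per_s",
                          "coverage_pct")], "features.tsv")
  wt(results$stats$summary, "summary.tsv")
  effects <- rbind(
    cbind(feature = "mean_duration_ms", results$stats$lmm_mean_duration),
    cbind(feature = "occurrence_per_s", results$stats$lmm_occurrence),
    cbind(feature = "coverage_pct", results$stats$dirichlet_coverage))
  wt(effects, "effects.tsv")
  wt(results$stats$tanova, "tanova.tsv")
  topo <- t(results$group_model$templates)
  topo <- data.frame(channel = results$group_model$montage$channel[
    results$group_model$montage$scalp], topo)
  wt(topo, "topographies.tsv")
  write_group_model(results$group_model, file.path(out_dir, "model.json"))
  manifest <- list(stage = "run", params = results$params,
                   gev_per_subject = as.list(results$gev),
                   fwer = results$stats$fwer,
                   package_version = as.character(utils::packageVersion("microstatr")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Summarize a results directory as a two-group feature table
#'
#' Reads the serialized intermediates and recomputes, per class and
#' feature, the group mean +/- SD columns, Cohen's d, and the regression
#' p-value — the layout of a standard microstate dynamics table.
#'
#' @param results_dir directory written by [run_pipeline()] /
#'   [write_results()].
#' @return data.frame with one row per class x feature.
#' @export
report_results <- function(results_dir) {
  features <- utils::read.table(file.path(results_dir, "features.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  effects_path <- file.path(results_dir, "effects.tsv")
  effects <- if (file.exists(effects_path)) {
    utils::read.table(effects_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    warning("effects.tsv missing; reporting features without p-values")
    NULL
  }
  feats <- c("mean_duration_ms", "occurrence_per_s", "coverage_pct")
  rows <- list()
  for (fe in feats) {
    for (lb in sort(unique(features$label))) {
      x1 <- features[features$label == lb & features$group == "control", fe]
      x2 <- features[features$label == lb & features$group == "patient", fe]
      x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
      p <- if (!is.null(effects)) {
        effects$p[effects$feature == fe & effects$label == lb][1]
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        feature = fe, class = lb,
        control = sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1)),
        patient = sprintf("%.2f ± %.2f", mean(x2), stats::sd(x2)),
        cohens_d = round(cohens_d(mean(x1), stats::sd(x1), length(x1),
                                  mean(x2), stats::sd(x2), length(x2)), 2),
        p = p)
    }
  }
  do.call(rbind, rows)
}
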