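#' Configuration for the synthetic two-group EEG cohort generator
#'
#' Defines the study conditions emulated by the generator: eyes-closed
#' resting-state scalp EEG sampled at 250 Hz, band-limited 1-40 Hz, with
#' quasi-stable topographic states of 50-65 ms mean dwell time switching on
#' an ~10 Hz amplitude carrier, and two groups ("control", "patient") with
#' planted class-specific differences (shorter class-C dwell times and a
#' higher class-D switching propensity in patients).
#'
#' @param n_per_group subjects per group (default 32).
#' @param n_channels scalp electrodes (default 64; 204 supported).
#' @param sampling_rate Hz (default 250).
#' @param duration recording length in seconds (default 300).
#' @param n_classes number of planted microstate classes (default 5).
#' @param carrier_freq carrier frequency in Hz (default 10); GFP peaks occur
#'   at roughly twice this rate.
#' @param carrier_floor minimum of the rectified amplitude envelope as a
#'   fraction of its maximum (default 0.2). Real eyes-closed EEG keeps a
#'   substantial broadband topographic signal between alpha-band GFP
#'   maxima; a zero floor would make every inter-peak trough pure noise.
#' @param dwell_means named list (`control`, `patient`) of per-class mean
#'   dwell times in ms. Defaults plant a shorter class-C dwell in patients.
#' @param dwell_shape gamma shape of the dwell-time law (default 2).
#' @param occurrence_weights named list of per-class relative transition
#'   propensities. Defaults plant a higher class-D weight in patients.
#' @param subject_dwell_cv between-subject coefficient of variation of the
#'   per-class dwell-time means (default 0.2): each subject draws one
#'   mean-one lognormal factor per class, emulating the between-subject
#'   spread seen in group feature tables of real cohorts.
#' @param subject_weight_cv between-subject coefficient of variation of the
#'   per-class occurrence weights (default 0.3), lognormal as above;
#'   matches the spread of occurrence rates across subjects in real
#'   cohorts.
#' @param snr ratio of state-signal RMS GFP to noise RMS GFP (default 4).
#' @param template_jitter per-subject template perturbation magnitude in
#'   `[0, 1]` (default 0.05).
#' @param n_mask_segments number of artifact-mask gaps inserted per
#'   recording (default 2; set 0 to disable).
#' @param mask_segment_s length of each masked gap in seconds (default 2).
#' @param seed master integer seed for the cohort.
#' @return a validated list of class `ms_sim_config`.
#' @export
simulation_config <- function(n_per_group = 32L,
                              n_channels = 64L,
                              sampling_rate = 250,
                              duration = 300,
                              n_classes = 5L,
                              carrier_freq = 10,
                              carrier_floor = 0.2,
                              dwell_means = NULL,
                              dwell_shape = 2,
                              occurrence_weights = NULL,
                              subject_dwell_cv = 0.2,
                              subject_weight_cv = 0.3,
                              snr = 4,
                              template_jitter = 0.05,
                              n_mask_segments = 2L,
                              mask_segment_s = 2,
                              seed = 1L) {
  if (is.null(dwell_means)) dwell_means <- default_dwell_means(n_classes)
  if (is.null(occurrence_weights)) occurrence_weights <- default_occurrence_weights(n_classes)
  cfg <- list(
    n_per_group = as.integer(n_per_group), n_channels = as.integer(n_channels),
    sampling_rate = sampling_rate, duration = duration,
    n_classes = as.integer(n_classes), carrier_freq = carrier_freq,
    carrier_floor = carrier_floor,
    dwell_means = dwell_means, dwell_shape = dwell_shape,
    occurrence_weights = occurrence_weights,
    subject_dwell_cv = subject_dwell_cv,
    subject_weight_cv = subject_weight_cv, snr = snr,
    template_jitter = template_jitter,
    n_mask_segments = as.integer(n_mask_segments),
    mask_segment_s = mask_segment_s, seed = as.integer(seed)
  )
  class(cfg) <- "ms_sim_config"
  validate_sim_config(cfg)
  cfg
}

default_dwell_means <- function(n_classes) {
  if (n_classes == 5L) {
    list(control = c(54, 58, 61, 60, 50), patient = c(51, 54, 53, 63, 47))
  } else {
    m <- seq(50, 65, length.out = n_classes)
    list(control = m, patient = m)
  }
}

default_occurrence_weights <- function(n_classes) {
  if (n_classes == 5L) {
    list(control = c(1, 1, 1, 1, 0.9), patient = c(1, 1, 1, 1.25, 0.9))
  } else {
    w <- rep(1, n_classes)
    list(control = w, patient = w)
  }
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "ms_sim_config"))
  if (cfg$n_classes < 2L) stop("n_classes must be at least 2 (a single state cannot alternate)")
  if (cfg$n_per_group < 1L) stop("n_per_group must be positive")
  if (cfg$snr <= 0) stop("snr must be positive")
  if (cfg$subject_dwell_cv < 0) stop("subject_dwell_cv must be non-negative")
  if (cfg$subject_weight_cv < 0) stop("subject_weight_cv must be non-negative")
  if (cfg$carrier_floor < 0 || cfg$carrier_floor >= 1) {
    stop("carrier_floor must be in [0, 1)")
  }
  if (cfg$template_jitter < 0 || cfg$template_jitter > 1) stop("template_jitter must be in [0, 1]")
  for (g in c("control", "patient")) {
    dm <- cfg$dwell_means[[g]]; ow <- cfg$occurrence_weights[[g]]
    if (length(dm) != cfg$n_classes || any(dm <= 0)) stop("dwell means must be positive, one per class")
    if (length(ow) != cfg$n_classes || any(ow < 0) || sum(ow > 0) < 2) {
      stop("occurrence weights must be non-negative with at least two positive classes")
    }
  }
  n_samples <- cfg$duration * cfg$sampling_rate
  if (abs(n_samples - round(n_samples)) > 1e-9) stop("duration x sampling_rate must be an integer sample count")
  invisible(cfg)
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Draws alternating class labels with gamma-distributed dwell times
#' (mean per class and group from the config, common shape) and next-class
#' transitions proportional to the occurrence weights with self-transitions
#' excluded.
#'
#' @param config an `ms_sim_config`.
#' @param group `"control"` or `"patient"`.
#' @param subject_seed integer seed for this subject.
#' @return integer vector of length `duration * sampling_rate` with values
#'   in `1..n_classes`; every sample is labeled.
#' @export
simulate_state_sequence <- function(config, group = c("control", "patient"),
                                    subject_seed = 1L) {
  validate_sim_config(config)
  group <- match.arg(group)
  n_samples <- as.integer(round(config$duration * config$sampling_rate))
  means <- config$dwell_means[[group]]
  w <- config$occurrence_weights[[group]]
  shape <- config$dwell_shape
  fs <- config$sampling_rate
  k <- config$n_classes
  rng <- local_rng(subject_seed)
  rng$eval(function() {
    # per-subject heterogeneity: mean-one lognormal factors per class for
    # both the dwell means and the occurrence weights
    lnorm_factors <- function(cv) {
      if (cv <= 0) return(rep(1, k))
      sdl <- sqrt(log(1 + cv^2))
      exp(stats::rnorm(k, -sdl^2 / 2, sdl))
    }
    means <- means * lnorm_factors(config$subject_dwell_cv)
    w <- w * lnorm_factors(config$subject_weight_cv)
    labels <- integer(n_samples)
    pos <- 0L
    current <- sample.int(k, 1L, prob = w)
    while (pos < n_samples) {
      dwell_ms <- stats::rgamma(1L, shape = shape, scale = means[current] / shape)
      len <- max(1L, as.integer(round(dwell_ms * fs / 1000)))
      len <- min(len, n_samples - pos)
      labels[(pos + 1L):(pos + len)] <- current
      pos <- pos + len
      w_next <- w
      w_next[current] <- 0
      current <- sample.int(k, 1L, prob = w_next)
    }
    labels
  })
}

# Spatial smoothing operator over the electrode neighbourhood graph:
# Gaussian kernel in Euclidean electrode distance with length scale equal to
# the median nearest-neighbour distance, rows normalised to sum 1.
spatial_smoother <- function(montage) {
  pos <- montage_positions(montage)
  d <- as.matrix(stats::dist(pos))
  nn <- apply(d + diag(Inf, nrow(d)), 1, min)
  ell <- stats::median(nn)
  w <- exp(-d^2 / (2 * ell^2))
  w / rowSums(w)
}

#' Render a multichannel EEG recording from a state sequence
#'
#' The signal model: at sample `t` with class label `l(t)`, the scalp map is
#' the subject's (jittered) class template times a rectified ~10 Hz carrier
#' `|sin(2 pi f t + phi)|`, with the sign of the template flipped randomly
#' per dwell segment to exercise polarity invariance downstream. Spatially
#' smoothed, 1-40 Hz band-limited Gaussian noise is added and scaled so that
#' the RMS GFP of the state signal over the RMS GFP of the noise equals
#' `snr`. Output is average-referenced. Optionally inserts artifact-mask
#' gaps.
#'
#' @param state_sequence integer labels, one per sample.
#' @param templates planted class templates (`n_classes x n_channels`,
#'   average-referenced unit GFP).
#' @param config an `ms_sim_config`.
#' @param subject_seed integer seed for this subject's noise, phase, sign
#'   flips, jitter, and mask placement.
#' @param subject,group identifiers stored in the recording.
#' @param montage the `ms_montage` the templates live on.
#' @return list with elements `recording` (an [ms_recording()]) and `truth`
#'   (planted labels, the subject's jittered templates, and true features
#'   from direct counting).
#' @export
render_eeg <- function(state_sequence, templates, config, subject_seed = 1L,
                       subject = "S01", group = "control", montage) {
  validate_sim_config(config)
  if (config$snr <= 0) stop("snr must be positive")
  n <- length(state_sequence)
  p <- ncol(templates)
  fs <- config$sampling_rate
  rng <- local_rng(subject_seed)
  out <- rng$eval(function() {
    # per-subject template perturbation, then renormalized
    subj_tpl <- templates
    if (config$template_jitter > 0) {
      pert <- matrix(stats::rnorm(nrow(templates) * p), nrow(templates), p)
      pert <- pert %*% spatial_smoother(montage)
      pert <- normalize_map(pert)
      subj_tpl <- normalize_map(templates + config$template_jitter * pert)
    }
    tt <- (seq_len(n) - 1) / fs
    phi <- stats::runif(1, 0, 2 * pi)
    fl <- config$carrier_floor
    env <- fl + (1 - fl) * abs(sin(2 * pi * config$carrier_freq * tt + phi))
    # random polarity per dwell segment
    r <- rle(state_sequence)
    seg_sign <- sample(c(-1, 1), length(r$lengths), replace = TRUE)
    sign_t <- rep(seg_sign, r$lengths)
    state <- subj_tpl[state_sequence, , drop = FALSE] * (env * sign_t)
    noise <- matrix(stats::rnorm(n * p), n, p) %*% spatial_smoother(montage)
    noise <- bandpass_filter(noise, 1, 40, fs)
    noise <- avg_reference(noise)
    rms_gfp <- function(m) sqrt(mean(rowMeans(m^2)))
    noise <- noise * (rms_gfp(state) / (config$snr * rms_gfp(noise)))
    data <- state + noise
    mask <- rep(TRUE, n)
    if (config$n_mask_segments > 0L && config$mask_segment_s > 0) {
      gap <- as.integer(round(config$mask_segment_s * fs))
      lo <- as.integer(n * 0.1); hi <- as.integer(n * 0.9) - gap
      if (hi > lo) {
        starts <- sort(sample(lo:hi, config$n_mask_segments))
        for (s in starts) mask[s:(s + gap - 1L)] <- FALSE
      }
    }
    list(data = data, mask = mask, subj_tpl = subj_tpl)
  })
  rec <- ms_recording(t(out$data), fs, montage, subject = subject,
                      group = group, mask = out$mask)
  truth <- list(
    labels = state_sequence,
    subject_templates = out$subj_tpl,
    features = sequence_features(state_sequence, fs,
                                 n_classes = config$n_classes)
  )
  list(recording = rec, truth = truth)
}

#' True dynamic features of a label sequence by direct counting
#'
#' Mean duration (ms), occurrence (1/s), and coverage (%) of every class,
#' counted directly on a fully labeled sample sequence (all dwell segments,
#' including the first and last, enter the counts).
#'
#' @param labels integer class labels, one per sample.
#' @param sampling_rate Hz.
#' @param n_classes total class count (classes absent from `labels` get
#'   occurrence 0, coverage 0, and `NA` duration).
#' @return data.frame with columns `class`, `mean_duration_ms`,
#'   `occurrence_per_s`, `coverage_pct`.
#' @export
sequence_features <- function(labels, sampling_rate, n_classes = max(labels)) {
  r <- rle(labels)
  total_s <- length(labels) / sampling_rate
  out <- data.frame(class = seq_len(n_classes),
                    mean_duration_ms = NA_real_,
                    occurrence_per_s = 0,
                    coverage_pct = 0)
  for (cl in seq_len(n_classes)) {
    sel <- r$values == cl
    if (any(sel)) {
      lens <- r$lengths[sel]
      out$mean_duration_ms[cl] <- mean(lens) / sampling_rate * 1000
      out$occurrence_per_s[cl] <- sum(sel) / total_s
      out$coverage_pct[cl] <- 100 * sum(lens) / length(labels)
    }
  }
  out
}

#' Simulate a full two-group cohort
#'
#' Generates planted templates on a synthetic montage, then one recording
#' per subject with group-specific dwell/transition laws, plus demographic
#' covariates (ages around the late 40s, a predominantly female sample,
#' mirroring typical insomnia case-control cohorts).
#'
#' @param config an `ms_sim_config`.
#' @return list of class `ms_cohort`: `recordings` (list of
#'   [ms_recording()]), `sample_sheet` (subject, group, age, sex),
#'   `montage`, `templates` (planted), `truth` (per-subject ground truth),
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  montage <- make_montage(config$n_channels)
  templates <- make_templates(montage, config$n_classes, seed = config$seed)
  rng <- local_rng(config$seed)
  n_tot <- 2L * config$n_per_group
  seeds <- rng$sample_int(.Machine$integer.max - 1L, n_tot)
  ages <- round(rng$rnorm(n_tot, mean = 47.5, sd = 14.5))
  ages <- pmin(pmax(ages, 20), 75)
  sexes <- ifelse(rng$runif(n_tot) < 0.8, "F", "M")
  groups <- rep(c("control", "patient"), each = config$n_per_group)
  ids <- sprintf("%s%02d", ifelse(groups == "control", "C", "P"),
                 c(seq_len(config$n_per_group), seq_len(config$n_per_group)))
  recordings <- vector("list", n_tot)
  truth <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    labs <- simulate_state_sequence(config, groups[i], seeds[i])
    r <- render_eeg(labs, templates, config, subject_seed = seeds[i] %% 2147483646L + 1L,
                    subject = ids[i], group = groups[i], montage = montage)
    recordings[[i]] <- r$recording
    truth[[i]] <- r$truth
  }
  names(recordings) <- ids
  names(truth) <- ids
  cohort <- list(
    recordings = recordings,
    sample_sheet = data.frame(subject = ids, group = groups,
                              age = ages, sex = sexes,
                              sampling_rate = config$sampling_rate,
                              stringsAsFactors = FALSE),
    montage = montage, templates = templates, truth = truth, config = config
  )
  class(cohort) <- "ms_cohort"
  cohort
}
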