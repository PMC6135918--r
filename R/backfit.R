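#' Competitive back-fitting of group templates to a recording
#'
#' Assigns each topography to the microstate class with which the highest
#' absolute spatial correlation is attained, either at GFP peaks only
#' (`at_peaks_only = TRUE`, the default) or at every usable timeframe. Ties
#' are broken by the lowest class index. Zero-variance frames inherit the
#' label of the previous labeled point; a leading zero-variance run stays
#' unlabeled (`NA`).
#'
#' @param recording an average-referenced `ms_recording`.
#' @param group_model an `ms_group_model` (channel counts must match).
#' @param at_peaks_only label only GFP peaks (default) or all usable frames.
#' @return list of class `ms_backfit`: `mode`, `indices` (sample indices of
#'   the labeled points), `labels` (class index per point, `NA` where
#'   unlabeled), `classes` (canonical letters if the model is labeled),
#'   `sampling_rate`, `mask`.
#' @export
backfit <- function(recording, group_model, at_peaks_only = TRUE) {
  tpl <- normalize_map(group_model$templates)
  if (ncol(tpl) != nrow(recording$data)) {
    stop("model channel count does not match the recording")
  }
  if (at_peaks_only) {
    g <- compute_gfp(recording)
    idx <- find_gfp_peaks(g)
    maps <- t(recording$data[, idx, drop = FALSE])
    zerovar <- map_gfp(maps) <= .Machine$double.eps
  } else {
    if (!is_avg_referenced(recording)) {
      stop("recording must be average-referenced")
    }
    idx <- which(recording$mask)
    maps <- t(recording$data[, idx, drop = FALSE])
    zerovar <- map_gfp(maps) <= .Machine$double.eps
  }
  labels <- rep(NA_integer_, length(idx))
  if (any(!zerovar)) {
    mm <- normalize_map(maps[!zerovar, , drop = FALSE])
    A <- abs(corr_cross(mm, tpl))
    labels[!zerovar] <- max.col(A, ties.method = "first")
  }
  # zero-variance frames copy the previous label; a leading run stays NA
  if (any(zerovar)) {
    for (i in which(zerovar)) {
      if (i > 1L) labels[i] <- labels[i - 1L]
    }
  }
  structure(list(
    mode = if (at_peaks_only) "peaks" else "frames",
    indices = idx, labels = labels,
    classes = if (!is.null(group_model$labels)) group_model$labels else
      as.character(seq_len(nrow(tpl))),
    sampling_rate = recording$sampling_rate, mask = recording$mask
  ), class = "ms_backfit")
}

#' Segment labeled points into a microstate sequence
#'
#' Runs of consecutive equally-labeled points within one usable stretch are
#' merged into one microstate. Segment boundaries are the midpoints (in
#' continuous time) between the neighboring labeled points of adjacent
#' runs. The first and last run of every usable stretch are marked invalid
#' (their outer boundary cannot be estimated), as are runs bordering masked
#' gaps; stretches with fewer than three labeled points yield no valid
#' segments.
#'
#' @param bf an `ms_backfit` (or a list with `indices`, `labels`, `mask`,
#'   `sampling_rate`, `classes`).
#' @param subject identifier stored on the sequence.
#' @return list of class `ms_sequence`: `segments` (data.frame `class`,
#'   `label`, `start_s`, `end_s`, `valid`), `total_usable_s`, `classes`,
#'   `subject`.
#' @export
segment_microstates <- function(bf, subject = NA_character_) {
  fs <- bf$sampling_rate
  segs <- list()
  for (run in usable_runs(bf$mask)) {
    in_run <- bf$indices >= run[1] & bf$indices <= run[length(run)]
    idx <- bf$indices[in_run]
    lab <- bf$labels[in_run]
    keep <- !is.na(lab)
    idx <- idx[keep]; lab <- lab[keep]
    if (length(idx) == 0) next
    r <- rle(lab)
    n_runs <- length(r$values)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (j in seq_len(n_runs)) {
      valid <- j > 1L && j < n_runs
      start_s <- if (j > 1L) {
        (idx[ends_i[j - 1L]] + idx[starts_i[j]]) / 2 / fs
      } else NA_real_
      end_s <- if (j < n_runs) {
        (idx[ends_i[j]] + idx[starts_i[j + 1L]]) / 2 / fs
      } else NA_real_
      segs[[length(segs) + 1L]] <- data.frame(
        class = r$values[j], start_s = start_s, end_s = end_s, valid = valid)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(class = integer(0), start_s = numeric(0),
               end_s = numeric(0), valid = logical(0))
  segments$label <- bf$classes[segments$class]
  structure(list(segments = segments,
                 total_usable_s = sum(bf$mask) / fs,
                 classes = bf$classes, subject = subject),
            class = "ms_sequence")
}

#' Dynamic features of a microstate sequence
#'
#' Per class: mean duration of the valid segments (ms), frequency of
#' occurrence (valid segments per second), and proportional coverage time
#' (% of time). The default denominator for occurrence and coverage is the
#' total valid-segment time, which keeps the three features mutually
#' consistent and coverage summing to 100%; `denominator = "usable"`
#' switches to the raw usable recording time.
#'
#' @param sequence an `ms_sequence` with at least one valid segment.
#' @param n_classes total class count (defaults to the model's class set).
#' @param denominator `"valid"` (default) or `"usable"`.
#' @return data.frame with one row per class: `class`, `label`,
#'   `mean_duration_ms`, `occurrence_per_s`, `coverage_pct`. Classes with
#'   no valid segments get occurrence 0, coverage 0, and `NA` duration.
#' @export
microstate_features <- function(sequence, n_classes = length(sequence$classes),
                                denominator = c("valid", "usable")) {
  denominator <- match.arg(denominator)
  segs <- sequence$segments[sequence$segments$valid, , drop = FALSE]
  if (nrow(segs) == 0) stop("no valid segments: cannot compute features")
  dur <- segs$end_s - segs$start_s
  total_s <- if (denominator == "valid") sum(dur) else sequence$total_usable_s
  out <- data.frame(class = seq_len(n_classes),
                    label = sequence$classes[seq_len(n_classes)],
                    mean_duration_ms = NA_real_,
                    occurrence_per_s = 0, coverage_pct = 0)
  for (cl in seq_len(n_classes)) {
    sel <- segs$class == cl
    if (any(sel)) {
      out$mean_duration_ms[cl] <- mean(dur[sel]) * 1000
      out$occurrence_per_s[cl] <- sum(sel) / total_s
      out$coverage_pct[cl] <- 100 * sum(dur[sel]) / total_s
    }
  }
  out
}

#' Feature table for a set of recordings
#'
#' Runs back-fitting, segmentation, and feature extraction for every
#' recording and binds the rows with the subjects' covariates.
#'
#' @param recordings list of average-referenced `ms_recording`s.
#' @param group_model an `ms_group_model`.
#' @param sample_sheet data.frame with `subject`, `group`, `age`, `sex`.
#' @param at_peaks_only back-fitting mode (default peaks).
#' @param denominator passed to [microstate_features()].
#' @return data.frame, one row per subject x class, with covariates and the
#'   three dynamic features.
#' @export
feature_table <- function(recordings, group_model, sample_sheet,
                          at_peaks_only = TRUE,
                          denominator = c("valid", "usable")) {
  denominator <- match.arg(denominator)
  rows <- lapply(recordings, function(rec) {
    bf <- backfit(rec, group_model, at_peaks_only = at_peaks_only)
    sq <- segment_microstates(bf, subject = rec$subject)
    ft <- microstate_features(sq, denominator = denominator)
    ft$subject <- rec$subject
    ft
  })
  tab <- do.call(rbind, rows)
  merge(sample_sheet[, intersect(c("subject", "group", "age", "sex"),
                                 names(sample_sheet))],
        tab, by = "subject")
}

#' Equivalence of peak-only and every-timeframe back-fitting
#'
#' Computes the three dynamic features under both back-fitting modes and
#' returns, per class and feature, the Pearson correlation of the feature
#' values across subjects.
#'
#' @param recordings list of average-referenced `ms_recording`s.
#' @param group_model an `ms_group_model`.
#' @param sample_sheet data.frame of covariates (see [feature_table()]).
#' @return data.frame `label`, `feature`, `r`.
#' @export
peak_vs_frame_equivalence <- function(recordings, group_model, sample_sheet) {
  ft_p <- feature_table(recordings, group_model, sample_sheet, at_peaks_only = TRUE)
  ft_f <- feature_table(recordings, group_model, sample_sheet, at_peaks_only = FALSE)
  key <- c("subject", "label")
  m <- merge(ft_p, ft_f, by = key, suffixes = c(".peaks", ".frames"))
  feats <- c("mean_duration_ms", "occurrence_per_s", "coverage_pct")
  out <- expand.grid(label = sort(unique(m$label)), feature = feats,
                     stringsAsFactors = FALSE)
  out$r <- mapply(function(lb, fe) {
    sub <- m[m$label == lb, ]
    stats::cor(sub[[paste0(fe, ".peaks")]], sub[[paste0(fe, ".frames")]],
               use = "complete.obs")
  }, out$label, out$feature)
  out
}
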