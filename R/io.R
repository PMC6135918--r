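#' Write a recording as a delimited matrix
#'
#' Samples in rows, channels in columns, tab-separated with channel ids as
#' header. Masked (unusable) stretches, if any, are written alongside as
#' half-open `[start, end)` second intervals (time origin at the first
#' sample) in a `*.mask.tsv` file.
#'
#' @param recording an `ms_recording`.
#' @param path destination `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  m <- t(recording$data)
  colnames(m) <- recording$montage$channel[recording$montage$scalp]
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!all(recording$mask)) {
    write_mask_intervals(recording$mask, recording$sampling_rate,
                         mask_path_for(path))
  }
  invisible(path)
}

mask_path_for <- function(path) sub("\\.tsv$", ".mask.tsv", path)

#' Write and read artifact-mask intervals
#'
#' Intervals of *unusable* time as half-open `[start, end)` seconds,
#' 0-based time origin at the first sample.
#'
#' @param mask logical per-sample flag (`TRUE` = usable).
#' @param sampling_rate Hz.
#' @param path file path.
#' @return `path` (write) or a logical mask vector (read), invisibly.
#' @export
write_mask_intervals <- function(mask, sampling_rate, path) {
  r <- rle(!mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  bad <- r$values
  df <- data.frame(start_s = (starts[bad] - 1) / sampling_rate,
                   end_s = ends[bad] / sampling_rate)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mask_intervals
#' @param n_samples recording length in samples.
#' @export
read_mask_intervals <- function(path, n_samples, sampling_rate) {
  mask <- rep(TRUE, n_samples)
  if (!file.exists(path)) return(mask)
  iv <- utils::read.table(path, header = TRUE, sep = "\t")
  for (i in seq_len(nrow(iv))) {
    a <- floor(iv$start_s[i] * sampling_rate) + 1L
    b <- ceiling(iv$end_s[i] * sampling_rate)
    mask[max(1L, a):min(n_samples, b)] <- FALSE
  }
  mask
}

#' Read a recording written by [write_recording()]
#'
#' @param path `.tsv` matrix path.
#' @param montage an `ms_montage`.
#' @param sampling_rate Hz.
#' @param subject,group identifiers.
#' @return an `ms_recording`.
#' @export
read_recording <- function(path, montage, sampling_rate,
                           subject = basename(path), group = NA_character_) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  mask <- read_mask_intervals(mask_path_for(path), nrow(m), sampling_rate)
  ms_recording(t(m), sampling_rate, montage, subject = subject,
               group = group, mask = mask)
}

#' Serialize a group microstate model to JSON
#'
#' Templates, canonical labels, class count, dispersion curve, selection
#' criterion, per-subject assignment, and (if present) per-subject global
#' explained variance, in one structured text file.
#'
#' @param model an `ms_group_model`.
#' @param path destination `.json`.
#' @return `path`, invisibly.
#' @export
write_group_model <- function(model, path) {
  obj <- list(
    k_star = model$k_star,
    labels = model$labels,
    templates = model$templates,
    W = as.list(model$W),
    criterion = model$criterion,
    assignment = model$assignment,
    class_ev = model$class_ev,
    gev_per_subject = model$gev_per_subject,
    channels = model$montage$channel[model$montage$scalp]
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a group model written by [write_group_model()]
#'
#' @param path `.json` path.
#' @param montage the montage the model was built on.
#' @return an `ms_group_model`.
#' @export
read_group_model <- function(path, montage) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tpl <- as.matrix(obj$templates)
  rownames(tpl) <- obj$labels
  structure(list(
    k_star = as.integer(obj$k_star), templates = tpl, labels = obj$labels,
    assignment = obj$assignment, W = unlist(obj$W), criterion = obj$criterion,
    class_ev = obj$class_ev, gev_per_subject = obj$gev_per_subject,
    montage = montage
  ), class = "ms_group_model")
}

#' Read a simulation configuration from structured text
#'
#' Accepts YAML (`.yml`/`.yaml`, requires the yaml package) or JSON. Fields
#' mirror the arguments of [simulation_config()]; omitted fields keep their
#' defaults.
#'
#' @param path configuration file path.
#' @return a validated `ms_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configurations")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown configuration fields: ",
                            paste(unknown, collapse = ", "))
  for (f in c("dwell_means", "occurrence_weights")) {
    if (!is.null(raw[[f]])) raw[[f]] <- lapply(raw[[f]], unlist)
  }
  do.call(simulation_config, raw)
}

#' Write a simulated cohort to a directory
#'
#' One delimited recording per subject plus `montage.tsv`,
#' `sample_sheet.tsv`, a ground-truth sidecar (`ground_truth.json`:
#' planted templates, run-length-encoded state sequences, true features),
#' and a run manifest.
#'
#' @param config an `ms_sim_config`.
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory (default FALSE).
#' @return the cohort (invisibly), as from [simulate_cohort()].
#' @export
simulate_cohort_dir <- function(config, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force) {
    stop("output directory ", dir, " is not empty (use force = TRUE)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  write_montage(cohort$montage, file.path(dir, "montage.tsv"))
  sheet <- cohort$sample_sheet
  sheet$file <- paste0(sheet$subject, ".tsv")
  for (i in seq_len(nrow(sheet))) {
    write_recording(cohort$recordings[[sheet$subject[i]]],
                    file.path(dir, sheet$file[i]))
  }
  utils::write.table(sheet, file.path(dir, "sample_sheet.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- list(
    templates = cohort$templates,
    subjects = lapply(cohort$truth, function(tr) {
      r <- rle(tr$labels)
      list(labels_rle = list(values = r$values, lengths = r$lengths),
           features = tr$features)
    })
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  manifest <- list(stage = "simulate", seed = config$seed,
                   config = unclass(config),
                   package_version = as.character(utils::packageVersion("microstatr")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(cohort)
}

#' Read a cohort directory written by [simulate_cohort_dir()]
#'
#' @param dir cohort directory containing `montage.tsv` and
#'   `sample_sheet.tsv`.
#' @return list with `recordings`, `sample_sheet`, `montage`.
#' @export
read_cohort_dir <- function(dir) {
  montage <- read_montage(file.path(dir, "montage.tsv"))
  sheet <- utils::read.table(file.path(dir, "sample_sheet.tsv"),
                             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(sheet)), function(i) {
    path <- file.path(dir, sheet$file[i])
    if (!file.exists(path)) stop("recording for subject ", sheet$subject[i],
                                 " not found: ", path)
    read_recording(path, montage, sheet$sampling_rate[i],
                   subject = sheet$subject[i], group = sheet$group[i])
  })
  names(recordings) <- sheet$subject
  list(recordings = recordings, sample_sheet = sheet, montage = montage)
}
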