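#' Construct a synthetic scalp montage
#'
#' Places `n_channels` electrodes quasi-uniformly on the upper portion of a
#' unit sphere (a Fibonacci spiral over the spherical cap covered by
#' high-density EEG nets, reaching slightly below the equator as real nets
#' do). Coordinates follow the convention x = right, y = anterior, z = up.
#'
#' @param n_channels number of electrodes (default 64; 204 gives a layout of
#'   the density used for high-density scalp subsets).
#' @param cap_z_min lowest z coordinate covered by the net (default -0.15).
#' @return a `data.frame` of class `ms_montage` with columns `channel`,
#'   `x`, `y`, `z`, `scalp` (logical inclusion flag).
#' @export
make_montage <- function(n_channels = 64, cap_z_min = -0.15) {
  stopifnot(n_channels >= 3)
  i <- seq_len(n_channels) - 0.5
  z <- 1 - (1 - cap_z_min) * i / n_channels
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n_channels) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  m <- data.frame(
    channel = sprintf("E%03d", seq_len(n_channels)),
    x = r * cos(phi),
    y = r * sin(phi),
    z = z,
    scalp = TRUE,
    stringsAsFactors = FALSE
  )
  class(m) <- c("ms_montage", "data.frame")
  validate_montage(m)
  m
}

validate_montage <- function(m) {
  stopifnot(is.data.frame(m), all(c("channel", "x", "y", "z", "scalp") %in% names(m)))
  if (anyDuplicated(m$channel)) stop("montage channel ids must be unique")
  nrm <- sqrt(m$x^2 + m$y^2 + m$z^2)
  if (any(abs(nrm - 1) > 1e-6)) stop("montage positions must lie on the unit sphere")
  invisible(m)
}

#' Read a montage from delimited text
#'
#' Expected columns: `channel`, `x`, `y`, `z`, `scalp` (tab-separated, header).
#'
#' @param path file path.
#' @return an `ms_montage` data frame.
#' @export
read_montage <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  m$scalp <- as.logical(m$scalp)
  class(m) <- c("ms_montage", "data.frame")
  validate_montage(m)
  m
}

#' Write a montage to delimited text
#'
#' @param montage an `ms_montage` data frame.
#' @param path destination path.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(as.data.frame(montage), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Positions matrix (n_channels x 3) of the scalp subset.
montage_positions <- function(montage) {
  m <- montage[montage$scalp, , drop = FALSE]
  as.matrix(m[, c("x", "y", "z")])
}
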