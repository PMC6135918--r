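#' Average-reference a scalp map or a maps matrix
#'
#' Subtracts the instantaneous channel mean, re-expressing every channel
#' relative to the common average of all scalp channels.
#'
#' @param x numeric vector (one map) or matrix with maps in rows
#'   (`n_maps x n_channels`).
#' @return object of the same shape with zero channel mean per map.
#' @export
avg_reference <- function(x) {
  if (is.matrix(x)) {
    x - rowMeans(x)
  } else {
    x - mean(x)
  }
}

#' Global field power of one or more scalp maps
#'
#' GFP is the spatial standard deviation (population form, divisor `N`) of
#' the average-referenced map: `sqrt(mean(v^2))` with `v` centered across
#' channels.
#'
#' @param x numeric vector or matrix with maps in rows.
#' @param reref average-reference before computing (default `TRUE`); set
#'   `FALSE` when the input is already centered.
#' @return numeric scalar, or vector of length `nrow(x)`.
#' @export
map_gfp <- function(x, reref = TRUE) {
  if (reref) x <- avg_reference(x)
  if (is.matrix(x)) sqrt(rowMeans(x^2)) else sqrt(mean(x^2))
}

#' Normalize maps to zero mean and unit GFP
#'
#' @param x numeric vector or matrix with maps in rows.
#' @return same shape; each map has channel mean 0 and GFP 1. Maps with zero
#'   variance raise an error.
#' @export
normalize_map <- function(x) {
  x <- avg_reference(x)
  g <- map_gfp(x, reref = FALSE)
  if (any(g <= .Machine$double.eps)) {
    stop("cannot normalize a zero-variance (flat) scalp map")
  }
  if (is.matrix(x)) x / g else x / g
}

#' Absolute spatial correlation between two scalp maps
#'
#' The polarity-invariant similarity used throughout microstate analysis:
#' the absolute Pearson correlation of the two maps across channels. A map
#' and its sign-flip are identical under this measure.
#'
#' @param u,v numeric vectors of equal length (one value per channel).
#' @return value in `[0, 1]`.
#' @export
abs_spatial_corr <- function(u, v) {
  if (length(u) != length(v)) stop("maps must have the same channel count")
  u <- u - mean(u)
  v <- v - mean(v)
  du <- sqrt(sum(u^2)); dv <- sqrt(sum(v^2))
  if (du <= .Machine$double.eps || dv <= .Machine$double.eps) {
    stop("zero-variance map: spatial correlation undefined")
  }
  min(1, abs(sum(u * v)) / (du * dv))
}

# Signed correlation matrix between two sets of maps given as rows.
# Both inputs must already be average-referenced with unit GFP, in which
# case Pearson correlation reduces to mean(u*v) = (u . v) / n_channels.
corr_cross <- function(maps, templates) {
  tcrossprod(maps, templates) / ncol(maps)
}
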