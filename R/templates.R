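# Schematic topographic generators. Geodesic Gaussian blob centred at unit
# vector `centre` with angular width `sigma` (radians).
geodesic_blob <- function(pos, centre, sigma = 0.6) {
  ang <- acos(pmin(1, pmax(-1, pos %*% centre)))
  exp(-(ang^2) / (2 * sigma^2))
}

#' Canonical reference microstate topographies
#'
#' Renders schematic versions of the classical microstate classes A-E on a
#' montage, for canonical labeling of group templates and as the planted
#' classes of the synthetic generator: two mirror-image diagonal gradients
#' (A, B), a fronto-occipital pattern (C), a frontal-central pattern (D),
#' and a centro-parietal pattern (E).
#'
#' @param montage an `ms_montage`.
#' @param sigma angular width (radians) of the blob-shaped patterns.
#' @return matrix `5 x n_channels` of average-referenced unit-GFP maps, with
#'   rownames `A`..`E`.
#' @export
reference_templates <- function(montage, sigma = 0.45) {
  pos <- montage_positions(montage)
  x <- pos[, 1]; y <- pos[, 2]
  a <- x + y                       # right-anterior / left-posterior gradient
  b <- y - x                       # mirror-image diagonal
  c_map <- geodesic_blob(pos, c(0, 0.98, 0.20), sigma) -
    geodesic_blob(pos, c(0, -0.98, 0.20), sigma)       # fronto-occipital
  d_map <- geodesic_blob(pos, c(0, 0.50, 0.866), sigma) # frontal-central
  e_map <- geodesic_blob(pos, c(0, -0.60, 0.80), sigma) # centro-parietal
  tpl <- rbind(A = a, B = b, C = as.numeric(c_map),
               D = as.numeric(d_map), E = as.numeric(e_map))
  normalize_map(tpl)
}

#' Generate planted microstate class templates
#'
#' The first five classes are the schematic canonical topographies from
#' [reference_templates()]; further classes are smooth random patterns
#' (random tangential gradient plus a random blob), re-drawn until every
#' pairwise absolute spatial correlation is at most `max_abs_corr`.
#'
#' @param montage an `ms_montage`.
#' @param n_classes number of templates (>= 2).
#' @param seed integer seed controlling the random extra classes.
#' @param max_abs_corr pairwise similarity bound (default 0.7).
#' @param max_attempts redraw budget per extra class before failing.
#' @return matrix `n_classes x n_channels`, average-referenced, unit GFP.
#' @export
make_templates <- function(montage, n_classes, seed = 1L,
                           max_abs_corr = 0.7, max_attempts = 200L) {
  stopifnot(n_classes >= 2)
  pos <- montage_positions(montage)
  if (nrow(pos) < n_classes) stop("montage too small for requested class count")
  refs <- reference_templates(montage)
  tpl <- refs[seq_len(min(5, n_classes)), , drop = FALSE]
  pair_ok <- function(m) {
    cc <- abs(corr_cross(m, m))
    diag(cc) <- 0
    all(cc <= max_abs_corr)
  }
  if (!pair_ok(tpl)) {
    stop("montage too small to render reference templates below the ",
         "pairwise correlation bound")
  }
  if (n_classes > 5) {
    rng <- local_rng(seed)
    for (j in seq.int(6, n_classes)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        dir_g <- rng$runif_sphere()
        dir_b <- rng$runif_sphere()
        cand <- as.numeric(pos %*% dir_g) +
          rng$runif(1, 0.5, 2) * geodesic_blob(pos, dir_b, 0.5)
        cand <- normalize_map(cand)
        if (pair_ok(rbind(tpl, cand))) {
          tpl <- rbind(tpl, cand)
          rownames(tpl)[j] <- sprintf("X%d", j - 5L)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not draw template ", j, " below the pairwise ",
             "correlation bound in ", max_attempts, " attempts")
      }
    }
  }
  tpl
}

# Small self-contained RNG wrapper: isolates seeding from the caller's
# random state so generators are reproducible without clobbering .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    eval = with_state,
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    rgamma = function(n, shape, scale) with_state(function() stats::rgamma(n, shape = shape, scale = scale)),
    sample_int = function(n, size = 1, prob = NULL) with_state(function() sample.int(n, size, replace = TRUE, prob = prob)),
    runif_sphere = function() with_state(function() {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2))
    })
  )
}
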