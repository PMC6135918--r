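# Dominant eigenvector of crossprod(M) by warm-started power iteration.
# This is the polarity-invariant centroid: the unit map maximizing the sum
# of squared spatial correlations with the cluster members.
dominant_map <- function(M, v0 = NULL, tol = 1e-12, max_iter = 200L) {
  p <- ncol(M)
  v <- if (is.null(v0)) M[1, ] else v0
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(max_iter)) {
    w <- as.numeric(crossprod(M, M %*% v))
    nw <- sqrt(sum(w^2))
    if (nw <= .Machine$double.eps) break
    w <- w / nw
    if (1 - abs(sum(w * v)) < tol) { v <- w; break }
    v <- w
  }
  # members are centered maps, so v is centered up to round-off
  v <- v - mean(v)
  v / sqrt(mean(v^2))
}

restart_seed <- function(seed, r) {
  as.integer((as.numeric(seed) + 104729 * r) %% 2147483647)
}

#' Polarity-invariant (modified) k-means over scalp maps
#'
#' Clusters topographies by absolute spatial correlation: maps are assigned
#' to the template with the highest `|corr|`, and each template is updated
#' as the dominant eigenvector of the outer-product sum of its assigned
#' maps (the polarity-invariant centroid). The best of `n_restarts`
#' random initializations by minimal dispersion is returned, where
#' dispersion is the within-cluster sum of `1 - |corr|`.
#'
#' @param maps matrix `n_maps x n_channels`; normalized internally to zero
#'   mean and unit GFP per map.
#' @param k number of clusters, `1 <= k <= n_maps`.
#' @param n_restarts random restarts (default 20).
#' @param seed master seed; restart seeds are derived by fixed arithmetic.
#' @param max_iter iteration cap per restart (default 100).
#' @return list with `templates` (`k x n_channels`, unit GFP), `labels`
#'   (cluster index per map), `dispersion`, and `dispersion_trace` of the
#'   winning restart.
#' @export
modified_kmeans <- function(maps, k, n_restarts = 20L, seed = 1L,
                            max_iter = 100L) {
  maps <- normalize_map(maps)
  n <- nrow(maps)
  if (k > n) stop("k (", k, ") exceeds the number of maps (", n, ")")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    rng <- local_rng(restart_seed(seed, r))
    init <- rng$eval(function() sample.int(n, k))
    fit <- kmeans_once(maps, k, init, max_iter)
    if (is.null(best) || fit$dispersion < best$dispersion) best <- fit
  }
  best
}

# One k-means run. The eigenvector update maximizes the sum of squared
# correlations, which does not strictly decrease the 1 - |corr| dispersion,
# so the incumbent (best-visited) assignment is tracked and returned; the
# reported trace is the incumbent dispersion, which never increases.
kmeans_once <- function(maps, k, init, max_iter) {
  n <- nrow(maps)
  tpl <- maps[init, , drop = FALSE]
  labels <- integer(n)
  trace <- numeric(0)
  best <- list(dispersion = Inf)
  for (it in seq_len(max_iter)) {
    A <- abs(corr_cross(maps, tpl))
    new_labels <- max.col(A, ties.method = "first")
    # empty cluster: reseed its template from the currently worst-fit map
    counts <- tabulate(new_labels, nbins = k)
    if (any(counts == 0)) {
      fit_of <- A[cbind(seq_len(n), new_labels)]
      for (j in which(counts == 0)) {
        worst <- which.min(fit_of)
        tpl[j, ] <- maps[worst, ]
        fit_of[worst] <- Inf
      }
      A <- abs(corr_cross(maps, tpl))
      new_labels <- max.col(A, ties.method = "first")
    }
    disp <- sum(1 - pmin(A[cbind(seq_len(n), new_labels)], 1))
    if (disp < best$dispersion) {
      best <- list(templates = tpl, labels = new_labels, dispersion = disp)
    }
    trace <- c(trace, best$dispersion)
    converged <- it > 1L && identical(new_labels, labels)
    labels <- new_labels
    if (converged) break
    # warm-started power steps; the winner is polished at full precision
    for (j in seq_len(k)) {
      members <- maps[labels == j, , drop = FALSE]
      if (nrow(members) > 0) tpl[j, ] <- dominant_map(members, tpl[j, ], max_iter = 4L)
    }
  }
  tpl <- best$templates
  for (j in seq_len(k)) {
    members <- maps[best$labels == j, , drop = FALSE]
    if (nrow(members) > 0) tpl[j, ] <- dominant_map(members, tpl[j, ])
  }
  A <- abs(corr_cross(maps, tpl))
  labels <- max.col(A, ties.method = "first")
  disp <- sum(1 - pmin(A[cbind(seq_len(n), labels)], 1))
  if (disp > best$dispersion) {
    tpl <- best$templates; labels <- best$labels; disp <- best$dispersion
  }
  list(templates = tpl, labels = labels, dispersion = disp,
       dispersion_trace = c(trace, disp))
}

#' Krzanowski-Lai selection of the number of clusters
#'
#' Identifies the point of maximal normalized curvature of the dispersion
#' curve: `DIFF(k) = (k-1)^(2/p) W(k-1) - k^(2/p) W(k)` with `p` the data
#' dimensionality (number of scalp channels), and
#' `KL(k) = |DIFF(k)| / |DIFF(k+1)|`; the selected count maximizes `KL(k)`
#' over the candidate range.
#'
#' @param W_by_k named numeric vector of dispersions; names are the cluster
#'   counts, and must cover `min(candidate_range) - 1` through
#'   `max(candidate_range) + 1`.
#' @param n_channels data dimensionality `p`.
#' @param candidate_range integer candidates (default `3:11`).
#' @return the selected integer `k`, with attribute `"criterion"`: a
#'   data.frame of `k`, `DIFF`, `KL` over the candidate range. Candidates
#'   with `DIFF(k+1) = 0` are excluded; an error is raised if all are.
#' @export
krzanowski_lai_select <- function(W_by_k, n_channels, candidate_range = 3:11) {
  ks <- as.integer(names(W_by_k))
  need <- (min(candidate_range) - 1L):(max(candidate_range) + 1L)
  if (!all(need %in% ks)) {
    stop("W_by_k must cover k = ", min(need), "..", max(need))
  }
  W <- function(k) W_by_k[[as.character(k)]]
  p <- n_channels
  DIFF <- function(k) (k - 1)^(2 / p) * W(k - 1) - k^(2 / p) * W(k)
  d_here <- vapply(candidate_range, DIFF, numeric(1))
  d_next <- vapply(candidate_range + 1L, DIFF, numeric(1))
  kl <- abs(d_here) / abs(d_next)
  kl[d_next == 0] <- NA_real_
  if (all(is.na(kl))) stop("Krzanowski-Lai criterion undefined: all successive differences are zero")
  sel <- candidate_range[which.max(kl)]
  attr(sel, "criterion") <- data.frame(k = candidate_range, DIFF = d_here, KL = kl)
  sel
}

#' Subject-level microstate clustering with data-driven class count
#'
#' Extracts normalized topographies at the GFP peaks of one recording, runs
#' polarity-invariant k-means for every candidate cluster count (plus one
#' count below and above the range, needed by the selection criterion), and
#' selects the subject's optimal count by the Krzanowski-Lai criterion.
#'
#' @param recording an average-referenced `ms_recording`.
#' @param candidate_range candidate class counts (default `3:11`).
#' @param n_restarts k-means restarts per count (default 20).
#' @param seed master seed.
#' @return list of class `ms_subject_model`: `subject`, `k_star`,
#'   `templates` (`k_star x n_channels`), `W` (dispersion per count),
#'   `criterion`, `n_peaks`, `montage`.
#' @export
cluster_subject <- function(recording, candidate_range = 3:11,
                            n_restarts = 20L, seed = 1L) {
  if (!is_avg_referenced(recording)) {
    stop("recording must be average-referenced; run bandpass_and_reref() first")
  }
  g <- compute_gfp(recording)
  peaks <- find_gfp_peaks(g)
  k_all <- (min(candidate_range) - 1L):(max(candidate_range) + 1L)
  min_peaks <- max(k_all)
  if (length(peaks) < min_peaks) {
    stop("only ", length(peaks), " GFP peaks; at least ", min_peaks,
         " are required (>= ", 12 * max(candidate_range), " recommended)")
  }
  maps <- gfp_peak_maps(recording, peaks)
  W <- numeric(length(k_all))
  names(W) <- k_all
  fits <- vector("list", length(k_all))
  names(fits) <- k_all
  for (i in seq_along(k_all)) {
    k <- k_all[i]
    fits[[i]] <- modified_kmeans(maps, k, n_restarts = n_restarts,
                                 seed = restart_seed(seed, 1000L + k))
    W[i] <- fits[[i]]$dispersion
  }
  k_star <- krzanowski_lai_select(W, ncol(maps), candidate_range)
  structure(list(
    subject = recording$subject, group = recording$group,
    k_star = as.integer(k_star),
    templates = fits[[as.character(as.integer(k_star))]]$templates,
    W = W, criterion = attr(k_star, "criterion"),
    n_peaks = length(peaks), montage = recording$montage
  ), class = "ms_subject_model")
}

# One-to-one (when possible) assignment of one subject's templates to group
# classes, maximizing total |corr|. When the subject has more templates than
# classes, every class receives at least one template and the surplus is
# assigned freely by best |corr|.
assign_subject_templates <- function(A) {
  m <- nrow(A); k <- ncol(A)
  if (m <= k) {
    as.integer(clue::solve_LSAP(A, maximum = TRUE))
  } else {
    lab <- integer(m)
    cover <- as.integer(clue::solve_LSAP(t(A), maximum = TRUE))  # class -> template
    lab[cover] <- seq_len(k)
    rest <- setdiff(seq_len(m), cover)
    lab[rest] <- max.col(A[rest, , drop = FALSE], ties.method = "first")
    lab
  }
}

#' Group-level constrained microstate clustering
#'
#' Pools all subjects' template maps and clusters them with the
#' polarity-invariant k-means, under the constraint that each subject's
#' templates occupy `min(k_i, k)` distinct group classes. The constraint is
#' enforced at every assignment step by solving, per subject, the optimal
#' one-to-one assignment of its templates to group classes (Hungarian
#' algorithm) maximizing total `|corr|`. The group class count is selected
#' by the Krzanowski-Lai criterion.
#'
#' @param subject_models list of `ms_subject_model` (>= 2).
#' @param candidate_range candidate class counts (default `3:11`).
#' @param n_restarts restarts per count (default 20).
#' @param seed master seed.
#' @return list of class `ms_group_model`: `k_star`, `templates`
#'   (`k_star x n_channels`, unit GFP), `labels` (canonical letters, `NULL`
#'   until [canonical_labeling()] is applied), `assignment` (data.frame
#'   subject/template/class at `k_star`), `W`, `criterion`, `montage`.
#' @export
cluster_group <- function(subject_models, candidate_range = 3:11,
                          n_restarts = 20L, seed = 1L) {
  if (length(subject_models) < 2L) stop("need at least 2 subject models")
  X <- do.call(rbind, lapply(subject_models, `[[`, "templates"))
  X <- normalize_map(X)
  subj_of <- rep(seq_along(subject_models),
                 vapply(subject_models, function(m) nrow(m$templates), integer(1)))
  k_all <- (min(candidate_range) - 1L):(max(candidate_range) + 1L)
  W <- numeric(length(k_all)); names(W) <- k_all
  fits <- vector("list", length(k_all)); names(fits) <- k_all
  for (i in seq_along(k_all)) {
    k <- k_all[i]
    fits[[i]] <- constrained_kmeans(X, subj_of, k, n_restarts,
                                    restart_seed(seed, 2000L + k))
    W[i] <- fits[[i]]$dispersion
  }
  k_star <- krzanowski_lai_select(W, ncol(X), candidate_range)
  fit <- fits[[as.character(as.integer(k_star))]]
  assignment <- data.frame(
    subject = vapply(subject_models, `[[`, character(1), "subject")[subj_of],
    template = unlist(lapply(subject_models, function(m) seq_len(nrow(m$templates)))),
    class = fit$labels
  )
  Afin <- abs(corr_cross(X, fit$templates))
  class_ev <- vapply(seq_len(nrow(fit$templates)), function(j) {
    sum(Afin[fit$labels == j, j]^2)
  }, numeric(1))
  structure(list(
    k_star = as.integer(k_star), templates = fit$templates, labels = NULL,
    assignment = assignment, W = W, criterion = attr(k_star, "criterion"),
    class_ev = class_ev, montage = subject_models[[1]]$montage
  ), class = "ms_group_model")
}

constrained_kmeans <- function(X, subj_of, k, n_restarts, seed, max_iter = 100L) {
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of pooled templates")
  by_subj <- split(seq_len(n), subj_of)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    rng <- local_rng(restart_seed(seed, r))
    init <- rng$eval(function() sample.int(n, k))
    tpl <- X[init, , drop = FALSE]
    labels <- integer(n)
    incumbent <- list(dispersion = Inf)
    for (it in seq_len(max_iter)) {
      A <- abs(corr_cross(X, tpl))
      new_labels <- integer(n)
      for (idx in by_subj) {
        new_labels[idx] <- assign_subject_templates(A[idx, , drop = FALSE])
      }
      counts <- tabulate(new_labels, nbins = k)
      if (any(counts == 0)) {
        fit_of <- A[cbind(seq_len(n), new_labels)]
        for (j in which(counts == 0)) {
          worst <- which.min(fit_of)
          tpl[j, ] <- X[worst, ]
          fit_of[worst] <- Inf
        }
        A <- abs(corr_cross(X, tpl))
        for (idx in by_subj) {
          new_labels[idx] <- assign_subject_templates(A[idx, , drop = FALSE])
        }
      }
      disp <- sum(1 - pmin(A[cbind(seq_len(n), new_labels)], 1))
      if (disp < incumbent$dispersion) {
        incumbent <- list(templates = tpl, labels = new_labels, dispersion = disp)
      }
      converged <- it > 1L && identical(new_labels, labels)
      labels <- new_labels
      if (converged) break
      for (j in seq_len(k)) {
        members <- X[labels == j, , drop = FALSE]
        if (nrow(members) > 0) tpl[j, ] <- dominant_map(members, tpl[j, ], max_iter = 4L)
      }
    }
    tpl <- incumbent$templates
    for (j in seq_len(k)) {
      members <- X[incumbent$labels == j, , drop = FALSE]
      if (nrow(members) > 0) tpl[j, ] <- dominant_map(members, tpl[j, ])
    }
    A <- abs(corr_cross(X, tpl))
    labels <- integer(n)
    for (idx in by_subj) {
      labels[idx] <- assign_subject_templates(A[idx, , drop = FALSE])
    }
    disp <- sum(1 - pmin(A[cbind(seq_len(n), labels)], 1))
    if (disp > incumbent$dispersion) {
      tpl <- incumbent$templates; labels <- incumbent$labels
      disp <- incumbent$dispersion
    }
    if (is.null(best) || disp < best$dispersion) {
      best <- list(templates = tpl, labels = labels, dispersion = disp)
    }
  }
  best
}

#' Label group templates by the canonical microstate classes
#'
#' Matches group templates one-to-one to schematic renderings of the
#' canonical classes A-E by maximal total absolute spatial correlation
#' (exhausting all one-to-one assignments via the Hungarian algorithm,
#' polarity ignored). Surplus templates beyond the reference set are
#' labeled F, G, ... in descending order of their within-cluster explained
#' variance on the pooled subject templates.
#'
#' @param group_model an `ms_group_model`.
#' @param reference set of reference maps (`n_ref x n_channels`, rownames =
#'   letters); defaults to [reference_templates()] on the model's montage.
#' @return the model with `labels` set and templates (and the assignment
#'   table) reordered alphabetically.
#' @export
canonical_labeling <- function(group_model, reference = NULL) {
  if (is.null(reference)) reference <- reference_templates(group_model$montage)
  tpl <- group_model$templates
  k <- nrow(tpl); n_ref <- nrow(reference)
  A <- abs(corr_cross(tpl, reference))
  labels <- character(k)
  if (k <= n_ref) {
    sol <- as.integer(clue::solve_LSAP(A, maximum = TRUE))
    labels <- rownames(reference)[sol]
  } else {
    sol <- as.integer(clue::solve_LSAP(t(A), maximum = TRUE))  # ref -> template
    labels[sol] <- rownames(reference)
    surplus <- which(labels == "")
    ev <- if (!is.null(group_model$class_ev)) {
      group_model$class_ev[surplus]
    } else {
      rowSums(A[surplus, , drop = FALSE]^2)
    }
    labels[surplus[order(-ev)]] <- LETTERS[n_ref + seq_along(surplus)]
  }
  ord <- order(labels)
  out <- group_model
  out$templates <- tpl[ord, , drop = FALSE]
  rownames(out$templates) <- labels[ord]
  out$labels <- labels[ord]
  if (!is.null(group_model$class_ev)) out$class_ev <- group_model$class_ev[ord]
  remap <- match(seq_len(k), ord)
  out$assignment$class <- remap[group_model$assignment$class]
  out$assignment$label <- out$labels[out$assignment$class]
  out
}

#' Global explained variance of a group model on one recording
#'
#' The GFP-weighted proportion of topographic variance at the GFP peaks
#' accounted for by the competitively fitted class templates:
#' `GEV = 100 * sum_t (gfp_t * corr(v_t, T_label(t)))^2 / sum_t gfp_t^2`.
#'
#' @param recording an average-referenced `ms_recording`.
#' @param group_model an `ms_group_model`.
#' @return percentage in `[0, 100]`.
#' @export
global_explained_variance <- function(recording, group_model) {
  g <- compute_gfp(recording)
  peaks <- find_gfp_peaks(g)
  if (length(peaks) == 0) stop("no GFP peaks in recording")
  gfp_t <- g$gfp[peaks]
  if (sum(gfp_t^2) <= 0) stop("zero total GFP power at peaks")
  maps <- gfp_peak_maps(recording, peaks)
  C <- corr_cross(maps, normalize_map(group_model$templates))
  best <- apply(abs(C), 1, max)
  100 * sum((gfp_t * best)^2) / sum(gfp_t^2)
}
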