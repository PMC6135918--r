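test_that("absolute spatial correlation matches hand arithmetic and ignores polarity", {
  u <- rnorm(20)
  expect_equal(abs_spatial_corr(u, -u), 1)
  # orthogonal after centering
  a <- c(1, -1, 1, -1)
  b <- c(1, 1, -1, -1)
  expect_equal(abs_spatial_corr(a, b), 0)
  # hand-computed Pearson |r| for (1,2,3,4) vs (2,1,4,3): cov 3, var 5 -> 0.6
  expect_equal(abs_spatial_corr(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(abs_spatial_corr(rep(1, 4), a), "zero-variance")
})

test_that("modified k-means recovers noise-free clusters and the k=1 eigen solution", {
  p <- 8
  base <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
  tpl <- normalize_map(t(base))
  set.seed(2)
  signs <- sample(c(-1, 1), 30, replace = TRUE)
  maps <- tpl[rep(1:3, each = 10), ] * signs
  fit <- modified_kmeans(maps, 3, n_restarts = 10, seed = 1)
  expect_lt(fit$dispersion, 1e-9)
  A <- abs(microstatr:::corr_cross(maps, fit$templates))
  expect_equal(A[cbind(1:30, fit$labels)], rep(1, 30), tolerance = 1e-9)

  # k = 1: template is the dominant eigenvector of the outer-product sum
  maps <- rand_maps(40, 12, seed = 3)
  fit1 <- modified_kmeans(maps, 1, n_restarts = 1, seed = 1)
  ev <- eigen(crossprod(maps), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs_spatial_corr(fit1$templates[1, ], ev), 1, tolerance = 1e-8)
  disp_oracle <- sum(1 - abs(apply(maps, 1, abs_spatial_corr, v = ev)))
  expect_equal(fit1$dispersion, disp_oracle, tolerance = 1e-6)

  expect_error(modified_kmeans(maps[1:3, ], 4), "exceeds")
})

test_that("k-means dispersion beats every exhaustive labeling on a tiny instance", {
  maps <- rand_maps(8, 6, seed = 7)
  fit <- modified_kmeans(maps, 2, n_restarts = 20, seed = 5)
  disp_of_labeling <- function(lab) {
    d <- 0
    for (j in 1:2) {
      mem <- maps[lab == j, , drop = FALSE]
      if (nrow(mem) == 0) return(Inf)
      ev <- eigen(crossprod(mem), symmetric = TRUE)$vectors[, 1]
      d <- d + sum(1 - abs(apply(mem, 1, abs_spatial_corr, v = ev)))
    }
    d
  }
  all_disp <- vapply(0:(2^8 - 1), function(code) {
    disp_of_labeling(as.integer(intToBits(code))[1:8] + 1L)
  }, numeric(1))
  expect_lte(fit$dispersion, min(all_disp) + 1e-6)
})

test_that("clustering is invariant to sign flips and descends monotonically", {
  maps <- gfp_peak_maps(fix_prepped[[1]],
                        find_gfp_peaks(compute_gfp(fix_prepped[[1]])))
  maps <- maps[1:120, ]
  for (seed in 1:3) {
    fit <- modified_kmeans(maps, 4, n_restarts = 3, seed = seed)
    expect_true(all(diff(fit$dispersion_trace) <= 1e-9))
    set.seed(seed)
    flip <- sample(c(-1, 1), nrow(maps), replace = TRUE)
    fit2 <- modified_kmeans(maps * flip, 4, n_restarts = 3, seed = seed)
    expect_equal(fit2$dispersion, fit$dispersion, tolerance = 1e-9)
    expect_identical(fit2$labels, fit$labels)
  }
})

test_that("Krzanowski-Lai criterion finds the elbow and handles degeneracies", {
  W <- c(100, 60, 30, 10, 9.5, 9.2, 9.0, 8.8, 8.6, 8.5, 8.4)
  names(W) <- 2:12
  p <- 64
  sel <- krzanowski_lai_select(W, p)
  # independent evaluation of the criterion
  diff_o <- sapply(3:12, function(k) {
    (k - 1)^(2 / p) * W[[as.character(k - 1)]] - k^(2 / p) * W[[as.character(k)]]
  })
  kl_o <- abs(diff_o[1:9]) / abs(diff_o[2:10])
  expect_identical(as.integer(sel), (3:11)[which.max(kl_o)])
  expect_identical(as.integer(sel), 5L)

  # a linear decline still returns the formula's deterministic argmax
  W_lin <- seq(100, 0.5, length.out = 11)
  names(W_lin) <- 2:12
  expect_no_error(krzanowski_lai_select(W_lin, p))

  # a perfect fit at every k (W identically zero) leaves no defined ratio
  W_zero <- rep(0, 11)
  names(W_zero) <- 2:12
  expect_error(krzanowski_lai_select(W_zero, p), "undefined")
  expect_error(krzanowski_lai_select(W[1:5], p), "cover")
})

test_that("subject clustering recovers the planted class count near-noiselessly", {
  mon <- make_montage(32)
  cfg <- simulation_config(n_per_group = 1, n_channels = 32, duration = 30,
                           n_classes = 4, snr = 50, template_jitter = 0,
                           n_mask_segments = 0, seed = 21)
  tpl <- make_templates(mon, 4, seed = 21)
  labs <- simulate_state_sequence(cfg, "control", 8)
  r <- render_eeg(labs, tpl, cfg, 9, montage = mon)
  sm <- cluster_subject(r$recording, n_restarts = 5, seed = 1)
  expect_identical(sm$k_star, 4L)
  A <- abs(microstatr:::corr_cross(normalize_map(sm$templates), tpl))
  expect_equal(apply(A, 2, max), rep(1, 4), tolerance = 1e-3,
               ignore_attr = TRUE)

  # restart stability at snr 4: a different master seed, same selection
  rec4 <- fix_prepped[[1]]
  s1 <- cluster_subject(rec4, n_restarts = 5, seed = 11)
  s2 <- cluster_subject(rec4, n_restarts = 5, seed = 99)
  expect_identical(s1$k_star, s2$k_star)

  tiny <- ms_recording(matrix(rnorm(32 * 30), 32, 30), 250, mon)
  tiny$data <- sweep(tiny$data, 2, colMeans(tiny$data))
  expect_error(cluster_subject(tiny), "peaks")
})

test_that("constrained group clustering honors the per-subject distinctness rule", {
  # two subjects sharing identical templates: group model reproduces them
  mon <- make_montage(32)
  tpl <- make_templates(mon, 5)
  mk_model <- function(id) {
    structure(list(subject = id, k_star = 5L, templates = tpl,
                   montage = mon), class = "ms_subject_model")
  }
  models <- lapply(c("a", "b", "c"), mk_model)
  gm <- cluster_group(models, n_restarts = 5, seed = 3)
  expect_identical(gm$k_star, 5L)
  A <- abs(microstatr:::corr_cross(normalize_map(gm$templates), tpl))
  expect_equal(apply(A, 2, max), rep(1, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  # each subject's templates land on distinct classes
  by_subj <- split(gm$assignment$class, gm$assignment$subject)
  for (cl in by_subj) expect_identical(sort(cl), 1:5)

  # 2x2 assignment equals the best exhaustive one-to-one matching
  for (seed in 1:5) {
    set.seed(seed)
    A2 <- matrix(runif(4), 2, 2)
    got <- microstatr:::assign_subject_templates(A2)
    best <- if (A2[1, 1] + A2[2, 2] >= A2[1, 2] + A2[2, 1]) c(1L, 2L) else c(2L, 1L)
    expect_identical(got, best)
  }
})

test_that("canonical labeling matches references up to sign and permutation", {
  mon <- make_montage(32)
  refs <- reference_templates(mon)
  mk <- function(tpl) structure(list(k_star = nrow(tpl), templates = tpl,
                                     montage = mon, assignment = data.frame(
                                       subject = "s", template = 1,
                                       class = seq_len(nrow(tpl)))),
                                class = "ms_group_model")
  lab1 <- canonical_labeling(mk(refs))
  expect_identical(lab1$labels, LETTERS[1:5])
  flip <- refs * c(-1, 1, -1, 1, -1)
  lab2 <- canonical_labeling(mk(flip))
  expect_identical(lab2$labels, LETTERS[1:5])

  # shuffled templates: the recovered assignment equals the best of all 5!
  # one-to-one matchings by total |corr| (exhaustive oracle)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  lab3 <- canonical_labeling(mk(refs[perm, ]))
  A <- abs(microstatr:::corr_cross(refs[perm, ], refs))
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 5), ]
  scores <- apply(perms, 1, function(pp) sum(A[cbind(1:5, pp)]))
  best <- perms[which.max(scores), ]
  expect_identical(as.integer(best), perm)
  expect_identical(lab3$labels, LETTERS[1:5])
  expect_equal(diag(abs(microstatr:::corr_cross(lab3$templates, refs))),
               rep(1, 5), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("global explained variance matches its direct-sum definition", {
  rec <- fix_prepped[[2]]
  gev <- global_explained_variance(rec, fix_model)
  g <- compute_gfp(rec)
  pk <- find_gfp_peaks(g)
  maps <- gfp_peak_maps(rec, pk)
  tpln <- normalize_map(fix_model$templates)
  num <- 0
  for (i in seq_along(pk)) {
    cors <- apply(tpln, 1, function(tt) abs(sum((maps[i, ]) * tt) / ncol(maps)))
    num <- num + (g$gfp[pk[i]] * max(cors))^2
  }
  oracle <- 100 * num / sum(g$gfp[pk]^2)
  expect_equal(gev, oracle, tolerance = 1e-9)
  expect_gt(gev, 0)
  expect_lt(gev, 100)

  # maps exactly proportional to templates explain everything
  mon <- make_montage(16)
  tpl <- make_templates(mon, 3)
  amp <- 2 + sin(2 * pi * (0:59) / 6)
  dat <- t(tpl[rep(1:3, 20), ] * amp)
  rec2 <- ms_recording(dat, 250, mon)
  gm <- structure(list(k_star = 3L, templates = tpl, montage = mon),
                  class = "ms_group_model")
  expect_equal(global_explained_variance(rec2, gm), 100, tolerance = 1e-9)
})
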