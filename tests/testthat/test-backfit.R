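test_that("competitive fitting labels peaks by maximal |corr|, ignoring polarity", {
  rec <- fix_prepped[[1]]
  bf <- backfit(rec, fix_model)
  expect_identical(bf$mode, "peaks")

  # per-map brute-force argmax oracle
  maps <- gfp_peak_maps(rec, bf$indices)
  oracle <- apply(maps, 1, function(v) {
    which.max(apply(fix_model$templates, 1, function(tt) abs_spatial_corr(v, tt)))
  })
  expect_identical(bf$labels, as.integer(oracle))

  # polarity invariance: negate the whole recording
  neg <- rec; neg$data <- -neg$data
  expect_identical(backfit(neg, fix_model)$labels, bf$labels)

  # noise-free maps equal to templates reproduce planted identities
  mon <- make_montage(32)
  cfgh <- simulation_config(n_per_group = 1, n_channels = 32, duration = 20,
                            snr = 1e9, template_jitter = 0,
                            n_mask_segments = 0, seed = 33)
  tpl <- make_templates(mon, 5)
  labs <- simulate_state_sequence(cfgh, "control", 2)
  r <- render_eeg(labs, tpl, cfgh, 3, montage = mon)
  gm <- structure(list(k_star = 5L, templates = tpl, montage = mon),
                  class = "ms_group_model")
  bfh <- backfit(r$recording, gm)
  expect_identical(bfh$labels, labs[bfh$indices])
})

test_that("segmentation applies the midpoint rule and omits edge segments", {
  bf <- list(indices = c(10L, 20L, 30L, 40L, 50L), labels = c(1L, 1L, 2L, 2L, 1L),
             mask = rep(TRUE, 60), sampling_rate = 250,
             classes = c("A", "B"))
  sq <- segment_microstates(bf, subject = "toy")
  valid <- sq$segments[sq$segments$valid, ]
  expect_identical(nrow(valid), 1L)
  expect_identical(valid$label, "B")
  expect_equal(valid$start_s, 25 / 250)
  expect_equal(valid$end_s, 45 / 250)
  expect_equal((valid$end_s - valid$start_s) * 1000, 80)

  # a single label throughout a stretch leaves nothing estimable
  bf1 <- bf; bf1$labels <- rep(1L, 5)
  expect_identical(sum(segment_microstates(bf1)$segments$valid), 0L)

  # a masked gap splits the stretch and invalidates its borders
  bf2 <- list(indices = seq(10L, 120L, by = 10L),
              labels = rep(c(1L, 2L), 6), mask = rep(TRUE, 130),
              sampling_rate = 250, classes = c("A", "B"))
  base <- segment_microstates(bf2)
  gapmask <- bf2$mask; gapmask[55:75] <- FALSE
  bf2g <- bf2; bf2g$mask <- gapmask
  gap <- segment_microstates(bf2g)
  expect_lt(sum(gap$segments$valid), sum(base$segments$valid))
  # all valid segments lie strictly inside one of the two stretches
  v <- gap$segments[gap$segments$valid, ]
  expect_true(all(v$end_s < 55 / 250 | v$start_s > 75 / 250))
})

test_that("features follow the documented arithmetic and sum coverage to 100", {
  sq <- structure(list(
    segments = data.frame(class = c(1L, 2L, 1L),
                          start_s = c(0.1, 0.18, 0.22),
                          end_s = c(0.18, 0.22, 0.30),
                          valid = TRUE,
                          label = c("A", "B", "A")),
    total_usable_s = 1, classes = c("A", "B"), subject = "toy"),
    class = "ms_sequence")
  ft <- microstate_features(sq)
  expect_equal(ft$coverage_pct, c(80, 20))
  expect_equal(ft$occurrence_per_s, c(10, 5))
  expect_equal(ft$mean_duration_ms, c(80, 40))
  expect_equal(sum(ft$coverage_pct), 100)

  # a single valid segment covers everything
  sq1 <- sq; sq1$segments <- sq$segments[2, ]
  expect_equal(microstate_features(sq1)$coverage_pct, c(0, 100))

  sq0 <- sq; sq0$segments$valid <- FALSE
  expect_error(microstate_features(sq0), "no valid segments")

  # pipeline features equal brute-force counting on the fitted sequence
  for (rec in fix_prepped[1:2]) {
    bf <- backfit(rec, fix_model)
    sqr <- segment_microstates(bf, rec$subject)
    got <- microstate_features(sqr)
    oracle <- brute_features(sqr$segments, sqr$classes)
    expect_equal(got$mean_duration_ms, oracle$mean_duration_ms)
    expect_equal(got$occurrence_per_s, oracle$occurrence_per_s)
    expect_equal(got$coverage_pct, oracle$coverage_pct)
    expect_equal(sum(got$coverage_pct), 100, tolerance = 1e-6)
  }
})

test_that("features ignore what precedes the first and follows the last boundary", {
  bf <- list(indices = seq(10L, 150L, by = 10L),
             labels = c(1L, rep(c(2L, 1L, 3L), 4), 2L, 2L),
             mask = rep(TRUE, 160), sampling_rate = 250,
             classes = c("A", "B", "C"))
  base <- microstate_features(segment_microstates(bf), n_classes = 3)
  # relabel the (invalid) first and last runs
  bf2 <- bf
  bf2$labels[1] <- 3L
  bf2$labels[14:15] <- 1L
  alt <- microstate_features(segment_microstates(bf2), n_classes = 3)
  expect_equal(base, alt)
})

test_that("peak-only and every-frame fitting give identical r for identical labelings", {
  sheet <- fix_cohort$sample_sheet
  ft <- feature_table(fix_prepped, fix_model, sheet)
  # degenerate self-comparison: correlation of a feature with itself is 1
  m <- merge(ft, ft, by = c("subject", "label"), suffixes = c(".peaks", ".frames"))
  r <- cor(m$coverage_pct.peaks, m$coverage_pct.frames)
  expect_equal(r, 1)
  # and the real two-mode comparison returns finite correlations in [-1, 1]
  eq <- peak_vs_frame_equivalence(fix_prepped[1:4], fix_model, sheet)
  expect_true(all(is.finite(eq$r)))
  expect_true(all(eq$r >= -1 & eq$r <= 1 + 1e-12))
})
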