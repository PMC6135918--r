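test_that("planted templates are normalized and mutually distinct", {
  mon <- make_montage(64)
  tpl <- make_templates(mon, 5, seed = 1)
  expect_equal(nrow(tpl), 5)
  expect_equal(rowMeans(tpl), rep(0, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(map_gfp(tpl, reref = FALSE), rep(1, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  cc <- abs(microstatr:::corr_cross(tpl, tpl))
  diag(cc) <- 0
  expect_lte(max(cc), 0.7)

  two <- make_templates(mon, 2, seed = 1)
  expect_lt(abs_spatial_corr(two[1, ], two[2, ]), 0.7)
  # polarity identity: a map and its sign-flip are the same topography
  expect_equal(abs_spatial_corr(two[1, ], -two[1, ]), 1, tolerance = 1e-12)

  expect_error(make_templates(make_montage(4), 6), "too small")
})

test_that("semi-Markov sequences respect dwell laws, transitions, and seeds", {
  cfg <- simulation_config(n_per_group = 2, n_channels = 32, duration = 30,
                           seed = 5)
  s1 <- simulate_state_sequence(cfg, "control", 11)
  expect_length(s1, 30 * 250)
  expect_true(all(s1 %in% 1:5))
  # no self-transitions between consecutive dwell segments
  r <- rle(s1)
  expect_true(all(diff(r$values) != 0))
  # determinism
  expect_identical(s1, simulate_state_sequence(cfg, "control", 11))
  # a single planted class is rejected at configuration time
  expect_error(simulation_config(n_classes = 1), "at least 2")
})

test_that("planted class-C dwell difference appears in the generated sequences", {
  cfg <- simulation_config(n_per_group = 2, n_channels = 32, duration = 30,
                           seed = 5)
  dwell_of <- function(group, seeds) {
    mean(unlist(lapply(seeds, function(s) {
      r <- rle(simulate_state_sequence(cfg, group, s))
      r$lengths[r$values == 3] / cfg$sampling_rate * 1000
    })))
  }
  d_ctrl <- dwell_of("control", 1:60)
  d_pat <- dwell_of("patient", 61:120)
  expect_gt(d_ctrl, d_pat)  # planted 61 vs 53 ms
  expect_equal(d_ctrl, cfg$dwell_means$control[3], tolerance = 0.05)
  expect_equal(d_pat, cfg$dwell_means$patient[3], tolerance = 0.05)
})

test_that("rendered EEG has template topographies at GFP peaks and ~2f peak rate", {
  mon <- make_montage(32)
  tpl <- make_templates(mon, 5)
  cfg <- simulation_config(n_per_group = 1, n_channels = 32, duration = 20,
                           snr = 1e9, template_jitter = 0, n_mask_segments = 0,
                           seed = 2)
  labs <- simulate_state_sequence(cfg, "control", 3)
  r <- render_eeg(labs, tpl, cfg, subject_seed = 4, montage = mon)
  g <- compute_gfp(r$recording)
  pk <- find_gfp_peaks(g)
  maps <- gfp_peak_maps(r$recording, pk)
  cors <- vapply(seq_along(pk), function(i) {
    abs_spatial_corr(maps[i, ], tpl[labs[pk[i]], ])
  }, numeric(1))
  expect_equal(min(cors), 1, tolerance = 1e-6)
  # two GFP peaks per carrier cycle
  expect_equal(length(pk) / cfg$duration, 2 * cfg$carrier_freq,
               tolerance = 0.1)

  # peak rate survives realistic noise at the default montage density
  mon64 <- make_montage(64)
  tpl64 <- make_templates(mon64, 5)
  cfg4 <- simulation_config(n_per_group = 1, n_channels = 64, duration = 20,
                            snr = 4, n_mask_segments = 0, seed = 2)
  labs4 <- simulate_state_sequence(cfg4, "control", 3)
  r4 <- render_eeg(labs4, tpl64, cfg4, subject_seed = 4, montage = mon64)
  rate <- length(find_gfp_peaks(compute_gfp(r4$recording))) / cfg4$duration
  expect_equal(rate, 20, tolerance = 0.1)

  expect_error(simulation_config(snr = 0), "snr")
})

test_that("ground-truth features equal direct counting and a fixed seed is bit-stable", {
  for (s in c(3, 17)) {
    labs <- simulate_state_sequence(fix_cfg, "patient", s)
    ft <- sequence_features(labs, fix_cfg$sampling_rate, n_classes = 5)
    r <- rle(labs)
    for (cl in 1:5) {
      lens <- r$lengths[r$values == cl]
      expect_identical(ft$mean_duration_ms[cl],
                       mean(lens) / 250 * 1000)
      expect_identical(ft$occurrence_per_s[cl],
                       length(lens) / (length(labs) / 250))
      expect_identical(ft$coverage_pct[cl],
                       100 * sum(lens) / length(labs))
    }
    expect_equal(sum(ft$coverage_pct), 100, tolerance = 1e-9)
  }
  co2 <- simulate_cohort(fix_cfg)
  expect_identical(fix_cohort$recordings[[2]]$data, co2$recordings[[2]]$data)
  expect_identical(fix_cohort$sample_sheet, co2$sample_sheet)
  expect_identical(fix_cohort$truth, co2$truth)
})
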