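# microstatr

Resting-state EEG **microstate** analysis for two-group (case–control)
designs, from multichannel scalp recordings to class topographies,
per-subject dynamic features, and group statistics — plus a synthetic
cohort generator with planted ground truth for validating every stage.

Microstates are brief (~50–100 ms) periods during which the scalp voltage
topography stays quasi-stable. The pipeline implemented here:

1. **Signal conditioning** — zero-phase 1–40 Hz band-pass, common average
   reference, global field power `GFP(t) = sqrt(mean(v(t)^2))`, and
   topographies sampled at strict GFP local maxima within artifact-free
   stretches.
2. **Polarity-invariant clustering** — modified k-means on absolute
   spatial correlations (a map and its sign-flip are identical), template
   update = dominant eigenvector of the cluster's map outer-product sum,
   dispersion `W(k) = sum(1 - |corr|)`.
3. **Class-count selection** — Krzanowski–Lai criterion:
   `DIFF(k) = (k-1)^(2/p) W(k-1) - k^(2/p) W(k)`,
   `KL(k) = |DIFF(k)|/|DIFF(k+1)|`, maximized over k = 3..11, at the
   subject level and again at the group level, where each subject's
   templates must land on `min(k_i, k)` distinct group classes (enforced
   by optimal one-to-one assignment). Group templates are labeled by the
   canonical classes A–E.
4. **Back-fitting and dynamics** — competitive assignment by maximal
   `|corr|`, segments bounded by midpoints between neighboring GFP peaks,
   edge segments omitted; per class: mean duration (ms), occurrence (1/s),
   coverage (%).
5. **Group statistics** — pooled-SD Cohen's d (patients − controls),
   topographic permutation tests (TANOVA) with electrode-wise follow-up
   t-tests, linear mixed-effects contrasts (Wald z) for duration and
   occurrence, Dirichlet regression for compositional coverage, and the
   family-wise error threshold `0.05/(2 k*)`.

## Worked example

Simulate a small two-group cohort with five planted microstate classes and
run the full pipeline:

```r
library(microstatr)
cfg    <- simulation_config(n_per_group = 4, n_channels = 32,
                            duration = 30, seed = 7)
cohort <- simulate_cohort(cfg)
res    <- run_pipeline(cohort, out_dir = "demo_results",
                       n_restarts = 10, n_perm = 999, seed = 7)

res$group_model$k_star      # 5
res$group_model$labels      # "A" "B" "C" "D" "E"
round(res$gev, 1)           # 90.6 91.7 90.7 90.2 90.1 89.8 91.8 91.0

tab <- report_results("demo_results")
tab[tab$feature == "mean_duration_ms", ]
#           feature class       control       patient cohens_d       p
#  mean_duration_ms     A  55.11 ± 3.14  49.74 ± 7.22    -0.96 0.38385
#  mean_duration_ms     B 56.14 ± 11.86 52.51 ± 10.18    -0.33 0.55878
#  mean_duration_ms     C 60.20 ± 11.48  59.45 ± 4.39    -0.09 0.91024
#  mean_duration_ms     D 66.44 ± 13.20 71.07 ± 13.39     0.35 0.44084
#  mean_duration_ms     E 65.10 ± 12.54  47.42 ± 6.54    -1.77 0.00384

fwer_threshold(res$group_model$k_star)
# $cutoff 0.005   $n_effects 15
```

The Krzanowski–Lai criterion recovers the five planted classes; the
canonical labeling maps them to A–E; `gev` is the percentage of
GFP-weighted topographic variance each subject's peak maps share with the
fitted templates. The report table shows, per class, group mean ± SD of
each dynamic feature, the pooled-SD effect size, and the regression
p-value (mixed model for duration/occurrence, Dirichlet regression for
coverage). With only 4 subjects per group the effect sizes are noisy —
the defaults of `simulation_config()` are the full study conditions
(32 per group, 300 s, 64 channels).

A thin command-line wrapper with `simulate`, `run`, and `report`
subcommands is installed at `inst/cli/microstatr.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/microstatr.R", package = "microstatr"))')" \
  simulate --out cohort_dir --seed 7
```

## Package layout

- `R/` — synthetic generator (`simulation_config`, `simulate_cohort`,
  `render_eeg`), signal preparation (`bandpass_and_reref`, `compute_gfp`,
  `find_gfp_peaks`), clustering (`modified_kmeans`,
  `krzanowski_lai_select`, `cluster_subject`, `cluster_group`,
  `canonical_labeling`, `global_explained_variance`), dynamics
  (`backfit`, `segment_microstates`, `microstate_features`),
  statistics (`cohens_d`, `tanova`, `electrodewise_t`, `lmm_contrasts`,
  `dirichlet_regression`, `fwer_threshold`), and I/O (delimited
  recordings and montages, JSON models and manifests).
- `vignettes/microstate-analysis.Rmd` — the methods vignette: model,
  generator design and its limits, numerical choices.
- `tests/testthat/` — unit, property, and acceptance suites; all fixtures
  are generated in code.
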