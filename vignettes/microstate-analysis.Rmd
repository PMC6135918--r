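---
title: "Resting-state EEG microstate analysis with microstatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG microstate analysis with microstatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

EEG microstates are brief (roughly 50–100 ms) periods during which the
scalp voltage topography stays quasi-stable before switching abruptly to a
different configuration. `microstatr` implements the standard two-level
analysis of eyes-closed resting-state recordings for a two-group
case–control design:

1. **Conditioning.** Each cleaned recording is band-pass filtered (default
   1–40 Hz) with a zero-phase 4th-order Butterworth filter and
   re-referenced to the common average of the scalp channels. Global field
   power (GFP) is the spatial standard deviation of the average-referenced
   map, `sqrt(mean(v^2))` with the population divisor. Topographies are
   sampled at the strict local maxima of GFP, where the topographic
   signal-to-noise ratio is highest.
2. **Subject-level clustering.** The unit-GFP peak maps are clustered by a
   polarity-invariant ("modified") k-means: a map is assigned to the
   template with the largest absolute spatial correlation, and each
   template is updated as the dominant eigenvector of the outer-product
   sum of its assigned maps — the polarity-invariant centroid. The number
   of clusters is chosen per subject by the Krzanowski–Lai criterion on
   the dispersion curve `W(k) = sum(1 - |corr|)`, with
   `DIFF(k) = (k-1)^(2/p) W(k-1) - k^(2/p) W(k)` and
   `KL(k) = |DIFF(k)| / |DIFF(k+1)|` maximized over candidates 3–11
   (`W` is therefore computed for k = 2–12). The dimensionality `p` is the
   number of scalp channels.
3. **Group-level clustering.** All subjects' templates are pooled and
   clustered with the same algorithm under one constraint: a subject's
   templates must occupy `min(k_i, k)` distinct group classes. At every
   assignment step this is enforced exactly by solving, per subject, the
   optimal one-to-one assignment (Hungarian algorithm via
   `clue::solve_LSAP`) maximizing total `|corr|`. The group class count is
   again selected by the Krzanowski–Lai criterion, and group templates are
   matched one-to-one to schematic renderings of the canonical classes
   A–E for labeling.
4. **Back-fitting and dynamics.** Group templates are fitted back to each
   recording competitively (argmax `|corr|`, ties to the lowest class
   index), by default at the GFP peaks. Runs of equal labels merge into
   one microstate whose boundaries are the midpoints, in continuous time,
   between the neighboring peaks of adjacent runs. Microstates whose start
   or end cannot be estimated — the first and last run of every usable
   stretch, and runs bordering artifact-masked gaps — are excluded. Three
   features per class and subject follow: mean duration (ms), frequency of
   occurrence (1/s), and proportional coverage time (%).
5. **Statistics.** Group contrasts are expressed as pooled-SD Cohen's d
   (patients minus controls). Topographies are compared per class by
   TANOVA: subject mean maps are normalized to unit GFP, the statistic is
   the GFP of the difference of the group-mean maps, and the p-value comes
   from permuting group labels. Mean duration and occurrence are modeled
   as `feature ~ class * group + age + sex + (1 | subject)` by maximum
   likelihood (lme4) with Wald z tests for the per-class group contrast;
   coverage, being compositional, is modeled by Dirichlet regression.
   Because coverage is deducible from duration and occurrence, the
   family-wise error threshold is `0.05 / (2 k*)`.

# The synthetic cohort generator

No recordings are distributed with the underlying study design, so the
package ships a generator whose defaults define the validation conditions:
250 Hz sampling, 1–40 Hz band, 64-channel scalp montage (204 supported) on
a unit sphere, five planted classes rendered as two mirror-image diagonal
gradients, a fronto-occipital pattern, a frontal-central pattern, and a
centro-parietal pattern, pairwise `|corr| <= 0.7`.

State dynamics are semi-Markov: dwell times are gamma with shape 2 (a
positive, right-skewed law whose mean ± SD magnitudes match reported
feature tables; the literature does not pin a distribution) and per-class
means of 50–65 ms; the next class is drawn from occurrence weights with
self-transitions excluded. Two planted group differences mirror the
case–control contrast: class C dwells average 61 ms in controls versus
53 ms in patients, and class D carries a 25% higher transition weight in
patients. Each subject additionally draws mean-one lognormal factors for
its per-class dwell means (CV 0.2) and occurrence weights (CV 0.3); these
coefficients of variation were set from the between-subject spread of
published group feature tables (duration CVs roughly 0.15–0.28, occurrence
0.12–0.42) and are essential — with identical within-group parameters the
cohort would be unrealistically homogeneous and cross-subject correlations
of any estimator pair would be meaningless.

The signal model multiplies the (per-subject jittered, renormalized) class
template by a rectified 10 Hz carrier with a 20% amplitude floor,
`0.2 + 0.8 |sin(2 pi f t + phi)|`, flipping the template's sign randomly
per dwell segment so that downstream code must be polarity invariant. GFP
peaks therefore arrive at about twice the carrier frequency. The floor
reflects that real eyes-closed EEG retains broadband topographic signal
between alpha-band GFP maxima; with a floor of zero every inter-peak
trough is pure noise. Raising the floor much beyond 0.2 inflates the GFP
peak rate beyond the 2-per-cycle regime at the default signal-to-noise
ratio, so 0.2 is the final choice. Noise is Gaussian, spatially correlated
by smoothing over the electrode neighborhood graph (Gaussian kernel,
length scale = median nearest-neighbor distance), band-limited to 1–40 Hz,
and scaled so that the ratio of state-signal RMS GFP to noise RMS GFP
equals `snr` (default 4). Artifact masks (default two 2-s gaps) exercise
the edge-omission rules.

**What the generator does not emulate.** Cortical forward modeling, 1/f
background spectra, non-stationary vigilance drifts, eye movements, or any
artifact beyond masked gaps. Passing tests on synthetic cohorts show that
the pipeline recovers planted structure under this stand-in model; they do
not certify performance on real recordings.

One consequence is documented as a known limitation rather than patched:
at snr 4 the per-frame (as opposed to per-peak) label accuracy saturates
near 0.9 because the inter-peak troughs are noisier than in real data, so
every-timeframe back-fitting fragments sequences and its mean-duration and
occurrence estimates correlate with the peak-only estimates at roughly
0.8–0.9 across subjects rather than the near-unity agreement reported on
real recordings (coverage does agree at about 0.99). Reproducing the
near-unity agreement would have required inflating the between-subject
heterogeneity beyond the published magnitudes, which we declined to do;
the corresponding acceptance check is expected to fail on the duration and
occurrence components and the failure is informative about the generator,
not the back-fitting code.

# Numerical and design choices

- **Filter realization.** Only the band is prescribed by convention;
  zero-phase forward–backward filtering preserves GFP peak latencies.
  Channel means are removed before filtering (the high-pass removes DC
  anyway; centering avoids forward–backward edge transients).
- **Peak definition.** Strict local maxima with both immediate neighbors
  usable; a flat maximum contributes its first sample (deterministic,
  order-independent). No peaks at usable-run boundaries.
- **Template update and dispersion.** The dominant-eigenvector update is
  the standard polarity-invariant centroid and maximizes the sum of
  squared correlations; the dispersion driving model selection is
  `sum(1 - |corr|)`. These two are not the same objective, so a plain
  iteration can occasionally raise the dispersion. Each k-means run
  therefore tracks the best-visited assignment (the incumbent) and returns
  it; the reported per-iteration dispersion trace is the incumbent value
  and never increases. A squared-distance dispersion variant was
  considered and rejected to keep a single declared definition.
- **Eigenvector computation.** Warm-started power iteration (4 steps
  during the alternation, full convergence for the returned solution)
  rather than a dense eigendecomposition per cluster per iteration;
  results agree with `eigen()` to ~1e-6 in the dispersion.
- **Restarts and seeds.** 20 random restarts by default, best by minimal
  dispersion; all restart seeds derive from the master seed by fixed
  arithmetic, so every result is bit-reproducible.
- **Empty clusters** are reseeded from the currently worst-fit map.
- **Subjects with more templates than group classes** keep the constraint
  in its `min(k_i, k)` form: a transposed assignment guarantees every
  class receives one template and the surplus is assigned freely.
- **Occurrence/coverage denominator.** Total valid-segment time (keeps the
  three features mutually consistent and coverage summing to 100%);
  switchable to raw usable time (`denominator = "usable"`).
- **Boundaries** are midpoints in continuous time (samples/rate), not
  rounded to sample indices.
- **TANOVA.** Subject maps are unit-GFP normalized before averaging (maps
  are sign-aligned to the class template first, since polarity is
  arbitrary); default 4999 permutations; rows are put in a canonical order
  within groups before permuting so that p is exactly invariant to how
  subjects are listed. `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
- **Dirichlet regression.** Common parameterization
  `alpha_jc = exp(x_j' beta_c)`, maximum likelihood by BFGS with the
  analytic gradient, Wald z from the inverse observed information;
  boundary zeros are nudged by 1e-6 and renormalized because the density
  is undefined on the simplex boundary. A mean/precision parameterization
  is out of scope.
- **Mixed models** are fitted by ML (not REML) so that Wald z tests match
  the declared inference; a REML flag exists but is not the default.
  Singular fits are flagged on the result, never silently absorbed.
- **FWER threshold.** The printed form "0.05(2k*)" is implemented as
  division, `0.05 / (2 k*)`, which the worked value 0.05/10 = 0.005 fixes
  unambiguously.

# Problem sizes used by the tests and the acceptance script

The validation suite scales the study design down to run comfortably on a
single CPU: shared fixtures use six 30-s, 32-channel subjects; the
cluster-count selection study uses ten replicate cohorts of six subjects;
the equivalence and feature-recovery studies use 16–20 subjects at 45–60 s;
null calibrations simulate feature tables and subject mean maps directly
(300–400 replicates) rather than rendering EEG. The acceptance script runs
ten replicate cohorts of 16 subjects (64 channels, 60 s, snr 4) through
the full subject- and group-level clustering with 10 restarts per
candidate count and reports the majority selected group class count.
These sizes are the package's own validation design; the defaults users
see (`simulation_config()`) remain the full study conditions (32 subjects
per group, 300 s).

# Known limitations

- The Krzanowski–Lai criterion is undefined when successive dispersion
  differences vanish exactly (e.g., a perfect fit at every candidate);
  such candidates are excluded and an all-excluded curve is an error.
- Electrode-wise follow-up t-tests are computed on normalized absolute
  voltages with a pooled-variance statistic and are reported without a
  spatial multiplicity correction, as in the underlying design.
- The canonical A–E reference maps are schematic gradients and blobs, not
  empirical grand averages; labeling of real data should be reviewed.
- `lmm_contrasts` requires complete age/sex covariates and at least two
  classes (a single class falls back to ordinary least squares).
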