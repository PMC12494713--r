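---
title: "Temporal drift of resting-state connectivity patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal drift of resting-state connectivity patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restdrift)
```

## The question and the statistic

Dense-sampling resting-state fMRI studies scan the same person every day for
weeks. If a brain region's spontaneous activity carries a slowly changing
temporal context signal, then its *pattern* of functional connectivity with
the rest of the brain should become progressively less similar as more time
elapses between two scans — representational drift measured at the scale of
whole-brain connectivity.

`restdrift` quantifies this with the **temporal drift score**. For a seed
region (e.g. entorhinal cortex or hippocampus):

1. Per session $s$, the seed series is the unweighted mean BOLD series over
   the seed voxels; the connectivity map is the Pearson correlation of that
   series with every gray-matter voxel, Fisher-Z transformed
   ($z = \operatorname{arctanh} r$, clipped at $\pm(1-10^{-7})$).
2. For every unordered session pair $(i, j)$, pattern similarity is the
   Pearson correlation of the two maps over target voxels, Fisher-Z
   transformed, giving $z_{ij}$, with elapsed time
   $\Delta t_{ij} = |t_j - t_i|$ in days.
3. Pairs whose $z_{ij}$ deviates more than 3 SD from the mean over all pairs
   (computed once, no re-iteration) are excluded.
4. The drift score is $r = \operatorname{cor}(z_{ij}, \Delta t_{ij})$ over
   included pairs. Negative $r$ means patterns decorrelate with time.

Inference is two-fold: the parametric two-tailed $t$ test of a Pearson
correlation with $n-2$ df, and a one-tailed permutation test that shuffles
the $\Delta t$ labels across included pairs (default 5000 shuffles) and
counts how often the null scores are at least as negative as the observed
one, with add-one smoothing: $p = (1 + \#\{r^{*} \le r\})/(1 + n_{perm})$.
The lower tail encodes the a priori direction (drift, not convergence); the
add-one rule keeps $p$ strictly in $(0, 1]$ so a score below every null
draw reports $p < 1/n_{perm}$, never 0.

Downstream of this core statistic the package provides: a voxel-wise variant
with single-voxel seeds and a permutation test of the correlation between
voxel drift scores and the anterior–posterior (y) coordinate (the
hippocampal longitudinal-axis gradient); averaging of voxel-wise scores
within entorhinal subregions; Meng–Rosenthal–Rubin tests of the difference
between two seeds' drift scores (dependent, overlapping correlations);
multiple regression of $z_{ij}$ on $\Delta t$ plus per-pair covariate
deltas; network-restricted drift over a 17-network parcellation with
Benjamini–Hochberg adjustment; and a permutation Kruskal–Wallis test of
drift-score heterogeneity across networks.

## Session designs

Two schedules are built in, mirroring the two dense-sampling designs the
pipeline targets: `female30` (one scan per day, days 0–29; 435 session
pairs) and `male40` (40 scans over 30 days: mornings on days 1–10, morning
and evening on days 11–20, evenings on days 21–30; 780 pairs). Same-day
morning/evening scans are 13 hours apart and are coded as a fractional day
(13/24); the drift score is invariant to any common linear rescaling of
$\Delta t$, so the unit choice is immaterial.

## The phantom generator

Every stage is validated on synthetic multi-session data with known ground
truth (`phantom_layout()`, `generator_params()`, `simulate_sessions()`).
The phantom is a coordinate table, not a brain: seed ROIs (alEC, pmEC, a
12-voxel hippocampal strip spanning 22 mm of the y axis, and control ROIs
M1 and PRC) plus 306 gray-matter target voxels partitioned into 17 named
networks. Rendering to NIfTI (`write_phantom()`, `load_session()`) is a
thin serialization layer.

The generative model per latent seed unit (each ROI, and each hippocampal
voxel separately):

* a latent signal $u(t)$ per session — white noise band-limited to
  0.01–0.35 Hz; within a session all units' signals are orthonormalized, so
  cross-talk between units does not contaminate the maps;
* a latent weight vector $w_s$ over the target voxels; a target voxel emits
  $\sum_u w_s^{(u)}(v)\,u(t) + \sigma\,\varepsilon(t)$, so the empirical
  map estimates $w_s$ up to scale;
* **time drift**: $w$ evolves as a Euclidean random walk with step
  $\delta\sqrt{\Delta t}$ per transition, making expected similarity decay
  monotonically in elapsed time for every pair;
* **longitudinal gradient**: hippocampal voxel $v$ drifts at
  $\delta(v) = \delta\,(1 + \text{slope}\,(y_v - \bar y))$; positive slope
  = faster drift anteriorly, reproducing a negative drift-score-vs-y
  correlation under the RAS (anterior-positive) convention. All
  $\delta(v)$ must stay non-negative;
* **covariate channels**: hormone, motion and emotion series couple into
  the weights as independent *spherical* (norm-preserving) random walks
  indexed by the sorted covariate value, mixed with amplitude $\beta_k$ and
  normalized. A spherical walk makes the expected inner product between two
  positions a pure function of the accumulated steps between them, so
  expected similarity declines (approximately linearly) in
  $|\Delta \text{covariate}|$ with no dependence on covariate *levels* —
  exactly the structure the linear confound regression assumes. Additive or
  Euclidean covariate couplings fail this: they generate quadratic and
  level-dependent similarity terms that a linear control cannot absorb and
  that masquerade as spurious time effects.

Covariates themselves: four hormone series are phase-shifted sinusoids
(default period 28 days, random study-start phase) plus noise; mean
framewise displacement is log-normal around 0.12 mm; four questionnaire
scores load 0.9 each on one smooth latent emotion factor, so the
emotion PCA stage has a recoverable one-factor structure.

## Parameter defaults and why

| parameter | default | meaning |
|---|---|---|
| `n_timepoints` | 200 | timepoints per session (TR 0.72 s, ~2.4 min) |
| `tr_s` | 0.72 s | repetition time |
| `delta` | 0.315 | per-day drift step; calibrated once so the female30 population drift score is ≈ −0.2, the magnitude reported for medial-temporal seeds |
| `gradient_slope` | 0 | per-mm relative change of δ along y; 0.04 is used as the standard effect size in the gradient analyses (δ varies ~2.5× across the strip) |
| `beta_h, beta_m, beta_e` | 0 | covariate coupling amplitudes; the confound analyses use β_h = 1 |
| `sigma` | 4 | observation noise; sets the weak-map regime (below) |
| `latent_band` | 0.01–0.35 Hz | latent signal passband |

**Why the weak-map regime.** Session pairs share sessions, so pair
similarities are not independent: any session-level noise component (the
interaction between a session's map noise and the shared signal pattern)
adds variance to the drift score that the pair-level label shuffle cannot
reproduce, making the permutation test anticonservative. Diagnostic
simulations showed this inflation grows with the mean similarity level and
essentially vanishes when per-voxel map SNR is low. The default `sigma = 4`
therefore puts the phantom in a weak-map regime (mean pair similarity
$z \approx 0.04$) where the permutation null is calibrated (rejection rate
≈ 0.06 at $\alpha = 0.05$ over 200 replicates). This is a deliberate
realism tradeoff: real data show far higher similarity levels, and there
the label-shuffle test inherits exactly this caveat — pair non-independence
is *not* corrected beyond the shuffle scheme, faithfully reproducing the
method as practiced. The confound-regression analyses, which do not rely on
the permutation null, use a larger phantom (1003 targets, `sigma = 1.5`):
the pattern-similarity noise floor scales as $1/\sqrt{V}$, so more target
voxels let a hormone coupling of realistic strength become clearly
detectable while the similarity level stays low enough for the classical
regression t statistics to remain near-calibrated. Even so, the time term's
t statistic retains mild residual inflation from the shared-session
dependence of pairs — the same caveat the permutation null carries.

The drift statistic itself is scale-free (a correlation), so recovery power
is preserved in the weak regime: at the calibrated δ the permutation test
detects the drift in ≥ 95% of replicates, and the mean recovered score
matches a pooled 10,000-pair Monte-Carlo estimate of the population value
to well within ±0.05.

## Preprocessing

Two computations are implemented, applied in this order: ordinary
least-squares nuisance regression (six motion parameters plus mean CSF and
WM signals; a constant and linear trend are always included, since
detrending is required for a stable frequency-domain filter) and an ideal
FFT band-pass (default 0.01–0.1 Hz: bins with $f_{lo} < f < f_{hi}$
retained, everything else — including DC — zeroed). The ideal mask keeps
the passband analytically testable; no IIR option is provided. Residuals
are orthogonal to every regressor to 1e−8 and the regression is idempotent;
the filter is linear.

## Numerical and design choices

* **Fisher-Z clipping** at $\pm(1 - 10^{-7})$ maps $r = \pm 1$ (e.g. a
  target voxel identical to the seed) to a large finite value (~8.41)
  instead of infinity.
* **Zero-variance targets** get $z = 0$ with a warning rather than being
  dropped, keeping the target dimension constant across sessions as pattern
  similarity requires. A zero-variance *seed* is an error.
* **Targets include seed voxels** when the default (all gray-matter) target
  set is used; the phantom's seeds are disjoint from its gray-matter
  targets, so the question does not arise there.
* **Outlier exclusion before shuffling**: the 3-SD rule runs once per seed
  (per voxel-seed in the voxel-wise variant), and permutations shuffle
  labels over the included pairs only.
* **Gradient test tail**: fixed lower tail by default, mirroring the a
  priori directional hypothesis exactly as in the drift-score test. An
  observed-direction tail (`tail = "auto"`) is available but doubles the
  false-positive rate under the null, pushing it past the 9% bound the
  recovery analyses use.
* **Dependent-correlation test**: the overlapping-variables variant (both
  drift scores share $\Delta t$), with $r_{kh}$ computed on the
  intersection of the two seeds' included pairs.
* **Covariate deltas are absolute differences**, matching the
  non-directional similarity outcome.
* **Kruskal–Wallis unit and coupling**: observations are per-subject
  per-network drift scores (networks are groups); each permutation draws
  one time-label shuffle per subject and reuses it across that subject's 17
  networks, preserving the cross-network dependence induced by shared
  pairs. H uses the tie-corrected rank formula (via `stats::kruskal.test`),
  with H = 0, p = 1 when all observations tie.
* **BH adjustment** is applied within each subject × seed family of 17
  network p-values.
* **Male same-day pairs** are included in drift scores with
  $\Delta t = 13/24$ day; a custom schedule can encode any other choice.

## Problem sizes used in validation

The test suite and the acceptance script run the generator at the phantom
scale: 306 target voxels, 200 timepoints per session, 30 (or 40) sessions.
Null calibration uses 200 replicates × 500 shuffles; drift recovery 100
replicates plus a 24-replicate (10,440-pair) pooled oracle; gradient
recovery 100 effect and 200 null replicates; confound separation 100
replicates on the larger (1003-target) phantom. Oracle-equivalence checks (drift score vs. the covariance
formula, permutation p vs. full enumeration at 5 pairs, BH vs. a step-up
oracle, Kruskal–Wallis H vs. the rank formula, the Meng z vs. an
independently coded formula, OLS vs. normal equations, arctanh values) are
exact or at 1e−8.

## What passing these tests does and does not show

The phantom embodies the statistical structure the analysis assumes —
monotone similarity decay, a linear drift-rate gradient, separable
covariate channels, Gaussian observation noise, no spatial autocorrelation,
no hemodynamics, no motion artifacts, and similarity levels far below real
data. Passing the recovery and calibration suites shows the *pipeline*
computes its statistics correctly and detects the structures it claims to
detect at realistic effect sizes; it does not show that real resting-state
data satisfy those assumptions, nor does it reproduce any real-subject
value. Running the pipeline on real dense-sampling acquisitions
(per-session 4D NIfTI + labels + metadata TSV via `load_session()`) is
supported but requires the data.

## Known limitations

* The permutation null treats pairs as exchangeable; with strongly shared
  session noise (high-similarity regimes, as in real data) it is mildly
  anticonservative. A dyadic-dependence-aware null (e.g. session-label
  permutation) would be a methodological change and is intentionally not
  substituted.
* The 3-SD rule is a single hard threshold; no robust-similarity variant.
* The generator's linear-gradient and single-factor-emotion structures are
  idealizations chosen for recoverability, not biological claims.
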