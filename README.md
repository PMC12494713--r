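# restdrift

Temporal drift of seed-based resting-state functional connectivity patterns
across densely sampled fMRI sessions.

## The problem

When one person is scanned at rest every day for a month, does the
whole-brain connectivity pattern of a region slowly reorganize with the
passage of time? Regions that carry a temporal-context signal — entorhinal
cortex and hippocampus in particular — should show *representational
drift*: their seed-to-whole-brain connectivity patterns should become
progressively less similar the more time separates two sessions, beyond
what head motion, hormones, or mood changes explain.

`restdrift` is an analysis pipeline for exactly this design, aimed at
researchers working with dense-sampling ("precision imaging") resting-state
data. Its core statistic is the **temporal drift score**: for a seed
region, compute the Fisher-Z connectivity map per session
(z = arctanh of the seed-to-voxel Pearson correlation), correlate maps
between every pair of sessions (Fisher-Z pattern similarity `z_ij`),
exclude pairs more than 3 SD from the mean similarity, and take

    drift score r = cor(z_ij, delta_t_ij)      over included pairs,

with `delta_t` the elapsed time in days. Negative r = drift. Significance
comes from the parametric two-tailed t test and from a one-tailed
permutation null (time-interval labels shuffled across pairs, default
n = 5000, add-one counting, lower tail).

Around that core the package implements: voxel-wise drift maps and the
hippocampal longitudinal-axis gradient test (drift score vs. y coordinate,
y-shuffle permutation null); entorhinal subregion averaging;
Meng–Rosenthal–Rubin dependent-correlation comparisons between seeds;
confound-controlled multiple regression of pair similarity on elapsed time
plus hormone/motion/emotion deltas (with a PCA-derived emotion factor);
network-restricted drift over a 17-network parcellation with
Benjamini–Hochberg FDR; a permutation Kruskal–Wallis test across networks;
nuisance regression and 0.01–0.1 Hz FFT band-pass preprocessing; NIfTI/TSV
I/O; and a multi-session phantom generator with known ground-truth drift
rates, a drift-rate gradient, and covariate couplings, so the entire
pipeline is testable without any data download.

## Worked example

Thirty daily sessions of a phantom subject whose hippocampal drift rate
increases toward the anterior pole (`gradient_slope = 0.04` per mm):

```r
library(restdrift)
schedule <- make_schedule("female30")
layout   <- phantom_layout()
params   <- generator_params(gradient_slope = 0.04)
sim <- simulate_sessions(schedule, layout, params, seed = 101)

ec <- seed_spec("ec", voxel_id = layout$voxel_id[layout$label %in% c("ec_al", "ec_pm")])
da <- drift_analysis(sim$sessions, schedule, ec, n_shuffles = 5000, seed = 7)
da$result
#> Temporal drift score: r = -0.207 (n = 435 pairs)
#>   parametric two-tailed p = 1.408e-05
#>   permutation one-tailed p = 0.0002 (5000 shuffles)

vm <- voxelwise_drift(sim$sessions, schedule, seed_label = "hpc")
gradient_test(vm, n_perm = 5000, seed = 8)
#> Longitudinal gradient: r = -0.922 over 12 voxels, one-tailed permutation p = 0.0002 (5000 shuffles)
subregion_mean(vm)
#>   subregion mean_drift
#> 1      ahpc -0.2736357
#> 2      phpc -0.1185048
```

Reading: the entorhinal pattern decorrelates with elapsed time at the
generator's calibrated population magnitude (r ≈ −0.2, below every
permutation draw, so p sits at the 1/5001 floor), and voxel-wise drift is
markedly stronger in anterior than posterior hippocampus, giving a strongly
negative drift-score-vs-y correlation — the encoded longitudinal gradient,
recovered.

The full workflow lives in `analysis/` as numbered drivers writing tables
under `results/`:

```sh
Rscript analysis/01_simulate.R      # phantom subjects + NIfTI round-trip demo
Rscript analysis/02_drift_scores.R  # seed-level drift scores, both subjects
Rscript analysis/03_gradient.R      # voxelwise drift, gradient test, subregions
Rscript analysis/04_controls.R      # seed-vs-control tests, confound regression
Rscript analysis/05_networks.R      # 17-network drift, FDR, Kruskal-Wallis
```

The methods vignette (`vignettes/temporal-drift-methods.Rmd`) documents the
model, the generator, parameter defaults and their calibration, and the
statistical caveats (notably pair non-independence and the permutation
null).

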