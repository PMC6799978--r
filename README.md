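# hypoquant

Quantification of anti-correlated hypothalamic activity across hunger
states in larval zebrafish.

During food deprivation the caudal hypothalamus (cH) of the larval
zebrafish is tonically active while the lateral hypothalamus (lLH/mLH) is
quiet; when prey appears the relationship inverts within seconds. This
package implements, as tested R functions, the quantification pipeline used
to measure that opposition across three kinds of raw data:

* **stained brains** — pERK/tERK immunofluorescence stacks: ROI mean
  intensity with control normalization, adaptive-threshold active-cell
  counting, prey-type activity-change ratios, and voxelized
  independent-component activity maps;
* **calcium imaging** — Δf/f computation, quadratic detrending, calcium
  spike detection, per-epoch spike metrics, spike-triggered averages,
  movie downsampling into cell-sized voxels, zero-lag cross-correlograms,
  and an anti-correlation rank-enrichment statistic;
* **behavior and perturbations** — 220-dimensional posture featurization of
  swim bouts, binned hunting-bout probabilities with exact binomial
  intervals and per-bin Fisher tests, gut-fluorescence food intake, and
  pre/post window metrics for optogenetic stimulation with paired
  Wilcoxon signed-rank statistics.

A synthetic-data module (`latent_model()`, `generate_traces()`,
`generate_movie()`, `generate_stack()`, `generate_bout_stream()`,
`generate_opto_session()`, `generate_gut_image()`) generates every input
with ground truth attached, so each stage is validated end to end.

## The statistics at the core

* **Δf/f**: `(F − F0)/F0`, with `F0` either a declared pre-stimulus epoch
  mean or a running 10th percentile; slow drift is removed by subtracting a
  least-squares quadratic.
* **Spike detection**: local maxima whose prominence over a
  flanking-window median exceeds `k · σ̂`, where `σ̂` is the MAD of first
  differences divided by √2.
* **Spike-triggered average**: mean ± SEM of target segments aligned at
  trigger times, each baseline-subtracted by its own pre-window mean.
* **Cross-correlogram**: zero-lag Pearson correlations between
  cell-sized-voxel traces, ordered by region.
* **Rank enrichment**: for each voxel, the region of its n-th most
  anti-correlated partner, tabulated as `P(region | rank n)` and divided by
  that region's occupancy fraction (chance).
* **θ_A/θ_P**: artemia- vs paramecia-induced activity change, each a
  difference of group means against an unfed control.
* **ICA maps**: per-fish brightness normalization (divide by the 10th
  percentile), voxelwise mean subtraction, PCA to 30 components, symmetric
  FastICA with the cubic (`pow3`) nonlinearity, maps reported as z-scores.
* **Binned behavior**: hunting-bout probability per 3-min bin with
  two-sided 90 % Clopper–Pearson intervals and per-bin two-sided Fisher
  exact tests.
* **Paired stimulation statistics**: Wilcoxon signed-rank on per-pulse
  pre/post window metrics, exact (tie-aware dynamic programming) for
  n ≤ 25 pairs, normal approximation with tie and continuity correction
  above.

## Worked example

```r
library(hypoquant)

# Two hypothalamic populations with anti-correlated latent drive
model <- latent_model(n_regions = 2, seed = 11)   # latent corr -0.8
sim <- generate_traces(model, duration_s = 600, fps = 2)
cor(sim$truth$latent_traces)[1, 2]
#> [1] -0.8470226

# A sparse-spiking lLH on a tonically active cH: dff -> detrend -> spikes
spikes_model <- latent_model(rate_hz = c(2, 0.05), amp_mean = 30, amp_sd = 0,
                             noise_sd = 2, kernel_tau = 3, seed = 7)
fish <- generate_traces(spikes_model, duration_s = 3600, fps = 2)
tsf <- detrend_quadratic(compute_dff(fish$traces))
spk <- detect_spikes(tsf$dff[, "lLH"], tsf$fps, roi = "lLH")
nrow(spk)
#> [1] 169

tsf$epochs <- list(baseline = c(0, 300))
epoch_metrics(tsf, spk, "baseline")
#> # A tibble: 1 × 6
#>   epoch    roi   sum_dff  freq   amp n_spikes
#>   <chr>    <chr>   <dbl> <dbl> <dbl>    <int>
#> 1 baseline lLH      7.14   3.4 0.318       17

sta <- spike_triggered_average(spk, tsf$dff[, "cH"], tsf$fps)
round(min(sta$mean[sta$lag >= 0]), 3)
#> [1] -0.271
```

The lLH fires ~3.4 calcium spikes/min during the food-deprived baseline,
and the cH trace dips by ~0.27 Δf/f around those spikes — the
cross-regional signature the pipeline is built to measure. The same
structure is visible at the voxel level:

```r
corr3 <- matrix(c(1, -0.55, -0.8, -0.55, 1, 0.6, -0.8, 0.6, 1), 3,
                byrow = TRUE)
mv <- generate_movie(latent_model(n_regions = 3, latent_corr = corr3,
                                  seed = 33), 600, 2, ny = 12, nx = 72)
vox <- downsample_movie(mv$movie, cell_size_px = 6, mv$region_map)
cm <- crosscorrelogram(apply(vox$traces, 2, detrend_quadratic),
                       vox$labels, vox$coords)
rs <- anticorr_rank_stat(cm, max_rank = 3)
subset(rs, source == "cH" & rank == 1)
#> # A tibble: 3 × 6
#>   source target  rank  prob chance ratio
#>   <chr>  <chr>  <int> <dbl>  <dbl> <dbl>
#> 1 cH     cH         1     0  0.304  0
#> 2 cH     mLH        1     0  0.348  0
#> 3 cH     lLH        1     1  0.348  2.88
```

Every cH voxel's most anti-correlated partner lies in the lLH, at 2.9×
the chance fraction. `autoplot(cm)`, `autoplot(rs)`, `autoplot(sta)` and
`plot_traces()` draw the corresponding figures.

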