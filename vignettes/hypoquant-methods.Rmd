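---
title: "Methods: quantifying opposing hypothalamic activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying opposing hypothalamic activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoquant)
```

## The measurement problem

In larval zebrafish, the caudal hypothalamus (cH) and the medial and
lateral lobes of the lateral hypothalamus (mLH, lLH) show opposing
activity across hunger states: the cH is tonically active during food
deprivation and falls silent within seconds of prey presentation, while
the LH lobes activate. The state of this push–pull network is read out
through several independent measurement channels — pERK immunostaining of
fixed brains (a minutes-timescale activity proxy), GCaMP calcium imaging
in tethered fish, optogenetic perturbation, high-speed behavioral
tracking, and gut fluorescence of ingested labeled prey. This package
implements the quantification for each channel as composable functions,
plus a synthetic-data module that generates every input *with ground
truth*, so that each procedure can be validated end to end without any
animal data.

## Synthetic study conditions

`latent_model()` describes correlated populations: each region carries a
stationary unit-variance AR(1) latent state with timescale
`latent_tau_s`, cross-correlated according to `latent_corr`; the
instantaneous event rate is `rate_hz * 2 * pnorm(gain * z)` (mean
`rate_hz`); events convolve with a single-exponential calcium kernel
(`kernel_tau`) and acquire baseline, a quadratic drift polynomial and
additive Gaussian noise.

Defaults are fixed once, as the conditions a practitioner would call
realistic for this system, and are not adjusted per analysis:

* `latent_tau_s = 10` s and `gain = 2.5` — hunger-state modulation is slow
  relative to single transients, and strong enough that rates swing over
  most of their range, which is what figures of this system show
  qualitatively. Both are free parameters of the simulation: magnitudes of
  the real transients are not published as numbers anywhere, so no claim
  of calibration to the study is made.
* `rate_hz = 4`, `kernel_tau = 4` s for *voxel-level* (population/neuropil)
  movie signals; ROI-level spike analyses instead use a sparse
  condition — `rate_hz ≈ 0.05` (3 events/min), amplitude 6× the Δf/f noise
  scale — matching the spikes-per-minute regime the per-epoch metrics
  operate in.
* Calcium kernel: single exponential decay. This matches GCaMP6s
  phenomenology well enough to exercise detection; it is not a
  biophysical model.
* Noise: additive Gaussian, not mixed Poisson–Gaussian, because every
  detection threshold downstream is variance-based.
* All random streams derive from one user seed through named substreams,
  so adding a generator never perturbs another one's stream, and identical
  seeds reproduce outputs bit for bit.

Stained stacks are background plus Gaussian blobs whose width combines
the cell radius and point-spread blur in quadrature (support truncated at
6σ, so each blob's discrete mass matches the analytic
`amp·(2π)^{3/2}·σzσyσx` to ~1e−9). Cell centers keep a minimum separation
of 5σ so planted cells are resolvable — the generator emulates the *sparse,
well-separated* staining regime in which the counting procedure is
documented to be valid. Bout streams are homogeneous Poisson in time with
Bernoulli hunting labels at `p_hunt(t)` and label-conditioned 220-dim
posture vectors. Optogenetic sessions multiply event rates by a per-region
factor inside the post-stimulus window of each pulse.

What the generators deliberately do **not** emulate: optics and PSF
realism, bleaching, motion artifacts, bout kinematics beyond the feature
distribution, pERK biochemistry timescales, or inter-fish registration
error. Passing tests therefore demonstrate the *procedures* are correct
and calibrated, not that real data meet their assumptions.

## Calcium-trace analysis

**Δf/f.** The baseline f0 is either the mean of a declared pre-stimulus
epoch or a running 10th percentile over 60 s. The running percentile is
the default because it is robust to drift; the epoch mode matches designs
with an explicit food-deprived baseline. The f0 definition in the source
protocols is not published, so both modes are offered and recorded in the
output metadata, without a claim of fidelity.

**Detrending.** A least-squares quadratic is subtracted. The residual is
orthogonal to the quadratic basis, so refitting returns coefficients at
numerical zero, and sparse transients pass through with amplitudes
preserved to a few tenths of a percent (the projection of a sparse spike
train onto a quadratic is small).

**Spike detection.** No algorithm is published for this step, so the
detector is a documented parameterized choice validated against ground
truth only: local maxima whose prominence — peak minus the median of a
±20 s flanking window, excluding a half-separation guard around the
peak — exceeds `k_mad` times a robust noise scale, with a minimum peak
separation (higher peaks win). Two robustness choices matter: the noise
scale is the MAD of *first differences* over √2, which sparse transients
barely inflate, and the local baseline is a median, which decay tails
barely shift. `k_mad = 3.5` by default: at 6×-noise transients this yields
~98 % recall with essentially no false positives, and pure-noise traces
stay spike-free even at `k_mad = 5` (the peak of 600 Gaussian samples is
~3.3σ). Whether published per-epoch amplitudes are per-spike means or
epoch maxima is unstated; the per-spike mean is implemented.

**Spike-triggered averages.** Segments of the target trace are aligned at
trigger times and each is baseline-subtracted by its own pre-window mean;
triggers with clipped windows are dropped and counted. Pooling across
fish is done by n-weighted averaging of per-fish STAs.

**Cross-correlogram and rank enrichment.** Correlation is zero-lag
Pearson only; lagged analysis is out of scope since single coefficients
are what the downstream statistic consumes. "Cell-sized" voxels default
to 6 px tiles (the physical size is a config decision). For the rank
statistic, each voxel's partners are sorted by ascending correlation with
ties broken by voxel index; the chance fraction excludes the source voxel
itself, because a voxel cannot be its own partner. Under label shuffling
the per-(source, target, rank) ratios are binomial with only ~n/3 source
voxels each, so the package's permutation check pools the sources
(exchangeable under shuffling) to keep the null band tight.

## Stained-stack quantification

ROI means are plain voxel means within (optionally z-restricted) masks;
background subtraction uses a per-sample background mask, and results may
legitimately be negative. cH analysis is conventionally restricted to the
most ventral planes via `z_range`. Group normalization divides by the
control-group mean, making the control mean exactly 1.

Active-cell counting reinterprets an unnamed image-processing macro as
three parameterized steps: local-mean background subtraction
(clip at 0), adaptive thresholding at local mean plus an **absolute**
intensity offset, and connected components with a physical size filter.
The offset is absolute rather than contrast-normalized so that a
signal-free image thresholds to nothing instead of amplifying its own
noise floor. The adaptive window defaults to ~3 cell diameters (15 µm).
Counting is 3-D (face adjacency) on stacks — so cells spanning planes are
counted once — and 2-D (8-neighborhood available via `connectivity`) on
single planes, with area instead of volume filters. The procedure is
documented as reliable only for sparse regions (mLH/lLH), not the densely
stained cH.

θ ratios use differences of group means, not fold changes — the only
definition consistent with both intensity and count metrics; the ratio is
reported as `NA` when the paramecia-induced change is below a floor.

ICA follows the published recipe exactly in its documented steps: fish
with any unobserved voxel are excluded; per-fish brightness is divided by
the 10th percentile; the voxelwise mean across fish is subtracted; PCA
retains 30 components and symmetric FastICA with the cubic (`pow3`)
nonlinearity computes 30 ICs, treating each fish as a signal and each
voxel as a sample; maps are z-scored and oriented so each component's
largest-|z| voxel is positive (a deterministic display convention).
The FastICA iteration is authored in-package (symmetric decorrelation via
an eigendecomposition, convergence on the rotation angle). "4.7 µm³
voxels" is ambiguous between edge length and volume; the implementation
exposes `voxel_edge` with default 4.7 µm (edge). For recovery validation,
the simulated cohort uses *sparse* (strongly non-Gaussian) spatial
sources and one extra retained component, which absorbs the per-fish
brightness-normalization direction; with components matched exactly to
source count, that direction contaminates the subspace and recovery
degrades — a property of the decomposition, not of the implementation.

## Optogenetic windows

The pre window is `[onset − 90 s, onset)` and the post window
`[offset, offset + 90 s)`: stimulation frames are never analyzed, since
the illumination itself drives fluorescence. Whether published windows
abut onset or offset is unstated; excluding the artifact frames is this
package's decision. Each pulse is one statistical unit, as in the source
protocol; per-fish aggregation can be done upstream for sensitivity
analysis. The paired Wilcoxon signed-rank test drops zero differences
before ranking (a `pratt` option keeps them); the exact null is computed
by dynamic programming over doubled midranks for n ≤ 25 — correct under
tied magnitudes, where the stock implementation silently falls back to an
approximation — and the normal approximation with tie and continuity
corrections is used above. Its type-I error at n = 30, α = 0.05 sits at
~0.047.

## Behavior statistics

Each bout is 22 posture measurements × 10 frames: 20 tail tangent angles
plus two eye gaze angles, concatenated frame-major. The skeleton is
resampled to 21 points equally spaced by arc length (so the angle count is
independent of tracker point density); tangent directions are central
differences in the interior with a second-order one-sided extrapolation at
the tail tip, and angles are successive direction changes, the first taken
against the frame's body axis. On a circular arc of total turn Θ this
yields exactly 20 angles of Θ/20. The 10-frame window (~167 ms at 60 Hz)
is the default and overridable for other frame rates. Gaze angles are
passed through as signed per-eye values; whether the source
convention was signed or convergence-referenced is unstated.

The 2-D embedding is an injected dependency with a fit–transform
contract; the default is a deterministic 2-PC projection, and a t-SNE
implementation can be plugged in unchanged (its internals are out of
scope).

Hunting-bout probability uses 3-min bins over 45 min with two-sided 90 %
Clopper–Pearson intervals (the interval family is this package's choice;
only the level is published). Which bout types count as "hunting-related"
is configurable and defaults to j-turn, pursuit, strike and abort —
whether aborts were included in the published fraction is unknown.
Per-bin comparisons use the two-sided Fisher exact test. Gut fluorescence
is the integrated (and mean) above-background intensity over the gut
mask, clipped at zero; background is measured per sample.

## Numerical choices and degenerate inputs

* Frame selection for epochs and windows is half-open, `start ≤ t < end`,
  with `t = (i−1)/fps`.
* Coordinates are 0-based `(z, y, x)`; physical parameters are µm,
  converted through the stack's voxel size.
* Correlation maps drop zero-variance voxels with a warning; a
  single-region map is an error for the rank statistic.
* `run_ica()` rejects cohorts that are rank-deficient after normalization
  (all fish identical) and reduces `n_ics` to the retained rank with a
  warning.
* All-zero paired differences give p = 1 with a warning; a pulse whose
  window is clipped is excluded and counted rather than silently
  shortened.
* Over-dense blob placement warns and emits the cells actually placed,
  which remain the ground truth.

## Problem sizes in the test-suite

The suite validates on desk-scale versions of each design: 600-s traces
at 1–2 fps (20 seeds for detection recall), one 600-s three-region movie
of 24 voxels plus a 1000-voxel permutation null, 50 stacks of 4×96×96
voxels with 0–40 planted cells, 30-pulse stimulation sessions, a
40-fish ICA cohort, 10,000-replicate calibrations for the signed-rank
type-I error and interval coverage (per-bin n = 1600, where the exact
Clopper–Pearson coverage is 90.2 %), and a 3-fish pooled STA with ~330
triggers. These sizes were chosen so each check has adequate statistical
resolution at a fixed seed.

## Known limitations

The package assumes registered input (no motion correction or inter-fish
registration), does not deconvolve calcium to firing rates, does not
model the slow baseline-fluorescence confound of long recordings, and
none of the atlas-registration significance machinery of whole-brain
activity mapping is included. Cell counting is undefined in densely
stained regions by construction. Synthetic validation bounds what can be
claimed about real data: it certifies the estimators, not the biology.
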