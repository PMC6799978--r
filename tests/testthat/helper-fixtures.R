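# Shared fixture builders; everything is generated in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A slab mask with a fixed margin, for planting cells away from edges.
slab_mask <- function(shape, margin = 7, z_keep = NULL) {
  a <- array(FALSE, shape)
  z <- z_keep %||% seq_len(shape[1])
  a[z, (margin + 1):(shape[2] - margin), (margin + 1):(shape[3] - margin)] <- TRUE
  a
}

# Single-region stack spec used by the counting tests.
cell_stack_spec <- function(seed, density, shape = c(4, 96, 96),
                            intensity_mean = 120, intensity_sd = 10) {
  stack_spec(
    shape,
    regions = list(mLH = list(mask = slab_mask(shape), density = density,
                              intensity_mean = intensity_mean,
                              intensity_sd = intensity_sd)),
    seed = seed
  )
}

# Sparse-transient model for ROI-level spike analyses: ~3 events/min in the
# lLH riding on a tonically active cH, transient amplitude 30 on baseline
# 100 with noise sd 2 (6x the delta-F/F noise scale).
sparse_spike_model <- function(seed, latent_corr = NULL, ...) {
  latent_model(rate_hz = c(2, 0.05), amp_mean = 30, amp_sd = 0,
               noise_sd = 2, kernel_tau = 3,
               latent_corr = latent_corr, seed = seed, ...)
}

# Deterministic synthetic trace: zero-mean noise plus exponential transients
# of known amplitude at known frames.
transient_trace <- function(n, fps, spike_frames, amp, tau_s, noise_sd,
                            seed) {
  withr::with_seed(seed, {
    x <- rnorm(n, 0, noise_sd)
    kern <- exp(-(0:round(8 * tau_s * fps)) / (tau_s * fps))
    for (f in spike_frames) {
      j <- f:min(n, f + length(kern) - 1L)
      x[j] <- x[j] + amp * kern[seq_along(j)]
    }
    x
  })
}

# Pooled (source-region-exchangeable) rank-enrichment ratios: probability
# over all source voxels that the nth partner is in each target region,
# over pooled chance.
pooled_rank_ratio <- function(rs, labels) {
  n_src <- table(labels)
  rs$w <- as.numeric(n_src[rs$source])
  out <- dplyr::summarise(
    dplyr::group_by(rs, target, rank),
    prob = sum(prob * w) / sum(w),
    chance = sum(chance * w) / sum(w),
    .groups = "drop"
  )
  out$ratio <- out$prob / out$chance
  out
}
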