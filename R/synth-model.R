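#' Latent dynamics model for synthetic calcium activity
#'
#' Describes two or more neural populations whose event rates are driven by
#' correlated (or anti-correlated) slow latent states. The latent state of
#' each region is a stationary unit-variance AR(1) process with timescale
#' `latent_tau_s`; cross-region correlations follow `latent_corr`. The
#' instantaneous event rate is `rate_hz * 2 * pnorm(gain * z)`, so the mean
#' rate equals `rate_hz` and `gain` sets how strongly the latent state
#' modulates it. Events are convolved with a single-exponential calcium
#' kernel (`kernel_tau`), then baseline, a quadratic drift polynomial, and
#' additive Gaussian noise are added.
#'
#' Defaults emulate slow hunger-state modulation of population (voxel-level)
#' hypothalamic signals: a ~10 s latent timescale, a few events per second
#' per voxel, and a GCaMP6s-like decay of ~4 s.
#'
#' @param n_regions Number of regions.
#' @param latent_corr Target pairwise correlation matrix of the latent
#'   states, symmetric with unit diagonal, positive semi-definite.
#' @param rate_hz Mean event rate per region (events/s); scalar or
#'   per-region vector.
#' @param kernel_tau Calcium decay time constant in seconds.
#' @param latent_tau_s Latent-state AR(1) timescale in seconds.
#' @param gain Latent-to-rate modulation gain (dimensionless).
#' @param baseline Baseline fluorescence (intensity units).
#' @param drift_coeffs Quadratic drift polynomial `c(c0, c1, c2)` applied as
#'   `c0 + c1*t + c2*t^2` (intensity units over s, s^2).
#' @param amp_mean,amp_sd Per-event fluorescence amplitude mean and sd
#'   (intensity units; amplitudes are truncated at zero).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param region_names Optional region labels; defaults to `cH`/`lLH` for two
#'   regions and `cH`/`mLH`/`lLH` for three.
#' @param seed Integer seed; identical seeds reproduce outputs bit-for-bit.
#' @return An object of class `latent_model`.
#' @export
latent_model <- function(n_regions = 2,
                         latent_corr = NULL,
                         rate_hz = 4,
                         kernel_tau = 4,
                         latent_tau_s = 10,
                         gain = 2.5,
                         baseline = 100,
                         drift_coeffs = c(0, 0, 0),
                         amp_mean = 10,
                         amp_sd = 2,
                         noise_sd = 2,
                         region_names = NULL,
                         seed = 1L) {
  if (is.null(latent_corr)) {
    latent_corr <- diag(n_regions)
    if (n_regions == 2) latent_corr[1, 2] <- latent_corr[2, 1] <- -0.8
  }
  check_corr_matrix(latent_corr)
  if (nrow(latent_corr) != n_regions) {
    abort("`latent_corr` dimension must equal `n_regions`.")
  }
  rate_hz <- rep_len(rate_hz, n_regions)
  if (any(rate_hz < 0)) abort("`rate_hz` must be >= 0.")
  check_scalar_pos(kernel_tau, "kernel_tau")
  check_scalar_pos(latent_tau_s, "latent_tau_s")
  check_scalar_pos(gain, "gain", strict = FALSE)
  stopifnot(length(drift_coeffs) == 3, is.numeric(drift_coeffs))
  check_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  check_scalar_pos(amp_mean, "amp_mean")
  if (is.null(region_names)) {
    region_names <- switch(as.character(n_regions),
      "2" = c("cH", "lLH"),
      "3" = c("cH", "mLH", "lLH"),
      paste0("region_", seq_len(n_regions))
    )
  }
  stopifnot(length(region_names) == n_regions, !anyDuplicated(region_names))
  structure(
    list(n_regions = n_regions, latent_corr = latent_corr, rate_hz = rate_hz,
         kernel_tau = kernel_tau, latent_tau_s = latent_tau_s, gain = gain,
         baseline = baseline, drift_coeffs = as.numeric(drift_coeffs),
         amp_mean = amp_mean, amp_sd = amp_sd, noise_sd = noise_sd,
         region_names = region_names, seed = as.integer(seed)),
    class = "latent_model"
  )
}

#' Specification for a synthetic stained stack
#'
#' Describes a textured background with region-dependent densities of
#' blob-like active cells. Cells are rendered as Gaussian blobs whose width
#' combines the cell radius and the point-spread blur in quadrature, so the
#' image equals background plus a sum of analytically-known Gaussians.
#'
#' @param shape Integer `(z, y, x)` voxel counts. Shapes are capped at
#'   2^24 voxels (desk memory).
#' @param regions Named list; each element is a list with fields
#'   `mask` (logical `(z, y, x)` array), `density` (expected cells per 1000
#'   mask voxels), `intensity_mean` and `intensity_sd` (peak blob intensity).
#'   Masks must be disjoint.
#' @param cell_sigma Gaussian blob sigma in voxels, `(z, y, x)`.
#' @param psf_sigma Point-spread blur sigma in voxels, `(z, y, x)`.
#' @param background_mean,background_sd Background intensity mean and
#'   Gaussian noise sd.
#' @param min_separation Minimum center-to-center distance between cells in
#'   voxels (in-plane); placement falls back with a warning when the density
#'   is too high to honor it.
#' @param voxel_size Physical voxel size in um, `(z, y, x)`.
#' @param seed Integer seed.
#' @return An object of class `stack_spec`.
#' @export
stack_spec <- function(shape,
                       regions,
                       cell_sigma = c(1, 1.5, 1.5),
                       psf_sigma = c(0.5, 0.5, 0.5),
                       background_mean = 20,
                       background_sd = 2,
                       min_separation = 6,
                       voxel_size = c(2, 0.8, 0.8),
                       seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (prod(as.numeric(shape)) > 2^24) abort("Stack shape exceeds the 2^24-voxel cap.")
  if (!is.list(regions) || is.null(names(regions))) {
    abort("`regions` must be a named list.")
  }
  acc <- array(0L, shape)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (!all(c("mask", "density") %in% names(r))) {
      abort(sprintf("Region '%s' needs `mask` and `density`.", nm))
    }
    if (!identical(dim(r$mask), shape)) {
      abort(sprintf("Region '%s' mask does not match `shape`.", nm))
    }
    if (r$density < 0) abort("Densities must be >= 0.")
    acc <- acc + r$mask
  }
  if (any(acc > 1L)) abort("Region masks must be disjoint.")
  stopifnot(length(cell_sigma) == 3, all(cell_sigma > 0),
            length(psf_sigma) == 3, all(psf_sigma >= 0))
  structure(
    list(shape = shape, regions = regions, cell_sigma = as.numeric(cell_sigma),
         psf_sigma = as.numeric(psf_sigma), background_mean = background_mean,
         background_sd = background_sd, min_separation = min_separation,
         voxel_size = as.numeric(voxel_size), seed = as.integer(seed)),
    class = "stack_spec"
  )
}
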