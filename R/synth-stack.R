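## Synthetic stained stacks and gut images with ground truth.

## Render one Gaussian blob (peak amplitude `amp`, per-axis sigma) into `img`
## in place-style (returns updated array). Support truncated at 6 sigma so
## the discrete sum matches the analytic integral to ~1e-9 relative.
add_blob <- function(img, center, amp, sigma) {
  d <- dim(img)
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, floor(center[ax] - 6 * sigma[ax]))
    hi <- min(d[ax], ceiling(center[ax] + 6 * sigma[ax]))
    lo:hi
  })
  gz <- exp(-((rng[[1]] - center[1])^2) / (2 * sigma[1]^2))
  gy <- exp(-((rng[[2]] - center[2])^2) / (2 * sigma[2]^2))
  gx <- exp(-((rng[[3]] - center[3])^2) / (2 * sigma[3]^2))
  sub <- img[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  img[rng[[1]], rng[[2]], rng[[3]]] <- sub + amp * (gz %o% gy %o% gx)
  img
}

## Sample cell centers inside a mask honoring a minimum separation measured
## in units of the blob sigma (anisotropic, 3-D), so blobs stay resolvable;
## falls back (with a warning from the caller) when space runs out.
place_centers <- function(mask, n_cells, min_sep, sigma = c(1, 1, 1)) {
  cand <- which(mask, arr.ind = TRUE)
  centers <- matrix(numeric(0), 0, 3)
  if (n_cells == 0 || nrow(cand) == 0) return(centers)
  tries <- 0L
  while (nrow(centers) < n_cells && tries < 200L * n_cells) {
    tries <- tries + 1L
    p <- cand[sample.int(nrow(cand), 1L), ] + runif(3, -0.45, 0.45)
    if (nrow(centers)) {
      dd <- sqrt(colSums(((t(centers) - p) / sigma)^2))
      if (any(dd < min_sep)) next
    }
    centers <- rbind(centers, p)
  }
  centers
}

#' Generate a synthetic stained stack with ground-truth cell centers
#'
#' Builds `background texture + sum of Gaussian blobs` at randomly placed
#' mask-interior centers. The blob width combines the cell sigma and the
#' point-spread sigma in quadrature, so blurring is exact and each blob's
#' integrated intensity has the closed form
#' `amp * (2*pi)^(3/2) * prod(sigma_eff)`.
#'
#' @param spec A [stack_spec()].
#' @return A list with `stack` (a single-channel `pERK` [stained_stack()]),
#'   `rois` (a [roi_set()] with the region masks plus a `background` mask of
#'   all unassigned voxels), and `truth` (per-region cell centers (1-based
#'   `(z,y,x)`), peak amplitudes, effective sigma, and expected per-cell
#'   integrals).
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "stack_spec"))
  with_seed(substream_seed(spec$seed, "stack"), {
    sigma_eff <- sqrt(spec$cell_sigma^2 + spec$psf_sigma^2)
    img <- array(spec$background_mean, spec$shape)
    if (spec$background_sd > 0) {
      img <- img + array(rnorm(prod(spec$shape), 0, spec$background_sd),
                         spec$shape)
    }
    truth <- list()
    for (nm in names(spec$regions)) {
      r <- spec$regions[[nm]]
      n_cells <- rpois(1, r$density * sum(r$mask) / 1000)
      centers <- place_centers(r$mask, n_cells, spec$min_separation, sigma_eff)
      if (nrow(centers) < n_cells) {
        warn(sprintf(
          "Region '%s': placed %d of %d cells (density too high for min_separation).",
          nm, nrow(centers), n_cells))
      }
      int_sd <- if (is.null(r$intensity_sd)) 0 else r$intensity_sd
      amps <- pmax(rnorm(nrow(centers), r$intensity_mean, int_sd), 0)
      for (i in seq_len(nrow(centers))) {
        img <- add_blob(img, centers[i, ], amps[i], sigma_eff)
      }
      truth[[nm]] <- list(
        centers = centers, amps = amps, sigma = sigma_eff,
        integrals = amps * (2 * pi)^1.5 * prod(sigma_eff)
      )
    }
    img[img < 0] <- 0
    masks <- lapply(spec$regions, `[[`, "mask")
    bg <- Reduce(`|`, masks)
    masks$background <- !bg
    if (!any(masks$background)) masks$background <- NULL
    list(
      stack = stained_stack(list(pERK = img), voxel_size = spec$voxel_size),
      rois = roi_set(masks),
      truth = truth
    )
  })
}

#' Generate a synthetic gut-fluorescence image with known ingestion signal
#'
#' Deposits Gaussian blobs (labeled prey in the gut) inside a central
#' elliptical gut region and rescales them so the integrated above-background
#' signal inside the gut mask equals `total_signal` exactly before noise.
#'
#' @param total_signal Non-negative total above-background signal (a.u.).
#' @param shape Integer `(z, y, x)` image shape; use `z = 1` for a 2-D image.
#' @param n_deposits Number of prey deposits.
#' @param background_mean,background_sd Background level and noise sd.
#' @param seed Integer seed.
#' @return A list with `image` (array), `gut_mask`, `background_mask`
#'   (logical arrays), and `truth` (`total_signal`, deposit centers).
#' @export
generate_gut_image <- function(total_signal, shape = c(1, 64, 64),
                               n_deposits = 5, background_mean = 10,
                               background_sd = 0, seed = 1L) {
  check_scalar_pos(total_signal, "total_signal", strict = FALSE)
  shape <- as.integer(shape)
  with_seed(substream_seed(seed, "gut"), {
    zz <- seq_len(shape[1]); yy <- seq_len(shape[2]); xx <- seq_len(shape[3])
    cy <- (shape[2] + 1) / 2; cx <- (shape[3] + 1) / 2
    ell <- outer((yy - cy)^2 / (0.3 * shape[2])^2,
                 (xx - cx)^2 / (0.3 * shape[3])^2, `+`) <= 1
    gut_mask <- array(rep(ell, each = shape[1]) > 0, shape)
    ## background ring: everything at least 15% of the image away from the gut
    ell_bg <- outer((yy - cy)^2 / (0.42 * shape[2])^2,
                    (xx - cx)^2 / (0.42 * shape[3])^2, `+`) > 1
    background_mask <- array(rep(ell_bg, each = shape[1]) > 0, shape)
    sig <- array(0, shape)
    if (total_signal > 0) {
      centers <- place_centers(gut_mask, n_deposits, min_sep = 3)
      sigma <- c(max(0.6, shape[1] / 10), 2, 2)
      for (i in seq_len(nrow(centers))) {
        sig <- add_blob(sig, centers[i, ], 1, sigma)
      }
      inside <- sum(sig[gut_mask])
      if (inside <= 0) abort("Failed to deposit signal inside the gut mask.")
      sig <- sig * (total_signal / inside)
    } else {
      centers <- matrix(numeric(0), 0, 3)
    }
    img <- background_mean + sig
    if (background_sd > 0) {
      img <- img + array(rnorm(prod(shape), 0, background_sd), shape)
    }
    list(image = img, gut_mask = gut_mask, background_mask = background_mask,
         truth = list(total_signal = total_signal, centers = centers))
  })
}
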