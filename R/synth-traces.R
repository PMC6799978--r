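## Synthetic calcium traces and movies with ground truth.

## Simulate the correlated AR(1) latent states (time x region, unit variance).
simulate_latent <- function(model, n, fps) {
  l_factor <- psd_factor(model$latent_corr)
  phi <- exp(-1 / (model$latent_tau_s * fps))
  eps <- matrix(rnorm(n * model$n_regions), n, model$n_regions) %*% t(l_factor)
  z <- matrix(0, n, model$n_regions)
  z[1, ] <- eps[1, ]
  if (n > 1) {
    w <- sqrt(1 - phi^2)
    for (t in 2:n) z[t, ] <- phi * z[t - 1, ] + w * eps[t, ]
  }
  colnames(z) <- model$region_names
  z
}

## Event rate (events/s) implied by the latent state.
latent_rate <- function(model, z) {
  r <- 2 * pnorm(model$gain * z)
  sweep(r, 2, model$rate_hz, `*`)
}

exp_kernel <- function(tau, fps, n) {
  len <- min(max(2L, ceiling(10 * tau * fps)), n)
  exp(-(seq_len(len) - 1) / (tau * fps))
}

## Direct causal convolution (exact, O(n * k)); kernels are short.
causal_conv <- function(train, kernel) {
  n <- length(train)
  out <- numeric(n)
  idx <- which(train != 0)
  for (i in idx) {
    j <- i:min(n, i + length(kernel) - 1L)
    out[j] <- out[j] + train[i] * kernel[seq_along(j)]
  }
  out
}

#' Generate synthetic raw calcium traces with ground truth
#'
#' Builds raw fluorescence as `baseline + drift polynomial +
#' (event train convolved with an exponential kernel) + Gaussian noise`,
#' with event rates modulated by correlated latent states (see
#' [latent_model()]). The empirical correlation of the emitted latent traces
#' converges to `latent_corr` as the duration grows.
#'
#' @param model A [latent_model()].
#' @param duration_s Trace duration in seconds.
#' @param fps Sampling rate in frames/s; `duration_s * fps` must be >= 10.
#' @return A list with elements `traces` (a [trace_set()] holding raw
#'   fluorescence) and `truth` (latent traces, per-region event times and
#'   amplitudes, and the generating parameters).
#' @export
generate_traces <- function(model, duration_s, fps) {
  stopifnot(inherits(model, "latent_model"))
  check_scalar_pos(duration_s, "duration_s")
  check_scalar_pos(fps, "fps")
  n <- round(duration_s * fps)
  if (n < 10) abort("duration_s * fps must be at least 10 samples.")
  with_seed(substream_seed(model$seed, "traces"), {
    z <- simulate_latent(model, n, fps)
    rate <- latent_rate(model, z)
    counts <- matrix(rpois(n * model$n_regions, rate / fps), n)
    kernel <- exp_kernel(model$kernel_tau, fps, n)
    tvec <- (seq_len(n) - 1) / fps
    drift <- model$drift_coeffs[1] + model$drift_coeffs[2] * tvec +
      model$drift_coeffs[3] * tvec^2
    raw <- matrix(0, n, model$n_regions,
                  dimnames = list(NULL, model$region_names))
    event_times <- vector("list", model$n_regions)
    names(event_times) <- model$region_names
    event_amps <- event_times
    for (r in seq_len(model$n_regions)) {
      amp_train <- numeric(n)
      idx <- which(counts[, r] > 0)
      times <- amps <- numeric(0)
      for (i in idx) {
        a <- pmax(rnorm(counts[i, r], model$amp_mean, model$amp_sd), 0)
        amp_train[i] <- sum(a)
        times <- c(times, rep(tvec[i], counts[i, r]))
        amps <- c(amps, a)
      }
      signal <- causal_conv(amp_train, kernel)
      raw[, r] <- model$baseline + drift + signal +
        model$noise_sd * rnorm(n)
      event_times[[r]] <- times
      event_amps[[r]] <- amps
    }
    list(
      traces = trace_set(raw = raw, fps = fps,
                         params = list(generator = "latent_model",
                                       seed = model$seed)),
      truth = list(latent_traces = z, rate = rate,
                   event_times = event_times, event_amps = event_amps,
                   model = model)
    )
  })
}

#' Generate a synthetic two-or-more-population calcium movie
#'
#' Lays the regions of a [latent_model()] out as equal vertical bands of a
#' `time x y x x` movie. Every pixel of a band shares that region's
#' event-driven calcium signal (no drift or region-level noise) and adds
#' independent pixel shot noise, emulating cell-sized voxels carrying a
#' common population signal.
#'
#' @param model A [latent_model()].
#' @param duration_s,fps Duration (s) and sampling rate (frames/s).
#' @param ny,nx Movie height and width in pixels.
#' @param pixel_noise_sd Per-pixel additive noise sd (intensity units).
#' @return A list with `movie` (a `time x y x x` array), `region_map`
#'   (a `y x x` character matrix of region labels), and `truth` (as in
#'   [generate_traces()], plus the clean per-region signal).
#' @export
generate_movie <- function(model, duration_s, fps, ny = 24, nx = 48,
                           pixel_noise_sd = 60) {
  stopifnot(inherits(model, "latent_model"))
  gen <- generate_traces(model, duration_s, fps)
  n <- n_frames(gen$traces)
  ## clean per-region signal: raw minus noise is not recoverable, so rebuild
  ## the deterministic parts from truth
  with_seed(substream_seed(model$seed, "movie"), {
    kernel <- exp_kernel(model$kernel_tau, fps, n)
    tvec <- (seq_len(n) - 1) / fps
    clean <- matrix(model$baseline, n, model$n_regions,
                    dimnames = list(NULL, model$region_names))
    for (r in seq_len(model$n_regions)) {
      amp_train <- numeric(n)
      if (length(gen$truth$event_times[[r]]))  {
        fr <- round(gen$truth$event_times[[r]] * fps) + 1L
        for (k in seq_along(fr)) {
          amp_train[fr[k]] <- amp_train[fr[k]] + gen$truth$event_amps[[r]][k]
        }
      }
      clean[, r] <- clean[, r] + causal_conv(amp_train, kernel)
    }
    band <- pmin(((seq_len(nx) - 1) %/% ceiling(nx / model$n_regions)) + 1L,
                 model$n_regions)
    region_map <- matrix(model$region_names[band], ny, nx, byrow = TRUE)
    movie <- array(0, c(n, ny, nx))
    for (x in seq_len(nx)) {
      sig <- clean[, band[x]]
      movie[, , x] <- sig + matrix(rnorm(n * ny, 0, pixel_noise_sd), n, ny)
    }
    gen$truth$clean_signal <- clean
    list(movie = movie, region_map = region_map, truth = gen$truth)
  })
}
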