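## Synthetic optogenetic stimulation sessions.

#' Generate a synthetic optogenetic session with post-stimulus rate change
#'
#' Simulates calcium traces as in [generate_traces()], but multiplies each
#' region's event rate by `effect` inside the post-stimulation window
#' `[offset, offset + window_s)` of every pulse. `effect < 1` emulates
#' post-stimulus suppression, `> 1` excitation.
#'
#' @param model A [latent_model()].
#' @param pulses Data frame with `onset_s`, `duration_s`; pulses must be
#'   sorted, non-overlapping, with full pre/post windows inside the trace and
#'   not overlapping between consecutive pulses.
#' @param effect Per-region multiplicative rate factor (scalar recycled).
#' @param window_s Pre/post analysis window length (s), default 90.
#' @param duration_s,fps Trace duration and sampling rate; `duration_s`
#'   defaults to the last pulse offset plus `window_s`.
#' @return A list with `session` (a [stim_session()]) and `truth`
#'   (per-region event times, effect factors, and window bounds).
#' @export
generate_opto_session <- function(model, pulses, effect, window_s = 90,
                                  duration_s = NULL, fps = 2) {
  stopifnot(inherits(model, "latent_model"))
  pulses <- tibble::as_tibble(pulses)
  stopifnot(all(c("onset_s", "duration_s") %in% names(pulses)))
  effect <- rep_len(effect, model$n_regions)
  if (any(effect < 0)) abort("`effect` must be >= 0.")
  offs <- pulses$onset_s + pulses$duration_s
  if (is.null(duration_s)) duration_s <- max(offs) + window_s
  if (any(pulses$onset_s - window_s < 0) || any(offs + window_s > duration_s)) {
    abort("Every pulse needs a full pre and post window inside the trace.")
  }
  if (nrow(pulses) > 1) {
    if (is.unsorted(pulses$onset_s, strictly = TRUE) ||
        any(pulses$onset_s[-1] < offs[-nrow(pulses)])) {
      abort("Pulses must be sorted and non-overlapping.")
    }
    if (any(offs[-nrow(pulses)] + window_s > pulses$onset_s[-1] - window_s)) {
      abort("Pre/post windows of consecutive pulses overlap; space pulses further apart.")
    }
  }
  n <- round(duration_s * fps)
  tvec <- (seq_len(n) - 1) / fps
  post <- rep(FALSE, n)
  for (i in seq_len(nrow(pulses))) {
    post <- post | (tvec >= offs[i] & tvec < offs[i] + window_s)
  }
  with_seed(substream_seed(model$seed, "opto"), {
    z <- simulate_latent(model, n, fps)
    rate <- latent_rate(model, z)
    rate[post, ] <- sweep(rate[post, , drop = FALSE], 2, effect, `*`)
    counts <- matrix(rpois(n * model$n_regions, rate / fps), n)
    kernel <- exp_kernel(model$kernel_tau, fps, n)
    raw <- matrix(0, n, model$n_regions,
                  dimnames = list(NULL, model$region_names))
    event_times <- setNames(vector("list", model$n_regions), model$region_names)
    for (r in seq_len(model$n_regions)) {
      amp_train <- numeric(n)
      idx <- which(counts[, r] > 0)
      times <- numeric(0)
      for (i in idx) {
        a <- pmax(rnorm(counts[i, r], model$amp_mean, model$amp_sd), 0)
        amp_train[i] <- sum(a)
        times <- c(times, rep(tvec[i], counts[i, r]))
      }
      raw[, r] <- model$baseline + causal_conv(amp_train, kernel) +
        model$noise_sd * rnorm(n)
      event_times[[r]] <- times
    }
    ts <- trace_set(raw = raw, fps = fps,
                    params = list(generator = "opto", seed = model$seed))
    list(
      session = stim_session(ts, pulses, window_s = window_s),
      truth = list(event_times = event_times, effect = effect,
                   post_windows = cbind(start = offs, end = offs + window_s),
                   pre_windows = cbind(start = pulses$onset_s - window_s,
                                       end = pulses$onset_s),
                   latent_traces = z)
    )
  })
}
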