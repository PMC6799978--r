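## Calcium spike detection, per-epoch metrics and spike-triggered averages.

#' Detect calcium spikes by a prominence-over-noise rule
#'
#' Finds local maxima of a baseline-detrended delta-F/F series whose local
#' prominence — peak value minus the median of a flanking window (a guard
#' region around the peak excluded) — exceeds `k_mad` times a robust noise
#' scale (the MAD of first differences, insensitive to sparse transients),
#' enforcing a minimum separation between accepted peaks (higher peaks
#' win). The reported amplitude is the prominence (peak minus local
#' baseline).
#'
#' @param trace Numeric detrended delta-F/F series.
#' @param fps Frames/s.
#' @param k_mad Threshold multiplier on the noise scale (default 3.5).
#' @param min_separation_s Minimum spike separation in seconds (default 4).
#' @param baseline_window_s One-sided window (s) over which the local
#'   baseline median is taken (default 20).
#' @param detrended Caller's confirmation that the trace has been
#'   detrended; detection assumes a drift-free baseline.
#' @param roi Label stored on the output.
#' @return A `spike_train` tibble with columns `roi`, `time` (s, strictly
#'   increasing), `amplitude` (fraction, > 0).
#' @export
detect_spikes <- function(trace, fps, k_mad = 3.5, min_separation_s = 4,
                          baseline_window_s = 20, detrended = TRUE,
                          roi = "roi") {
  stopifnot(is.numeric(trace))
  check_scalar_pos(fps, "fps")
  check_scalar_pos(k_mad, "k_mad")
  if (!isTRUE(detrended)) {
    abort("Detection requires a detrended trace; run detrend_quadratic() and pass detrended = TRUE.")
  }
  n <- length(trace)
  sep <- max(1L, round(min_separation_s * fps))
  if (n <= sep) abort("Trace shorter than the minimum-separation window.")
  if (!all(is.finite(trace))) abort("Trace must be finite.")
  win <- max(1L, round(baseline_window_s * fps))
  guard <- max(1L, round(min_separation_s * fps / 2))
  sigma <- mad(diff(trace)) / sqrt(2)
  if (sigma == 0) sigma <- sd(trace)
  if (!is.finite(sigma) || sigma == 0) {
    return(new_spike_train(numeric(0), numeric(0), roi))
  }
  ## local maxima (strict on the left, non-strict right to break plateaus)
  dpre <- diff(trace)
  is_max <- c(FALSE, dpre > 0) & c(dpre <= 0, FALSE)
  cand <- which(is_max)
  if (!length(cand)) return(new_spike_train(numeric(0), numeric(0), roi))
  prom <- vapply(cand, function(i) {
    lo <- max(1L, i - win); hi <- min(n, i + win)
    base <- c(trace[lo:max(lo, i - guard)], trace[min(hi, i + guard):hi])
    trace[i] - median(base)
  }, numeric(1))
  keep <- prom >= k_mad * sigma
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(new_spike_train(numeric(0), numeric(0), roi))
  ## enforce separation: accept in decreasing peak height
  ord <- order(trace[cand], decreasing = TRUE)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(cand[i] - cand[accepted]) >= sep)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)
  new_spike_train((cand[accepted] - 1) / fps, prom[accepted], roi)
}

new_spike_train <- function(times, amplitudes, roi) {
  out <- tibble::tibble(roi = rep(roi, length(times)),
                        time = times, amplitude = amplitudes)
  class(out) <- c("spike_train", class(out))
  out
}

#' Per-epoch activity metrics
#'
#' Integrated fluorescence (`sum_dff`, fraction-samples), calcium spike
#' frequency (`freq`, spikes/min) and mean spike amplitude (`amp`, fraction;
#' `NA` when the epoch holds no spikes) over a named epoch.
#'
#' @param ts A [trace_set()] with dff.
#' @param spikes A `spike_train` from [detect_spikes()].
#' @param epoch Epoch name defined in `ts`.
#' @param roi ROI whose dff column is summed (defaults to the spike train's
#'   roi when present in the trace set).
#' @return A one-row tibble with `epoch`, `roi`, `sum_dff`, `freq`, `amp`,
#'   `n_spikes`.
#' @export
epoch_metrics <- function(ts, spikes, epoch, roi = NULL) {
  stopifnot(inherits(ts, "trace_set"))
  if (is.null(ts$dff)) abort("Trace set holds no dff.")
  ep <- ts$epochs[[epoch]]
  if (is.null(ep)) abort(sprintf("Epoch '%s' not defined.", epoch))
  if (ep[2] <= ep[1]) abort("Zero-length epoch.")
  if (is.null(roi)) {
    cand <- unique(spikes$roi)
    roi <- if (length(cand) && cand[1] %in% colnames(ts$dff)) cand[1]
           else colnames(ts$dff)[1]
  }
  if (!roi %in% colnames(ts$dff)) {
    abort(sprintf("ROI '%s' not in trace set.", roi))
  }
  sel <- epoch_frames(ep, ts$fps, n_frames(ts))
  sum_dff <- sum(ts$dff[sel, roi])
  in_ep <- spikes$time >= ep[1] & spikes$time < ep[2]
  n_sp <- sum(in_ep)
  minutes <- (ep[2] - ep[1]) / 60
  tibble::tibble(
    epoch = epoch, roi = roi, sum_dff = sum_dff,
    freq = n_sp / minutes,
    amp = if (n_sp) mean(spikes$amplitude[in_ep]) else NA_real_,
    n_spikes = n_sp
  )
}

#' Spike-triggered average of a target trace
#'
#' Averages segments of `target` aligned at trigger spike times. Each
#' segment is baseline-subtracted by its own pre-window mean; triggers whose
#' window is clipped by the trace edges are dropped and counted.
#'
#' @param trigger A `spike_train` supplying trigger times (s).
#' @param target Numeric delta-F/F series.
#' @param fps Frames/s of `target`.
#' @param window_s `c(pre, post)` window half-lengths in seconds.
#' @return An object of class `sta` — a tibble with `lag` (s), `mean`,
#'   `sem`, plus attributes `n_used` and `n_dropped`.
#' @export
spike_triggered_average <- function(trigger, target, fps,
                                    window_s = c(20, 20)) {
  stopifnot(is.numeric(target), length(window_s) == 2, all(window_s > 0))
  check_scalar_pos(fps, "fps")
  n <- length(target)
  pre <- round(window_s[1] * fps); post <- round(window_s[2] * fps)
  centers <- round(trigger$time * fps) + 1L
  ok <- centers - pre >= 1L & centers + post <= n
  n_dropped <- sum(!ok)
  centers <- centers[ok]
  if (!length(centers)) abort("No trigger has a full window inside the trace.")
  lags <- (-pre):post
  seg <- vapply(centers, function(c0) {
    s <- target[c0 + lags]
    s - mean(s[seq_len(pre)])  # subtract own pre-window mean
  }, numeric(length(lags)))
  seg <- matrix(seg, nrow = length(lags))
  out <- tibble::tibble(
    lag = lags / fps,
    mean = rowMeans(seg),
    sem = apply(seg, 1, sd) / sqrt(ncol(seg))
  )
  attr(out, "n_used") <- length(centers)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("sta", class(out))
  out
}
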