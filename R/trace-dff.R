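## Delta-F/F, detrending and side-averaging of calcium traces.

#' Parameters for delta-F/F baseline estimation
#'
#' The baseline f0 is either the mean of a declared pre-stimulus epoch
#' (mode `"epoch"`) or a running percentile (mode `"percentile"`), which is
#' robust to slow drift.
#'
#' @param f0_mode `"epoch"` or `"percentile"`.
#' @param f0_epoch Epoch name used in `"epoch"` mode (default `"baseline"`).
#' @param f0_percentile Percentile in (0, 100) for the running baseline
#'   (default 10).
#' @param f0_window_s Running-window length in seconds (default 60); must
#'   cover at least 10 samples at the trace's frame rate.
#' @return An object of class `dff_params`.
#' @export
dff_params <- function(f0_mode = c("percentile", "epoch"),
                       f0_epoch = "baseline",
                       f0_percentile = 10, f0_window_s = 60) {
  f0_mode <- match.arg(f0_mode)
  stopifnot(f0_percentile > 0, f0_percentile < 100)
  check_scalar_pos(f0_window_s, "f0_window_s")
  structure(
    list(f0_mode = f0_mode, f0_epoch = f0_epoch,
         f0_percentile = f0_percentile, f0_window_s = f0_window_s),
    class = "dff_params"
  )
}

## Centered running percentile via zoo::rollapply.
running_percentile <- function(x, width, prob) {
  width <- max(as.integer(width), 1L)
  zoo::rollapply(x, width = width, FUN = quantile, probs = prob,
                 names = FALSE, partial = TRUE, align = "center")
}

#' Compute delta-F/F from raw fluorescence
#'
#' `dff = (raw - f0) / f0`, with f0 either a per-ROI pre-stimulus epoch mean
#' or a per-frame running percentile (see [dff_params()]). Delta-F/F is
#' stored as a fraction; multiply by 100 for percent. The baseline mode and
#' parameters are recorded in the output metadata.
#'
#' @param ts A [trace_set()] holding raw fluorescence (or a bare time-by-ROI
#'   matrix plus `fps`).
#' @param params A [dff_params()].
#' @param fps Frames/s, only needed when `ts` is a bare matrix.
#' @return A [trace_set()] with `dff` filled in.
#' @export
compute_dff <- function(ts, params = dff_params(), fps = NULL) {
  if (is.matrix(ts)) {
    if (is.null(fps)) abort("Supply `fps` when passing a bare matrix.")
    ts <- trace_set(raw = ts, fps = fps)
  }
  stopifnot(inherits(ts, "trace_set"), inherits(params, "dff_params"))
  if (is.null(ts$raw)) abort("`ts` holds no raw fluorescence.")
  raw <- ts$raw
  if (!all(is.finite(raw))) abort("Raw traces must be finite.")
  n <- nrow(raw)
  dff <- raw
  if (params$f0_mode == "epoch") {
    ep <- ts$epochs[[params$f0_epoch]]
    if (is.null(ep)) abort(sprintf("Epoch '%s' not found for f0.", params$f0_epoch))
    sel <- epoch_frames(ep, ts$fps, n)
    for (j in seq_len(ncol(raw))) {
      f0 <- mean(raw[sel, j])
      if (f0 <= 0) abort(sprintf("f0 <= 0 for ROI '%s'.", colnames(raw)[j]))
      dff[, j] <- (raw[, j] - f0) / f0
    }
  } else {
    width <- round(params$f0_window_s * ts$fps)
    if (width < 10) abort("f0 window must cover at least 10 samples.")
    for (j in seq_len(ncol(raw))) {
      f0 <- running_percentile(raw[, j], width, params$f0_percentile / 100)
      if (any(f0 <= 0)) abort(sprintf("f0 <= 0 for ROI '%s'.", colnames(raw)[j]))
      dff[, j] <- (raw[, j] - f0) / f0
    }
  }
  trace_set(raw = raw, dff = dff, fps = ts$fps, events = ts$events,
            epochs = ts$epochs,
            params = c(ts$params, list(dff = unclass(params))))
}

## 1-based indices of frames whose time t = (i-1)/fps satisfies
## start <= t < end (start inclusive, end exclusive).
epoch_frames <- function(epoch, fps, n) {
  lo <- max(ceiling(epoch[1] * fps - 1e-9) + 1, 1)
  hi <- min(floor(epoch[2] * fps + 1 - 1e-9), n)
  if (hi < lo) abort("Epoch covers no frames.")
  lo:hi
}

#' Remove slow baseline drift by quadratic detrending
#'
#' Fits a least-squares quadratic polynomial to the series and subtracts it.
#' The residual is orthogonal to the quadratic basis, so refitting a
#' quadratic to the output yields coefficients that vanish to numerical
#' precision, and sparse transients riding on the drift are preserved.
#'
#' @param x Numeric series (>= 3 samples), or a [trace_set()] whose `dff`
#'   columns are each detrended.
#' @return Same shape as the input, detrended.
#' @export
detrend_quadratic <- function(x) {
  if (inherits(x, "trace_set")) {
    if (is.null(x$dff)) abort("Trace set holds no dff; run compute_dff() first.")
    x$dff <- apply(x$dff, 2, detrend_quadratic)
    x$params$detrended <- "quadratic"
    return(x)
  }
  stopifnot(is.numeric(x))
  n <- length(x)
  if (n < 3) abort("Need at least 3 samples to fit a quadratic.")
  t0 <- seq_len(n) / n  # scaled time for conditioning
  fit <- lm.fit(cbind(1, t0, t0^2), x)
  as.numeric(fit$residuals)
}

#' Average paired left/right lobe traces per region
#'
#' ROI labels of the form `region_side` (e.g. `lLH_left`, `lLH_right`) are
#' averaged into one trace per region; labels without a partner pass through
#' unchanged with a warning.
#'
#' @param ts A [trace_set()] with dff traces.
#' @return A [trace_set()] with one averaged column per region.
#' @export
average_sides <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  m <- ts$dff %||% ts$raw
  labels <- colnames(m)
  region <- sub("_(left|right|L|R)$", "", labels)
  out <- sapply(unique(region), function(rg) {
    cols <- which(region == rg)
    if (length(cols) == 1 && labels[cols] == rg) {
      ## label had no side suffix: passes through
    } else if (length(cols) < 2) {
      warn(sprintf("ROI '%s' has no left/right partner; passed through.",
                   labels[cols]))
    }
    rowMeans(m[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(NULL, unique(region)))
  if (!is.null(ts$dff)) {
    trace_set(dff = out, fps = ts$fps, events = ts$events, epochs = ts$epochs,
              params = c(ts$params, list(sides_averaged = TRUE)))
  } else {
    trace_set(raw = out, fps = ts$fps, events = ts$events, epochs = ts$epochs,
              params = c(ts$params, list(sides_averaged = TRUE)))
  }
}
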