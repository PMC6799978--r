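## Pre/post stimulation window metrics and paired statistics.

#' Pre/post window metrics around each stimulation pulse
#'
#' For each pulse and target ROI, computes the mean, summed and maximum
#' delta-F/F in a `window_s`-long window before pulse onset
#' (`[onset - window_s, onset)`) and after pulse offset
#' (`[onset + duration, onset + duration + window_s)`). Frames during the
#' stimulation itself are never included. Pulses whose windows are clipped
#' by the trace edges are excluded and counted.
#'
#' @param session A [stim_session()] whose trace set carries dff.
#' @return A tibble with one row per `(pulse, roi)`: `pulse`, `roi`,
#'   `pre_mean`, `post_mean`, `pre_sum`, `post_sum`, `pre_max`, `post_max`;
#'   attribute `n_excluded` counts dropped pulses.
#' @export
window_metrics <- function(session) {
  stopifnot(inherits(session, "stim_session"))
  ts <- session$ts
  if (is.null(ts$dff)) abort("Session trace set holds no dff; run compute_dff() first.")
  n <- n_frames(ts)
  dur <- n / ts$fps
  w <- session$window_s
  rows <- list()
  n_excluded <- 0L
  for (i in seq_len(nrow(session$pulses))) {
    onset <- session$pulses$onset_s[i]
    offset <- onset + session$pulses$duration_s[i]
    if (onset - w < 0 || offset + w > dur + 1e-9) {
      n_excluded <- n_excluded + 1L
      next
    }
    pre_sel <- window_frames(onset - w, onset, ts$fps, n)
    post_sel <- window_frames(offset, offset + w, ts$fps, n)
    for (roi in session$target_rois) {
      pre <- ts$dff[pre_sel, roi]
      post <- ts$dff[post_sel, roi]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pulse = i, roi = roi,
        pre_mean = mean(pre), post_mean = mean(post),
        pre_sum = sum(pre), post_sum = sum(post),
        pre_max = max(pre), post_max = max(post)
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    pulse = integer(0), roi = character(0),
    pre_mean = numeric(0), post_mean = numeric(0),
    pre_sum = numeric(0), post_sum = numeric(0),
    pre_max = numeric(0), post_max = numeric(0)
  )
  attr(out, "n_excluded") <- n_excluded
  out
}

## frames with start <= t < end, t = (i-1)/fps
window_frames <- function(start, end, fps, n) {
  lo <- max(ceiling(start * fps - 1e-9) + 1, 1)
  hi <- min(floor(end * fps + 1 - 1e-9), n)
  if (hi < lo) abort("Window covers no frames.")
  lo:hi
}

#' Paired Wilcoxon signed-rank test on pre/post values
#'
#' Wilcoxon signed-rank test on paired differences `post - pre`. Zero
#' differences are dropped before ranking (with `zero_method = "wilcox"`,
#' the default); the exact null distribution is used for n <= 25 untied
#' pairs and the normal approximation (with continuity correction) above.
#' One-tailed tests encode a prior prediction about the direction of change.
#'
#' @param pre,post Equal-length numeric vectors (>= 5 pairs).
#' @param tail `"two"` (default), `"one-greater"` (post > pre predicted) or
#'   `"one-less"` (post < pre predicted).
#' @param zero_method `"wilcox"` drops zero differences; `"pratt"` keeps
#'   them in the ranking and drops their ranks.
#' @return A one-row tibble with `statistic` (V), `p`, `n_pairs`,
#'   `n_zero_dropped`, `method`.
#' @export
paired_test <- function(pre, post, tail = c("two", "one-greater", "one-less"),
                        zero_method = c("wilcox", "pratt")) {
  tail <- match.arg(tail)
  zero_method <- match.arg(zero_method)
  stopifnot(is.numeric(pre), is.numeric(post))
  if (length(pre) != length(post)) abort("`pre` and `post` must have equal length.")
  if (length(pre) < 5) abort("Need at least 5 pairs.")
  d <- post - pre
  n_zero <- sum(d == 0)
  if (all(d == 0)) {
    warn("All paired differences are zero; p = 1.")
    return(tibble::tibble(statistic = NA_real_, p = 1, n_pairs = 0L,
                          n_zero_dropped = n_zero, method = "degenerate"))
  }
  alternative <- switch(tail, two = "two.sided",
                        `one-greater` = "greater", `one-less` = "less")
  dd <- if (zero_method == "wilcox") d[d != 0] else d
  n_eff <- length(dd)
  r <- rank(abs(dd))
  if (zero_method == "pratt") {
    ## rank zeros with everything, then discard them from the statistic
    keep <- dd != 0
    r <- r[keep]; dd <- dd[keep]
  }
  v <- sum(r[dd > 0])
  if (n_eff <= 25) {
    p <- exact_signed_rank_p(v, r, alternative)
    method <- "exact"
  } else {
    ## normal approximation with tie correction and continuity correction
    n <- length(r)
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- v - mu
    cc <- 0.5
    p <- switch(alternative,
      greater = pnorm((z - cc) / sqrt(sigma2), lower.tail = FALSE),
      less = pnorm((z + cc) / sqrt(sigma2)),
      two.sided = {
        zc <- (abs(z) - cc) / sqrt(sigma2)
        min(2 * pnorm(zc, lower.tail = FALSE), 1)
      })
    method <- "normal approximation"
  }
  tibble::tibble(
    statistic = v, p = p, n_pairs = n_eff,
    n_zero_dropped = if (zero_method == "wilcox") n_zero else 0L,
    method = method
  )
}

## Exact signed-rank tail probability under random sign flips, by dynamic
## programming over the (doubled, hence integer) rank sum; correct under
## tied absolute differences, where wilcox.test falls back to the normal
## approximation.
exact_signed_rank_p <- function(v, ranks, alternative) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  coefs <- numeric(total + 1)
  coefs[1] <- 1
  for (rr in r2) {
    shifted <- c(numeric(rr), coefs[seq_len(total + 1 - rr)])
    coefs <- coefs + shifted
  }
  probs <- coefs / 2^length(r2)
  v2 <- as.integer(round(2 * v))
  p_ge <- sum(probs[(v2 + 1):(total + 1)])
  p_le <- sum(probs[seq_len(v2 + 1)])
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(2 * min(p_ge, p_le), 1))
}

#' Summarize an optogenetic session: window metrics plus paired tests
#'
#' Runs [window_metrics()] and then a [paired_test()] per ROI and metric.
#' By default each stimulation event is one statistical unit; set
#' `by_fish` aggregation upstream for a per-fish sensitivity analysis.
#'
#' @param session A [stim_session()].
#' @param tail Tail passed to [paired_test()].
#' @return A tibble with one row per `(roi, metric)`: `statistic`, `p`,
#'   `n_pairs`.
#' @export
opto_summary <- function(session, tail = "two") {
  wm <- window_metrics(session)
  purrr::map_dfr(unique(wm$roi), function(r) {
    sub <- dplyr::filter(wm, .data$roi == r)
    purrr::map_dfr(c("mean", "sum", "max"), function(metric) {
      res <- paired_test(sub[[paste0("pre_", metric)]],
                         sub[[paste0("post_", metric)]], tail = tail)
      dplyr::mutate(res, roi = r, metric = metric, .before = 1)
    })
  })
}
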