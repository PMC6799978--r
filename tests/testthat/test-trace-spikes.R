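test_that("a flat trace yields an empty spike train", {
  out <- detect_spikes(rep(0, 600), fps = 1)
  expect_identical(nrow(out), 0L)
})

test_that("injected 6x-noise transients are found at the right frames with no extras", {
  frames <- seq(30, 570, by = 30)  # 19 transients
  res <- vapply(1:5, function(s) {
    x <- transient_trace(600, 1, frames, amp = 0.12, tau_s = 1.5,
                         noise_sd = 0.02, seed = 300 + s)
    spk <- detect_spikes(x, fps = 1)
    hits <- vapply(frames - 1, function(f) any(abs(spk$time - f) <= 1),
                   logical(1))
    extras <- sum(vapply(spk$time, function(t0) all(abs(t0 - (frames - 1)) > 2),
                         logical(1)))
    c(hits = sum(hits), extras = extras)
  }, numeric(2))
  recall <- sum(res["hits", ]) / (5 * length(frames))
  expect_gte(recall, 0.95)
  expect_identical(sum(res["extras", ]), 0)
})

test_that("pure-noise traces stay almost spike-free at k_mad = 5", {
  fp <- vapply(1:10, function(s) {
    x <- transient_trace(600, 1, integer(0), amp = 0, tau_s = 1,
                         noise_sd = 0.02, seed = 400 + s)
    nrow(detect_spikes(x, fps = 1, k_mad = 5))
  }, integer(1))
  expect_lt(sum(fp) / (10 * 10), 0.1)  # false positives per minute
})

test_that("spike count is monotone non-increasing in k_mad and shift-equivariant", {
  x <- transient_trace(600, 1, seq(50, 550, by = 50), amp = 0.1, tau_s = 2,
                       noise_sd = 0.02, seed = 12)
  counts <- vapply(c(2, 3.5, 5, 8, 12), function(k) {
    nrow(detect_spikes(x, fps = 1, k_mad = k))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  shift <- 37
  spk <- detect_spikes(x, fps = 1)
  spk_sh <- detect_spikes(c(rep(0, shift), x)[1:600], fps = 1)
  keep <- spk$time + shift <= 580
  expect_true(all((spk$time[keep] + shift) %in% spk_sh$time))
})

test_that("amplitudes are positive and times strictly increasing", {
  x <- transient_trace(900, 2, seq(60, 840, by = 60), amp = 0.15, tau_s = 2,
                       noise_sd = 0.02, seed = 5)
  spk <- detect_spikes(x, fps = 2)
  expect_gt(nrow(spk), 5)
  expect_true(all(spk$amplitude > 0))
  expect_true(all(diff(spk$time) > 0))
})

test_that("epoch metrics match the stated arithmetic and a brute-force oracle", {
  n <- 1200; fps <- 2
  dff <- matrix(0, n, 1, dimnames = list(NULL, "lLH"))
  ts <- trace_set(dff = dff, fps = fps,
                  epochs = list(baseline = c(0, 300), water = c(300, 600)))
  spk <- new_spikes <- tibble::tibble(
    roi = "lLH", time = seq(10, 290, length.out = 15), amplitude = rep(0.2, 15)
  )
  got <- epoch_metrics(ts, spk, "baseline")
  expect_identical(got$freq, 3)  # 15 spikes in 5 minutes
  expect_identical(got$sum_dff, 0)
  expect_identical(got$amp, 0.2)
  w <- epoch_metrics(ts, spk, "water")
  expect_identical(w$n_spikes, 0L)
  expect_true(is.na(w$amp))

  withr::with_seed(9, {
    dff2 <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "lLH"))
    ts2 <- trace_set(dff = dff2, fps = fps,
                     epochs = list(para = c(130.2, 412.7)))
    tms <- sort(runif(40, 0, 600)); amps <- runif(40, 0.1, 1)
    spk2 <- tibble::tibble(roi = "lLH", time = tms, amplitude = amps)
    got2 <- epoch_metrics(ts2, spk2, "para")
    # brute-force loop oracle
    acc <- 0
    for (i in seq_len(n)) {
      t0 <- (i - 1) / fps
      if (t0 >= 130.2 - 1e-9 && t0 < 412.7) acc <- acc + dff2[i, 1]
    }
    sel <- tms >= 130.2 & tms < 412.7
    expect_equal(got2$sum_dff, unname(acc), tolerance = 1e-10)
    expect_equal(got2$freq, sum(sel) / ((412.7 - 130.2) / 60),
                 tolerance = 1e-12)
    expect_equal(got2$amp, mean(amps[sel]), tolerance = 1e-12)
  })
})

test_that("self-triggered averages peak at lag zero; sign flips invert the trough", {
  x <- transient_trace(1200, 2, seq(100, 1100, by = 120), amp = 0.3,
                       tau_s = 2, noise_sd = 0.01, seed = 20)
  spk <- detect_spikes(x, fps = 2)
  sta <- spike_triggered_average(spk, x, 2, window_s = c(15, 15))
  expect_equal(sta$lag[which.max(sta$mean)], 0, tolerance = 1e-9)
  sta_neg <- spike_triggered_average(spk, -x, 2, window_s = c(15, 15))
  expect_equal(sta_neg$lag[which.min(sta_neg$mean)], 0, tolerance = 1e-9)
  expect_equal(sta_neg$mean, -sta$mean, tolerance = 1e-12)
})

test_that("independent-noise targets stay inside 3 sem at nearly all lags", {
  x <- transient_trace(3000, 2, seq(50, 1400, by = 13), amp = 0.3,
                       tau_s = 2, noise_sd = 0.01, seed = 21)
  spk <- detect_spikes(x, fps = 2, min_separation_s = 3)
  expect_gt(nrow(spk), 90)
  withr::with_seed(22, target <- rnorm(3000, 0, 0.05))
  sta <- spike_triggered_average(spk, target, 2, window_s = c(10, 10))
  expect_gte(mean(abs(sta$mean) < 3 * sta$sem), 0.95)
})

test_that("clipped windows are dropped and counted; no usable trigger errors", {
  spk <- tibble::tibble(roi = "r", time = c(2, 50), amplitude = c(1, 1))
  sta <- spike_triggered_average(spk, rnorm(200), 1, window_s = c(10, 10))
  expect_identical(attr(sta, "n_used"), 1L)
  expect_identical(attr(sta, "n_dropped"), 1L)
  spk0 <- tibble::tibble(roi = "r", time = 1, amplitude = 1)
  expect_error(spike_triggered_average(spk0, rnorm(30), 1,
                                       window_s = c(10, 10)),
               "full window")
})
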