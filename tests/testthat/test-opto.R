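const_session <- function(value = 0.2, n = 2400, fps = 2) {
  dff <- matrix(value, n, 1, dimnames = list(NULL, "lLH"))
  ts <- trace_set(dff = dff, fps = fps)
  stim_session(ts, data.frame(onset_s = 120 + (0:4) * 210, duration_s = 10),
               window_s = 90)
}

test_that("constant traces give identical pre and post metrics", {
  wm <- window_metrics(const_session())
  expect_equal(wm$pre_mean, wm$post_mean, tolerance = 1e-12)
  expect_equal(wm$pre_sum, wm$post_sum, tolerance = 1e-12)
  expect_equal(wm$pre_max, wm$post_max, tolerance = 1e-12)
})

test_that("stimulation frames are excluded and clipped pulses dropped", {
  n <- 800; fps <- 2
  dff <- matrix(0, n, 1, dimnames = list(NULL, "lLH"))
  # mark the stimulation frames of a pulse at 120 s with a huge artifact
  stim_frames <- (120 * fps + 1):(130 * fps)
  dff[stim_frames, 1] <- 100
  ts <- trace_set(dff = dff, fps = fps)
  s <- stim_session(ts, data.frame(onset_s = 120, duration_s = 10),
                    window_s = 90)
  wm <- window_metrics(s)
  expect_identical(wm$pre_max, 0)
  expect_identical(wm$post_max, 0)

  s2 <- stim_session(trace_set(dff = dff, fps = fps),
                     data.frame(onset_s = 30, duration_s = 10),
                     window_s = 90)
  wm2 <- window_metrics(s2)
  expect_identical(nrow(wm2), 0L)
  expect_identical(attr(wm2, "n_excluded"), 1L)
})

test_that("metrics are invariant to appending data outside all windows", {
  withr::with_seed(1, {
    n <- 700; fps <- 2
    dff <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "lLH"))
    s1 <- stim_session(trace_set(dff = dff, fps = fps),
                       data.frame(onset_s = 120, duration_s = 10), 90)
    dff2 <- rbind(dff, matrix(rnorm(100), 100, 1,
                              dimnames = list(NULL, "lLH")))
    s2 <- stim_session(trace_set(dff = dff2, fps = fps),
                       data.frame(onset_s = 120, duration_s = 10), 90)
    expect_equal(window_metrics(s1), window_metrics(s2),
                 ignore_attr = TRUE, tolerance = 1e-15)
  })
})

test_that("the exact one-sided signed-rank p for a uniform shift is 2^-n", {
  pre <- as.numeric(1:10)
  res <- paired_test(pre, pre + 1, tail = "one-greater")
  expect_equal(res$p, 1 / 2^10, tolerance = 1e-12)
  expect_identical(res$method, "exact")
})

test_that("identical pairs give p = 1 with a warning", {
  expect_warning(res <- paired_test(1:8, 1:8), "zero")
  expect_identical(res$p, 1)
})

test_that("swapping pre/post with the flipped tail gives the same p", {
  withr::with_seed(2, {
    pre <- rnorm(14); post <- pre + rnorm(14, 0.3)
    a <- paired_test(pre, post, tail = "one-greater")
    b <- paired_test(post, pre, tail = "one-less")
    expect_equal(a$p, b$p, tolerance = 1e-12)
  })
})

test_that("zero differences are dropped before ranking by default", {
  pre <- c(1, 2, 3, 4, 5, 6)
  post <- c(1, 2, 3, 5.5, 6.5, 7.5)
  res <- paired_test(pre, post, tail = "one-greater")
  expect_identical(res$n_pairs, 3L)
  expect_identical(res$n_zero_dropped, 3L)
})

test_that("suppression sessions show post < pre and a significant one-tailed test", {
  pulses <- data.frame(onset_s = 90 + (0:29) * 190, duration_s = 10)
  m <- latent_model(n_regions = 1, latent_corr = diag(1),
                    region_names = "lLH", seed = 31)
  g <- generate_opto_session(m, pulses, effect = 0.3)
  g$session$ts <- compute_dff(g$session$ts)
  wm <- window_metrics(g$session)
  expect_gte(mean(wm$post_sum < wm$pre_sum), 0.95)
  res <- paired_test(wm$pre_sum, wm$post_sum, tail = "one-less")
  expect_lt(res$p, 0.05)
})

test_that("null sessions split post vs pre evenly", {
  pulses <- data.frame(onset_s = 90 + (0:19) * 190, duration_s = 10)
  fr <- vapply(1:4, function(s) {
    m <- latent_model(n_regions = 1, latent_corr = diag(1),
                      region_names = "lLH", seed = 600 + s)
    g <- generate_opto_session(m, pulses, effect = 1)
    g$session$ts <- compute_dff(g$session$ts)
    wm <- window_metrics(g$session)
    mean(wm$post_sum < wm$pre_sum)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 0.15)
})

test_that("opto_summary reports one test per roi and metric", {
  s <- const_session()
  res <- suppressWarnings(opto_summary(s))
  expect_identical(nrow(res), 3L)
  expect_setequal(res$metric, c("mean", "sum", "max"))
  expect_true(all(res$p == 1))  # constant trace: degenerate pairs
})
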