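const_stack <- function(value, shape = c(4, 8, 8), bg = NULL) {
  img <- array(value, shape)
  masks <- list(roi = slab_mask(shape, margin = 2))
  if (!is.null(bg)) {
    img[, 1:2, ] <- bg
    m <- array(FALSE, shape); m[, 1:2, ] <- TRUE
    masks$background <- m
  }
  list(stack = stained_stack(list(pERK = img)),
       rois = roi_set(masks))
}

test_that("roi mean is the plain mean, minus background when requested", {
  s <- const_stack(7)
  expect_identical(roi_mean_intensity(s$stack, s$rois, "roi"), 7)
  s2 <- const_stack(7, bg = 2)
  expect_identical(
    roi_mean_intensity(s2$stack, s2$rois, "roi", subtract_background = TRUE),
    5
  )
})

test_that("roi mean equals a brute-force voxel loop on random stacks", {
  withr::with_seed(10, {
    shape <- c(6, 20, 20)
    img <- array(runif(prod(shape), 0, 100), shape)
    mask <- array(runif(prod(shape)) < 0.3, shape)
    mask[1, 1, 1] <- TRUE
    st <- stained_stack(list(pERK = img))
    rs <- roi_set(list(roi = mask))
    acc <- 0; n <- 0
    for (z in 1:shape[1]) for (y in 1:shape[2]) for (x in 1:shape[3]) {
      if (mask[z, y, x]) { acc <- acc + img[z, y, x]; n <- n + 1 }
    }
    expect_equal(roi_mean_intensity(st, rs, "roi"), acc / n,
                 tolerance = 1e-12)
  })
})

test_that("z-range restriction selects only the declared planes", {
  shape <- c(4, 6, 6)
  img <- array(0, shape); img[1:2, , ] <- 10; img[3:4, , ] <- 2
  m <- array(TRUE, shape)
  rs <- roi_set(list(cH = m), z_range = list(cH = c(3, 4)))
  st <- stained_stack(list(pERK = img))
  expect_identical(roi_mean_intensity(st, rs, "cH"), 2)
})

test_that("control normalization fixes the control mean at 1 and is scale-free", {
  cc <- 3.7
  out <- normalize_to_control(c(cc, cc, cc), c(cc, cc))
  expect_identical(out$normalized, c(1, 1, 1))
  out2 <- normalize_to_control(2 * cc, c(cc, cc, cc))
  expect_identical(out2$normalized, 2)
  withr::with_seed(3, {
    v <- runif(20, 1, 5); ctl <- runif(8, 1, 5)
    base <- normalize_to_control(v, ctl)$normalized
    expect_equal(base, v / mean(ctl), tolerance = 1e-15)
    scaled <- normalize_to_control(7 * v, 7 * ctl)$normalized
    expect_equal(scaled, base, tolerance = 1e-12)
    expect_equal(mean(normalize_to_control(ctl, ctl)$normalized), 1,
                 tolerance = 1e-15)
  })
  expect_error(normalize_to_control(1:3, numeric(0)), "non-empty")
  expect_error(normalize_to_control(1:3, c(1e-20, -1e-20)), "degenerate")
})

test_that("perk_at_points returns the constant on constant images and the voxel at radius 0", {
  s <- const_stack(4.25)
  pts <- rbind(c(1, 3, 3), c(2, 5, 5))
  expect_identical(perk_at_points(s$stack, pts, 3)$mean_perk, c(4.25, 4.25))
  withr::with_seed(4, {
    shape <- c(4, 10, 10)
    img <- array(runif(prod(shape)), shape)
    st <- stained_stack(list(pERK = img))
    expect_identical(perk_at_points(st, rbind(c(2, 4, 7)), 0)$mean_perk,
                     img[3, 5, 8])
    # brute-force neighborhood scan oracle
    p <- c(1, 5, 5); r_um <- 2
    vs <- st$voxel_size
    acc <- c(); n <- 0
    for (z in 1:shape[1]) for (y in 1:shape[2]) for (x in 1:shape[3]) {
      d2 <- ((z - 1 - p[1]) * vs[1])^2 + ((y - 1 - p[2]) * vs[2])^2 +
        ((x - 1 - p[3]) * vs[3])^2
      if (d2 <= r_um^2 + 1e-9) acc <- c(acc, img[z, y, x])
    }
    expect_equal(perk_at_points(st, rbind(p), r_um)$mean_perk, mean(acc),
                 tolerance = 1e-12)
  })
  expect_error(perk_at_points(s$stack, rbind(c(0, 0, 99)), 1), "out of bounds")
})

test_that("theta ratio follows the difference-of-means definition", {
  ctl <- c(1, 2, 3); para <- c(4, 5, 6)
  expect_identical(theta_ratio(para, ctl, para)$ratio, 1)
  r0 <- theta_ratio(ctl, ctl, para)
  expect_identical(r0$theta_A, 0)
  expect_identical(r0$ratio, 0)
  withr::with_seed(5, {
    a <- rnorm(9); c0 <- rnorm(9); p <- rnorm(11)
    got <- theta_ratio(a, c0, p)
    expect_equal(got$theta_A, mean(a) - mean(c0), tolerance = 1e-15)
    expect_equal(got$theta_P, mean(p) - mean(c0), tolerance = 1e-15)
    expect_equal(got$ratio, (mean(a) - mean(c0)) / (mean(p) - mean(c0)),
                 tolerance = 1e-12)
    # invariant to adding a constant to all three groups
    shifted <- theta_ratio(a + 11, c0 + 11, p + 11)
    expect_equal(shifted$ratio, got$ratio, tolerance = 1e-9)
  })
  und <- theta_ratio(c(1, 2), c(0, 0), c(1e-14, -1e-14))
  expect_true(is.na(und$ratio))
  expect_false(is.na(und$theta_A))
})
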