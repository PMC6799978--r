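arc_points <- function(theta_total, n_pts = 41, radius = 1) {
  ang <- seq(0, theta_total, length.out = n_pts)
  cbind(radius * sin(ang), radius * (1 - cos(ang)))
}

test_that("a straight tail with neutral gaze featurizes to the zero vector", {
  pts <- cbind(seq(0, 1, length.out = 30), 0)
  v <- featurize_bout(pts, matrix(0, 10, 2))
  expect_length(v, 220)
  expect_lt(max(abs(v)), 1e-9)
})

test_that("a circular arc gives 20 equal tangent angles of theta/20", {
  theta <- 0.8
  pts <- arc_points(theta)
  v <- featurize_bout(pts, matrix(0, 10, 2))
  first_frame <- v[1:20]
  expect_equal(first_frame, rep(theta / 20, 20), tolerance = 1e-6)
})

test_that("featurization is rotation-invariant and mirror-equivariant", {
  withr::with_seed(11, {
    ang <- cumsum(c(0, rnorm(29, 0, 0.1)))
    pts <- cbind(cumsum(cos(ang)), cumsum(sin(ang)))
    pts <- rbind(c(0, 0), pts)
    eyes <- matrix(runif(20, -10, 10), 10, 2)
    v <- featurize_bout(pts, eyes)
    phi <- 0.7
    rot <- cbind(c(cos(phi), sin(phi)), c(-sin(phi), cos(phi)))
    v_rot <- featurize_bout(pts %*% t(rot), eyes, body_axis = phi)
    expect_equal(v_rot, v, tolerance = 1e-9)
    mirrored <- cbind(pts[, 1], -pts[, 2])
    v_mir <- featurize_bout(mirrored, -eyes)
    tails <- as.vector(sapply(0:9, function(f) f * 22 + 1:20))
    expect_equal(v_mir, -v, tolerance = 1e-9)
  })
})

test_that("too few frames or skeleton points are rejected by name", {
  pts <- cbind(seq(0, 1, length.out = 10), 0)  # only 10 points
  expect_error(featurize_bout(pts, matrix(0, 10, 2), bout_id = "bout_7"),
               "bout_7")
  ok_pts <- cbind(seq(0, 1, length.out = 25), 0)
  expect_error(
    featurize_bout(rep(list(ok_pts), 4), matrix(0, 10, 2), bout_id = "b2"),
    "b2"
  )
})

test_that("separated clusters stay separated by the default embedding", {
  withr::with_seed(12, {
    f1 <- matrix(rnorm(30 * 220, 0, 0.2), 30)
    f2 <- matrix(rnorm(30 * 220, 0, 0.2), 30)
    f2[, 1:40] <- f2[, 1:40] + 3
    feats <- rbind(f1, f2)
    emb <- embed_bouts(feats, seed = 1)
    xy <- as.matrix(emb)
    lab <- rep(1:2, each = 30)
    # silhouette of the known partition
    sil <- vapply(seq_len(60), function(i) {
      d <- sqrt(rowSums(sweep(xy, 2, xy[i, ])^2))
      a <- mean(d[lab == lab[i]][d[lab == lab[i]] > 0])
      b <- mean(d[lab != lab[i]])
      (b - a) / max(a, b)
    }, numeric(1))
    expect_gt(mean(sil), 0.5)
    # duplicates land together; same seed reproduces
    feats2 <- rbind(feats, feats[1, , drop = FALSE])
    emb2 <- embed_bouts(feats2, seed = 1)
    expect_equal(unlist(emb2[61, ]), unlist(emb2[1, ]), tolerance = 1e-8)
    expect_identical(embed_bouts(feats, seed = 1), embed_bouts(feats, seed = 1))
  })
})

test_that("hunting probability handles all-or-none bins and bin bookkeeping", {
  b <- tibble::tibble(bout_start = runif(50, 0, 45 * 60), hunting = TRUE)
  bs <- hunting_probability(b)
  expect_true(all(bs$p_hat[bs$n_bouts > 0] == 1))
  expect_true(all(bs$ci_hi[bs$n_bouts > 0] == 1))
  b0 <- tibble::tibble(bout_start = seq(10, 170, length.out = 10),
                       hunting = FALSE)
  bs0 <- hunting_probability(b0)
  expect_identical(bs0$p_hat[1], 0)
  expect_identical(bs0$ci_lo[1], 0)
  expect_true(all(is.na(bs0$p_hat[-1])))
  expect_identical(sum(bs0$n_bouts), 10L)
})

test_that("bin CIs cover the generating rate on a synthetic stream", {
  g <- generate_bout_stream(0.2, 0.3, 2700, seed = 14)  # one fish, ~54/bin
  bs <- hunting_probability(g$bouts)
  covered <- mean(bs$ci_lo <= 0.2 & 0.2 <= bs$ci_hi)
  expect_gte(covered, 0.85)
})

test_that("labels map onto the hunting set configurably", {
  b <- tibble::tibble(
    bout_start = c(10, 20, 30, 40, 50),
    label = c("j-turn", "pursuit", "abort", "strike", "exploratory")
  )
  bs <- hunting_probability(b, bin_min = 1, horizon_min = 1)
  expect_identical(bs$n_hunting, 4L)
  bs2 <- hunting_probability(b, bin_min = 1, horizon_min = 1,
                             hunting_labels = c("j-turn", "pursuit", "strike"))
  expect_identical(bs2$n_hunting, 3L)
})

test_that("per-bin Fisher tests match hypergeometric enumeration", {
  a <- tibble::tibble(n_hunting = c(10, 5), n_bouts = c(10, 10))
  b <- tibble::tibble(n_hunting = c(0, 5), n_bouts = c(10, 10))
  p <- per_bin_fisher(a, b)
  # [[10,0],[0,10]]: both extreme tables, 2 / choose(20, 10)
  expect_equal(p$p[1], 2 / choose(20, 10), tolerance = 1e-12)
  expect_identical(p$p[2], 1)
})

test_that("gut fluorescence is background-invariant and additive", {
  g <- generate_gut_image(600, background_sd = 0, seed = 21)
  base <- gut_fluorescence(g$image, g$gut_mask, g$background_mask)
  raised <- gut_fluorescence(g$image + 5, g$gut_mask, g$background_mask)
  expect_equal(base$integrated, raised$integrated, tolerance = 1e-9)
  expect_identical(gut_fluorescence(array(3, c(1, 20, 20)),
                                    slab_mask(c(1, 20, 20), margin = 7),
                                    !slab_mask(c(1, 20, 20), margin = 2))$integrated,
                   0)
  # additivity: deposits in disjoint halves sum
  img <- array(10, c(1, 40, 40))
  m1 <- array(FALSE, dim(img)); m1[1, 5:15, 5:35] <- TRUE
  m2 <- array(FALSE, dim(img)); m2[1, 25:35, 5:35] <- TRUE
  bgm <- array(FALSE, dim(img)); bgm[1, 18:22, ] <- TRUE
  imgA <- img; imgA[1, 10, 10] <- 10 + 120
  imgB <- img; imgB[1, 30, 30] <- 10 + 80
  both <- img; both[1, 10, 10] <- 130; both[1, 30, 30] <- 90
  gm <- m1 | m2
  sA <- gut_fluorescence(imgA, gm, bgm)$integrated
  sB <- gut_fluorescence(imgB, gm, bgm)$integrated
  sBoth <- gut_fluorescence(both, gm, bgm)$integrated
  expect_equal(sBoth, sA + sB, tolerance = 1e-9)
})
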