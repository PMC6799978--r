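test_that("movie downsampling at cell size 1 is the identity", {
  withr::with_seed(1, {
    mv <- array(rnorm(20 * 4 * 6), c(20, 4, 6))
    out <- downsample_movie(mv, 1)
    expect_identical(ncol(out$traces), 24L)
    expect_equal(out$traces[, 1], mv[, 1, 1], tolerance = 1e-15)
  })
})

test_that("downsampling matches a block-mean oracle and keeps constants", {
  cst <- array(2.5, c(12, 6, 6))
  expect_true(all(downsample_movie(cst, 3)$traces == 2.5))
  withr::with_seed(4, {
    mv <- array(rnorm(10 * 6 * 9), c(10, 6, 9))
    out <- downsample_movie(mv, 3)
    oracle <- sapply(0:2, function(bx) sapply(0:1, function(by) {
      rowMeans(matrix(mv[, (3 * by + 1):(3 * by + 3),
                         (3 * bx + 1):(3 * bx + 3)], 10))
    }))
    expect_equal(out$traces, matrix(oracle, 10), tolerance = 1e-12)
  })
})

test_that("tiles outside the region map are dropped; labels use the majority", {
  mv <- array(1, c(15, 4, 4))
  rmap <- matrix(NA_character_, 4, 4)
  rmap[1:2, 1:2] <- "cH"
  rmap[1, 3] <- "cH"; rmap[2:4, 3:4] <- "lLH"
  out <- downsample_movie(mv, 2, rmap)
  expect_identical(ncol(out$traces), 3L)
  expect_identical(sort(unique(out$labels)), c("cH", "lLH"))
})

test_that("the correlogram has unit diagonal, -1 for a negation, and drops flats", {
  withr::with_seed(5, {
    x <- rnorm(60)
    tr <- cbind(x, -x, rnorm(60))
    cm <- crosscorrelogram(tr, c("a", "a", "b"))
    expect_equal(diag(cm$r), rep(1, 3), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(cm$r[1, 2], -1, tolerance = 1e-12)
    tr2 <- cbind(x, rep(3, 60), rnorm(60))
    expect_warning(cm2 <- crosscorrelogram(tr2, c("a", "a", "b")),
                   "zero-variance")
    expect_identical(length(cm2$labels), 2L)
  })
})

test_that("correlations are invariant to positive affine transforms per voxel", {
  withr::with_seed(6, {
    tr <- matrix(rnorm(50 * 4), 50)
    cm1 <- crosscorrelogram(tr, rep(c("a", "b"), 2))
    tr2 <- sweep(sweep(tr, 2, c(2, 0.5, 7, 1.3), `*`), 2, c(1, -4, 0, 9), `+`)
    cm2 <- crosscorrelogram(tr2, rep(c("a", "b"), 2))
    expect_equal(cm1$r, cm2$r, tolerance = 1e-12)
  })
})

test_that("rank-1 enrichment is forced to 1/f when every minimum partner is in one region", {
  # 3 voxels in A, 2 in B; construct r so every voxel's most negative
  # partner is in B
  labs <- c("A", "A", "A", "B", "B")
  r <- matrix(0.5, 5, 5); diag(r) <- 1
  r[1:3, 4] <- r[4, 1:3] <- -0.9
  r[4, 5] <- r[5, 4] <- -0.95
  cm <- structure(list(r = r, labels = labs, coords = NULL),
                  class = "corr_map")
  rs <- anticorr_rank_stat(cm, max_rank = 1)
  a_to_b <- rs[rs$source == "A" & rs$target == "B", ]
  expect_identical(a_to_b$prob, 1)
  expect_identical(a_to_b$chance, 0.5)  # 2 of 4 non-self voxels
  expect_identical(a_to_b$ratio, 2)
})

test_that("rank statistics match a brute-force sort-and-count oracle", {
  withr::with_seed(8, {
    nv <- 40
    m <- matrix(rnorm(nv * nv), nv); m <- (m + t(m)) / 2; diag(m) <- 1
    labs <- sample(c("cH", "mLH", "lLH"), nv, replace = TRUE)
    cm <- structure(list(r = m, labels = labs, coords = NULL),
                    class = "corr_map")
    rs <- anticorr_rank_stat(cm, max_rank = 4)
    for (src in unique(labs)) for (tgt in unique(labs)) for (rk in 1:4) {
      hits <- 0; srcs <- which(labs == src)
      for (i in srcs) {
        ord <- order(m[i, -i])
        partner <- (seq_len(nv)[-i])[ord][rk]
        if (labs[partner] == tgt) hits <- hits + 1
      }
      prob <- hits / length(srcs)
      chance <- mean((sum(labs == tgt) - (labs[srcs] == tgt)) / (nv - 1))
      got <- rs[rs$source == src & rs$target == tgt & rs$rank == rk, ]
      expect_equal(got$prob, prob, tolerance = 1e-12)
      expect_equal(got$ratio, prob / chance, tolerance = 1e-12)
    }
  })
})

test_that("per-source probabilities sum to one over targets at each rank", {
  withr::with_seed(9, {
    nv <- 30
    m <- matrix(rnorm(nv * nv), nv); m <- (m + t(m)) / 2; diag(m) <- 1
    labs <- rep(c("a", "b", "c"), each = 10)
    cm <- structure(list(r = m, labels = labs, coords = NULL),
                    class = "corr_map")
    rs <- anticorr_rank_stat(cm, max_rank = 5)
    sums <- dplyr::summarise(dplyr::group_by(rs, source, rank),
                             total = sum(prob), .groups = "drop")
    expect_equal(sums$total, rep(1, nrow(sums)), tolerance = 1e-12)
  })
})

test_that("relabeling voxels within a region leaves the statistic unchanged", {
  withr::with_seed(10, {
    nv <- 24
    m <- matrix(rnorm(nv * nv), nv); m <- (m + t(m)) / 2; diag(m) <- 1
    labs <- rep(c("a", "b"), each = 12)
    cm <- structure(list(r = m, labels = labs, coords = NULL),
                    class = "corr_map")
    rs1 <- anticorr_rank_stat(cm, max_rank = 3)
    # permute voxels within region a (consistent row/col permutation)
    perm <- c(sample(1:12), 13:24)
    cm2 <- structure(list(r = m[perm, perm], labels = labs[perm],
                          coords = NULL), class = "corr_map")
    rs2 <- anticorr_rank_stat(cm2, max_rank = 3)
    expect_equal(rs1$prob, rs2$prob, tolerance = 1e-12)
  })
})

test_that("degenerate single-region input is rejected", {
  m <- diag(4)
  cm <- structure(list(r = m, labels = rep("a", 4), coords = NULL),
                  class = "corr_map")
  expect_error(anticorr_rank_stat(cm, max_rank = 2), "2 regions")
})
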