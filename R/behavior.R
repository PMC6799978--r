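## Bout posture featurization, embedding hook, binned hunting-probability
## statistics and gut-fluorescence food intake.

wrap_angle <- function(a) atan2(sin(a), cos(a))

## Resample an ordered 2-D polyline to n_points equally spaced by arc length.
resample_polyline <- function(pts, n_points) {
  seg <- sqrt(rowSums(diff(pts)^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    pts <- pts[keep, , drop = FALSE]
    seg <- sqrt(rowSums(diff(pts)^2))
  }
  if (nrow(pts) < 2) abort("Skeleton degenerate: all points coincide.")
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = n_points)
  cbind(approx(s, pts[, 1], xout = target)$y,
        approx(s, pts[, 2], xout = target)$y)
}

#' Featurize a swim bout into posture space
#'
#' Accumulates 22 posture measurements — 20 tail tangent angles encoding
#' tail shape plus the two eye gaze angles — across the first `n_frames`
#' frames of a bout (10 frames, ~167 ms at 60 Hz, by default), yielding a
#' `22 * n_frames`-dimensional vector (220 by default).
#'
#' The skeleton of each frame is resampled to `n_segments + 1` points
#' equally spaced by arc length; tangent angles are the successive direction
#' changes along the resampled skeleton, the first taken relative to the
#' body axis of that frame. A straight tail aligned with the body axis gives
#' all-zero angles; mirror reflection negates them.
#'
#' @param tail_points List of per-frame numeric matrices (ordered skeleton
#'   points, columns x and y, rostral to caudal; at least `n_segments + 1`
#'   rows each), or a single matrix reused for all frames.
#' @param eye_angles Numeric `n_frames x 2` matrix of (left, right) gaze
#'   angles in degrees.
#' @param body_axis Per-frame body-axis direction in radians (scalar
#'   recycled; default 0, i.e. tracker-aligned frames).
#' @param n_frames Frames accumulated from bout start (default 10).
#' @param n_segments Number of tail segments (default 20).
#' @param bout_id Identifier used in error messages.
#' @return Numeric vector of length `(n_segments + 2) * n_frames`,
#'   frame-major: 20 tangent angles (radians) then 2 gaze angles (radians)
#'   per frame.
#' @export
featurize_bout <- function(tail_points, eye_angles, body_axis = 0,
                           n_frames = 10, n_segments = 20,
                           bout_id = "bout") {
  if (is.matrix(tail_points)) {
    tail_points <- rep(list(tail_points), n_frames)
  }
  if (length(tail_points) < n_frames) {
    abort(sprintf("Bout '%s': %d frames supplied, %d required.",
                  bout_id, length(tail_points), n_frames))
  }
  eye_angles <- matrix(as.numeric(eye_angles), ncol = 2)
  if (nrow(eye_angles) < n_frames) {
    abort(sprintf("Bout '%s': eye angles cover %d frames, %d required.",
                  bout_id, nrow(eye_angles), n_frames))
  }
  body_axis <- rep_len(body_axis, n_frames)
  out <- numeric(0)
  for (fr in seq_len(n_frames)) {
    pts <- tail_points[[fr]]
    if (nrow(pts) < n_segments + 1) {
      abort(sprintf("Bout '%s' frame %d: %d skeleton points, need >= %d.",
                    bout_id, fr, nrow(pts), n_segments + 1))
    }
    rs <- resample_polyline(pts, n_segments + 1)
    ## tangent direction at each non-base point: central difference in the
    ## interior, second-order one-sided extrapolation at the tail tip (exact
    ## on circular arcs)
    np <- n_segments + 1
    tang <- numeric(n_segments)
    for (k in 2:(np - 1)) {
      tang[k - 1] <- atan2(rs[k + 1, 2] - rs[k - 1, 2],
                           rs[k + 1, 1] - rs[k - 1, 1])
    }
    last_chord <- atan2(rs[np, 2] - rs[np - 1, 2], rs[np, 1] - rs[np - 1, 1])
    tang[n_segments] <- tang[n_segments - 1] +
      2 * wrap_angle(last_chord - tang[n_segments - 1])
    ref <- c(body_axis[fr], tang[-n_segments])
    ang <- wrap_angle(tang - ref)
    out <- c(out, ang, eye_angles[fr, ] * pi / 180)
  }
  out
}

#' Embed bout feature vectors into two dimensions
#'
#' The embedding method is an injected dependency satisfying a
#' fit-transform contract: a function `(matrix, seed) -> n x 2 matrix`.
#' The default projects onto the first two principal components, which is
#' deterministic; a t-SNE implementation can be plugged in unchanged.
#'
#' @param features Bout-by-dimension numeric matrix (>= 10 bouts, finite).
#' @param method Embedding function `(features, seed)`; default PCA.
#' @param seed Seed forwarded to the method.
#' @return A tibble with columns `dim1`, `dim2`.
#' @export
embed_bouts <- function(features, method = embed_pca, seed = 1L) {
  stopifnot(is.matrix(features))
  if (nrow(features) < 10) abort("Need at least 10 bouts to embed.")
  if (!all(is.finite(features))) abort("Features must be finite.")
  xy <- method(features, seed)
  stopifnot(ncol(xy) == 2, nrow(xy) == nrow(features))
  tibble::tibble(dim1 = xy[, 1], dim2 = xy[, 2])
}

#' @rdname embed_bouts
#' @export
embed_pca <- function(features, seed = 1L) {
  ctr <- scale(features, scale = FALSE)
  sv <- svd(ctr, nu = 2, nv = 0)
  xy <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
  ## deterministic sign: largest-|loading| coordinate positive
  for (j in 1:2) if (xy[which.max(abs(xy[, j])), j] < 0) xy[, j] <- -xy[, j]
  xy
}

#' Binned hunting-bout probability with exact binomial intervals
#'
#' Fraction of bouts that are hunting-related per time bin (3 min bins over
#' 45 min by default) with a two-sided exact Clopper-Pearson confidence
#' interval (90 % by default).
#'
#' @param bouts Tibble with `bout_start` (s) and either a logical `hunting`
#'   column or a `label` column; labels in `hunting_labels` count as
#'   hunting.
#' @param bin_min Bin width in minutes (default 3).
#' @param horizon_min Total horizon in minutes (default 45).
#' @param conf Confidence level (default 0.90).
#' @param hunting_labels Labels counted as hunting-related.
#' @return A `bin_stats` tibble: `bin_start` (min), `n_bouts`, `n_hunting`,
#'   `p_hat`, `ci_lo`, `ci_hi` (empty bins report `NA`).
#' @export
hunting_probability <- function(bouts, bin_min = 3, horizon_min = 45,
                                conf = 0.90,
                                hunting_labels = c("j-turn", "pursuit",
                                                   "strike", "abort")) {
  bouts <- tibble::as_tibble(bouts)
  if (!"bout_start" %in% names(bouts)) abort("`bouts` needs a bout_start column.")
  hunting <- if ("hunting" %in% names(bouts)) {
    as.logical(bouts$hunting)
  } else if ("label" %in% names(bouts)) {
    bouts$label %in% hunting_labels
  } else {
    abort("`bouts` needs a `hunting` or `label` column.")
  }
  check_scalar_pos(bin_min, "bin_min")
  breaks <- seq(0, horizon_min, by = bin_min)
  start_min <- bouts$bout_start / 60
  out <- purrr::map_dfr(seq_len(length(breaks) - 1), function(i) {
    sel <- start_min >= breaks[i] & start_min < breaks[i + 1]
    n <- sum(sel); k <- sum(hunting[sel])
    if (n == 0) {
      tibble::tibble(bin_start = breaks[i], n_bouts = 0L, n_hunting = 0L,
                     p_hat = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
    } else {
      ci <- binom.test(k, n, conf.level = conf)$conf.int
      tibble::tibble(bin_start = breaks[i], n_bouts = n, n_hunting = k,
                     p_hat = k / n, ci_lo = ci[1], ci_hi = ci[2])
    }
  })
  class(out) <- c("bin_stats", class(out))
  attr(out, "conf") <- conf
  out
}

#' Per-bin Fisher exact tests between two groups
#'
#' Two-sided Fisher exact test on each bin's 2x2 table of hunting vs other
#' bout counts.
#'
#' @param group_a,group_b Data frames (e.g. from [hunting_probability()])
#'   with `n_hunting` and `n_bouts` (or `n_other`) columns, one row per bin.
#' @return A tibble with `bin`, `p`.
#' @export
per_bin_fisher <- function(group_a, group_b) {
  ga <- tibble::as_tibble(group_a); gb <- tibble::as_tibble(group_b)
  if (nrow(ga) != nrow(gb)) abort("The two groups must cover the same bins.")
  other <- function(g) {
    if ("n_other" %in% names(g)) g$n_other else g$n_bouts - g$n_hunting
  }
  oa <- other(ga); ob <- other(gb)
  if (any(c(ga$n_hunting, gb$n_hunting, oa, ob) < 0, na.rm = TRUE)) {
    abort("Counts must be non-negative.")
  }
  p <- vapply(seq_len(nrow(ga)), function(i) {
    tab <- matrix(c(ga$n_hunting[i], oa[i], gb$n_hunting[i], ob[i]), 2)
    if (any(is.na(tab)) || sum(tab) == 0) return(NA_real_)
    fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
  tibble::tibble(bin = seq_len(nrow(ga)), p = p)
}

#' Gut fluorescence as a food-intake readout
#'
#' Integrated and mean above-background intensity over the gut mask, with
#' the per-sample background level measured over `background_mask` and
#' subtracted. The integrated value is clipped at zero.
#'
#' @param image Numeric array (2-D or 3-D).
#' @param gut_mask,background_mask Logical arrays matching `image`;
#'   non-empty and disjoint.
#' @return A one-row tibble with `integrated`, `mean`, `background`,
#'   `n_pixels`.
#' @export
gut_fluorescence <- function(image, gut_mask, background_mask) {
  stopifnot(identical(dim(image), dim(gut_mask)),
            identical(dim(image), dim(background_mask)))
  if (!any(gut_mask) || !any(background_mask)) abort("Masks must be non-empty.")
  if (any(gut_mask & background_mask)) abort("Masks must be disjoint.")
  bg <- mean(image[background_mask])
  vals <- image[gut_mask] - bg
  tibble::tibble(
    integrated = max(sum(vals), 0),
    mean = max(mean(vals), 0),
    background = bg,
    n_pixels = sum(gut_mask)
  )
}
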