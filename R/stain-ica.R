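## Voxelization and independent-component analysis of activity maps.

#' Downsample a stack channel into coarse voxels
#'
#' Block-averages a channel into cubes of physical edge `voxel_edge` um
#' (default 4.7 um) and flattens the result into a per-fish voxel vector.
#' The flattening order is fixed: column-major over the downsampled
#' `(z, y, x)` array, z varying fastest. Partial blocks at the image border
#' are averaged over the voxels they do contain.
#'
#' @param stack A [stained_stack()].
#' @param rois Optional [roi_set()]; when given, a block counts as covered
#'   if it contains at least one voxel belonging to any ROI mask.
#' @param voxel_edge Downsampled voxel edge length (um); must be at least
#'   the native voxel size on every axis.
#' @param channel Channel role (default `"pERK"`).
#' @return A list with `vector` (named numeric), `covered` (logical of the
#'   same length), and `dims` (downsampled `(z, y, x)` counts).
#' @export
voxelize <- function(stack, rois = NULL, voxel_edge = 4.7, channel = "pERK") {
  stopifnot(inherits(stack, "stained_stack"))
  ch <- stack$channels[[channel]]
  if (is.null(ch)) abort(sprintf("Channel '%s' not in stack.", channel))
  vs <- stack$voxel_size
  if (any(voxel_edge < vs - 1e-9)) {
    abort("`voxel_edge` must be at least the native voxel size.")
  }
  fac <- as.integer(pmax(round(voxel_edge / vs), 1))
  d <- dim(ch)
  bins <- lapply(1:3, function(ax) ((seq_len(d[ax]) - 1L) %/% fac[ax]) + 1L)
  nd <- vapply(bins, max, 1L)
  grp <- array(0L, d)
  grp[] <- bins[[1]] +
    (rep(bins[[2]], each = d[1]) - 1L) * nd[1] +
    (rep(bins[[3]], each = d[1] * d[2]) - 1L) * nd[1] * nd[2]
  sums <- tapply(ch, grp, sum)
  cnts <- tapply(array(1, d), grp, sum)
  vec <- as.numeric(sums / cnts)
  covered <- rep(TRUE, length(vec))
  if (!is.null(rois)) {
    any_mask <- Reduce(`|`, rois$masks)
    cov_cnt <- tapply(any_mask, grp, sum)
    covered <- as.numeric(cov_cnt) > 0
  }
  names(vec) <- paste0("v", seq_along(vec))
  list(vector = vec, covered = covered, dims = nd)
}

## Symmetric FastICA with the cubic ('pow3') nonlinearity on whitened data
## y (dims x samples). Returns the unmixing matrix W (n_ics x dims).
fastica_pow3 <- function(y, n_ics, max_iter = 500, tol = 1e-8) {
  r <- nrow(y); m <- ncol(y)
  w <- matrix(rnorm(n_ics * r), n_ics, r)
  sym_decor <- function(w) {
    s <- w %*% t(w)
    e <- eigen(s, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), n_ics) %*%
      t(e$vectors) %*% w
  }
  w <- sym_decor(w)
  for (it in seq_len(max_iter)) {
    u <- w %*% y
    w_new <- (u^3 %*% t(y)) / m - 3 * w
    w_new <- sym_decor(w_new)
    delta <- max(abs(abs(rowSums(w_new * w)) - 1))
    w <- w_new
    if (delta < tol) return(list(w = w, converged = TRUE, iterations = it))
  }
  list(w = w, converged = FALSE, iterations = max_iter)
}

#' Independent component analysis of per-fish voxel vectors
#'
#' Reproduces the activity-map decomposition: fish with any unobserved voxel
#' are excluded; each remaining fish is normalized for overall brightness by
#' dividing by its 10th-percentile intensity; the voxelwise mean across fish
#' is subtracted; the fish-by-voxel array is reduced to `n_pcs` principal
#' components and decomposed into `n_ics` independent components with
#' symmetric FastICA using the cubic (`pow3`) nonlinearity, treating each
#' fish as a signal and each voxel as a sample. Component maps are reported
#' as z-scores, oriented so each component's largest-magnitude voxel is
#' positive.
#'
#' @param vectors Fish-by-voxel numeric matrix.
#' @param coverage Optional fish-by-voxel logical matrix marking observed
#'   voxels; fish with any `FALSE` are excluded.
#' @param n_pcs Number of principal components retained (default 30).
#' @param n_ics Number of independent components (default 30; capped at the
#'   retained rank).
#' @param seed Seed for the FastICA initialization.
#' @return An object of class `ica_result` with fields `components`
#'   (`n_ics` x voxel z-score matrix), `fish_loadings` (fish x `n_ics`),
#'   `kept_fish`, `n_pcs`, `n_ics`, `converged`.
#' @export
run_ica <- function(vectors, coverage = NULL, n_pcs = 30, n_ics = 30,
                    seed = 1L) {
  stopifnot(is.matrix(vectors))
  n_fish <- nrow(vectors)
  kept <- seq_len(n_fish)
  if (!is.null(coverage)) {
    stopifnot(identical(dim(coverage), dim(vectors)))
    kept <- which(apply(coverage, 1, all))
  }
  if (length(kept) < 2) {
    abort(sprintf("Only %d fish with complete coverage; need at least 2.",
                  length(kept)))
  }
  x <- vectors[kept, , drop = FALSE]
  p10 <- apply(x, 1, quantile, probs = 0.10, names = FALSE)
  if (any(p10 <= 0)) abort("10th-percentile intensity must be positive for every fish.")
  x <- x / p10
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  keep_r <- sv$d > max(sv$d) * 1e-10
  r <- min(n_pcs, sum(keep_r))
  if (r < 1) {
    abort("Data are rank-deficient after normalization (all fish identical); nothing to decompose.")
  }
  if (n_ics > r) {
    warn(sprintf("n_ics reduced from %d to the retained rank %d.", n_ics, r))
    n_ics <- r
  }
  m <- ncol(x)
  ## whitened signals: rows have unit variance across voxels
  y <- sqrt(m) * t(sv$v[, seq_len(r), drop = FALSE])
  fit <- with_seed(substream_seed(seed, "fastica"),
                   fastica_pow3(y, n_ics))
  s <- fit$w %*% y                      # n_ics x voxels
  z <- t(scale(t(s)))                   # z-score each map
  flip <- vapply(seq_len(n_ics), function(i) {
    sign(z[i, which.max(abs(z[i, ]))])
  }, numeric(1))
  z <- z * flip
  loadings <- x %*% t(z) / m
  structure(
    list(components = z, fish_loadings = loadings, kept_fish = kept,
         n_pcs = r, n_ics = n_ics, converged = fit$converged,
         iterations = fit$iterations),
    class = "ica_result"
  )
}

#' @export
print.ica_result <- function(x, ...) {
  cat(sprintf(
    "<ica_result> %d ICs from %d PCs, %d fish kept, %s after %d iterations\n",
    x$n_ics, x$n_pcs, length(x$kept_fish),
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  invisible(x)
}

#' Tidy the component maps of an ICA decomposition
#'
#' @param x An `ica_result`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `voxel`, `z`.
#' @export
tidy.ica_result <- function(x, ...) {
  tibble::tibble(
    component = rep(seq_len(nrow(x$components)), times = ncol(x$components)),
    voxel = rep(seq_len(ncol(x$components)), each = nrow(x$components)),
    z = as.vector(x$components)
  )
}

#' One-row summary of an ICA decomposition
#'
#' @param x An `ica_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ica_result <- function(x, ...) {
  tibble::tibble(n_ics = x$n_ics, n_pcs = x$n_pcs,
                 n_fish = length(x$kept_fish),
                 converged = x$converged, iterations = x$iterations)
}
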