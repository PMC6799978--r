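## Voxel cross-correlograms and the anti-correlation rank statistic.

#' Downsample a movie into cell-sized voxel traces
#'
#' Block-averages each frame over `cell_size_px` x `cell_size_px` tiles.
#' Tiles falling entirely outside a supplied region map are dropped; a tile
#' overlapping several regions takes the majority label.
#'
#' @param movie Numeric `time x y x x` array.
#' @param cell_size_px Tile edge in pixels (>= 1; 6 px by default, a
#'   cell-sized voxel).
#' @param region_map Optional `y x x` character matrix of region labels
#'   (`NA` pixels belong to no region).
#' @return A list with `traces` (time x voxel matrix), `labels` (region per
#'   voxel), and `coords` (tile-center `(y, x)` pixel coordinates, 0-based).
#' @export
downsample_movie <- function(movie, cell_size_px = 6, region_map = NULL) {
  stopifnot(length(dim(movie)) == 3)
  cell_size_px <- as.integer(cell_size_px)
  if (cell_size_px < 1) abort("`cell_size_px` must be >= 1.")
  d <- dim(movie)
  by_y <- ((seq_len(d[2]) - 1L) %/% cell_size_px) + 1L
  by_x <- ((seq_len(d[3]) - 1L) %/% cell_size_px) + 1L
  ny <- max(by_y); nx <- max(by_x)
  traces <- matrix(0, d[1], ny * nx)
  labels <- character(ny * nx)
  coords <- matrix(0, ny * nx, 2, dimnames = list(NULL, c("y", "x")))
  keep <- logical(ny * nx)
  k <- 0L
  for (tx in seq_len(nx)) {
    xs <- which(by_x == tx)
    for (ty in seq_len(ny)) {
      ys <- which(by_y == ty)
      k <- k + 1L
      sub <- movie[, ys, xs, drop = FALSE]
      traces[, k] <- rowMeans(matrix(sub, d[1]))
      coords[k, ] <- c(mean(ys) - 1, mean(xs) - 1)
      if (is.null(region_map)) {
        labels[k] <- "all"; keep[k] <- TRUE
      } else {
        lb <- region_map[ys, xs]
        lb <- lb[!is.na(lb)]
        if (length(lb)) {
          labels[k] <- names(which.max(table(lb)))
          keep[k] <- TRUE
        }
      }
    }
  }
  list(traces = traces[, keep, drop = FALSE], labels = labels[keep],
       coords = coords[keep, , drop = FALSE])
}

#' Zero-lag cross-correlogram of voxel traces
#'
#' Pearson correlation matrix of delta-F/F voxel traces, ordered by region
#' label blocks. Zero-variance voxels are dropped with a warning.
#'
#' @param traces Time x voxel numeric matrix.
#' @param labels Region label per voxel.
#' @param coords Optional voxel coordinates, carried through.
#' @return An object of class `corr_map`: a list with `r` (voxel x voxel
#'   correlation matrix), `labels`, and `coords`.
#' @export
crosscorrelogram <- function(traces, labels, coords = NULL) {
  stopifnot(is.matrix(traces))
  if (ncol(traces) < 2) abort("Need at least 2 voxels.")
  if (nrow(traces) < 10) abort("Need at least 10 timepoints.")
  if (length(labels) != ncol(traces)) abort("One label per voxel required.")
  v <- apply(traces, 2, var)
  if (any(v == 0)) {
    warn(sprintf("Dropping %d zero-variance voxel(s).", sum(v == 0)))
    keep <- v > 0
    traces <- traces[, keep, drop = FALSE]
    labels <- labels[keep]
    if (!is.null(coords)) coords <- coords[keep, , drop = FALSE]
    if (ncol(traces) < 2) abort("Fewer than 2 voxels left after dropping.")
  }
  ord <- order(factor(labels, levels = unique(labels)))
  traces <- traces[, ord, drop = FALSE]
  labels <- labels[ord]
  if (!is.null(coords)) coords <- coords[ord, , drop = FALSE]
  r <- cor(traces)
  dimnames(r) <- list(labels, labels)
  structure(list(r = r, labels = labels, coords = coords),
            class = "corr_map")
}

#' @export
print.corr_map <- function(x, ...) {
  cat(sprintf("<corr_map> %d voxels, regions: %s\n", length(x$labels),
              paste(unique(x$labels), collapse = ", ")))
  invisible(x)
}

#' Mean within- and between-region correlations of a corr_map
#'
#' @param x A `corr_map`.
#' @param ... Unused.
#' @return A tibble with `source`, `target`, `mean_r`, `n_pairs`
#'   (off-diagonal pairs only).
#' @export
tidy.corr_map <- function(x, ...) {
  regions <- unique(x$labels)
  purrr::map_dfr(regions, function(a) {
    purrr::map_dfr(regions, function(b) {
      ra <- x$labels == a; rb <- x$labels == b
      m <- x$r[ra, rb, drop = FALSE]
      if (a == b) diag(m) <- NA
      tibble::tibble(source = a, target = b,
                     mean_r = mean(m, na.rm = TRUE),
                     n_pairs = sum(!is.na(m)))
    })
  })
}

#' Rank-enrichment of anti-correlated partner regions
#'
#' For each voxel, all other voxels are sorted by ascending correlation (most
#' anti-correlated first; ties broken by voxel index). For each source
#' region, target region and rank `n`, the fraction of source voxels whose
#' nth most anti-correlated partner lies in the target region is divided by
#' the target's chance fraction — the fraction of all voxels (excluding the
#' source voxel itself) occupied by the target region.
#'
#' @param cmap A `corr_map`.
#' @param max_rank Largest rank tabulated (default 10; must be < voxel
#'   count).
#' @return A `rank_enrichment` tibble with `source`, `target`, `rank`,
#'   `prob`, `chance`, `ratio`.
#' @export
anticorr_rank_stat <- function(cmap, max_rank = 10) {
  stopifnot(inherits(cmap, "corr_map"))
  labels <- cmap$labels
  regions <- unique(labels)
  if (length(regions) < 2) abort("Need at least 2 regions for the rank statistic.")
  nv <- length(labels)
  if (max_rank >= nv) abort("`max_rank` must be smaller than the voxel count.")
  ## partner region at each rank, per source voxel
  partner <- matrix(NA_character_, nv, max_rank)
  for (i in seq_len(nv)) {
    others <- seq_len(nv)[-i]
    ord <- others[order(cmap$r[i, -i], others)]
    partner[i, ] <- labels[ord[seq_len(max_rank)]]
  }
  out <- purrr::map_dfr(regions, function(src) {
    src_idx <- which(labels == src)
    purrr::map_dfr(regions, function(tgt) {
      chance <- mean((sum(labels == tgt) - (labels[src_idx] == tgt)) / (nv - 1))
      purrr::map_dfr(seq_len(max_rank), function(rk) {
        prob <- mean(partner[src_idx, rk] == tgt)
        tibble::tibble(source = src, target = tgt, rank = rk,
                       prob = prob, chance = chance,
                       ratio = prob / chance)
      })
    })
  })
  class(out) <- c("rank_enrichment", class(out))
  out
}
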