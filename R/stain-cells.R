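## Adaptive-threshold active-cell counting.

#' Parameters for active-cell counting
#'
#' Controls the three-step counting procedure: (1) background reduction,
#' (2) adaptive (local-mean + offset) thresholding to isolate
#' strongly-stained cells, (3) connected-component particle analysis with a
#' size filter. All lengths are micrometres and are converted to voxels
#' through the stack's voxel size.
#'
#' @param background_radius Radius (um) of the local-mean background that is
#'   subtracted before thresholding.
#' @param threshold_window Adaptive-threshold window (um); about three cell
#'   diameters by default.
#' @param threshold_offset Offset above the local mean, in intensity units
#'   of the background-reduced image. Larger offsets keep fewer voxels;
#'   the offset should clear the noise floor by a comfortable margin.
#' @param size_range `(min, max)` object size in um^2 (single-plane input)
#'   or um^3 (stacks); `NULL` picks `c(4, 500)` um^2 or `c(10, 1500)` um^3.
#' @param connectivity `"face"` (4-neighborhood in-plane, 6 in 3-D) or
#'   `"full"` (8 in-plane, 26 in 3-D).
#' @return An object of class `cell_count_params`.
#' @export
cell_count_params <- function(background_radius = 10,
                              threshold_window = 15,
                              threshold_offset = 20,
                              size_range = NULL,
                              connectivity = c("face", "full")) {
  check_scalar_pos(background_radius, "background_radius")
  check_scalar_pos(threshold_window, "threshold_window")
  stopifnot(is.numeric(threshold_offset), length(threshold_offset) == 1)
  if (!is.null(size_range)) {
    stopifnot(length(size_range) == 2, all(size_range > 0),
              size_range[1] < size_range[2])
  }
  connectivity <- match.arg(connectivity)
  structure(
    list(background_radius = background_radius,
         threshold_window = threshold_window,
         threshold_offset = threshold_offset,
         size_range = size_range, connectivity = connectivity),
    class = "cell_count_params"
  )
}

## Neighbor offsets for connected components.
neighbor_offsets <- function(connectivity, two_d) {
  if (connectivity == "face") {
    offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    if (two_d) offs <- offs[-1, , drop = FALSE]
  } else {
    grid <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    if (two_d) grid <- grid[grid[, 1] == 0, , drop = FALSE]
    ## keep one of each +/- pair (undirected edges)
    keep <- apply(grid, 1, function(o) {
      nz <- which(o != 0)
      length(nz) > 0 && o[nz[1]] > 0
    })
    offs <- grid[keep, , drop = FALSE]
  }
  offs
}

## Label connected foreground voxels of a logical (z,y,x) array.
## Returns an integer vector of component ids aligned with which(fg).
label_components <- function(fg, connectivity = "face") {
  d <- dim(fg)
  idx <- which(fg)
  if (!length(idx)) return(list(ids = integer(0), idx = idx))
  coords <- arrayInd(idx, d)
  two_d <- d[1] == 1L
  offs <- neighbor_offsets(connectivity, two_d)
  lin <- function(cc) (cc[, 3] - 1L) * d[1] * d[2] + (cc[, 2] - 1L) * d[1] + cc[, 1]
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- lin(nb[ok, , drop = FALSE])
    hit <- fg[nb_lin]
    if (!any(hit)) next
    edges[[length(edges) + 1L]] <- cbind(idx[ok][hit], nb_lin[hit])
  }
  comp <- match(idx, idx)  # self-ids to start
  if (length(edges)) {
    e <- do.call(rbind, edges)
    a <- match(e[, 1], idx)
    b <- match(e[, 2], idx)
    g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_along(idx)]
  }
  list(ids = as.integer(comp), idx = idx)
}

#' Count active cells in an ROI by adaptive thresholding
#'
#' Isolates strongly-stained cells in three steps: local-mean background
#' subtraction, adaptive thresholding (local mean plus offset), and
#' connected-component analysis with a physical size filter. Reliable only where active cells are well separated (sparse
#' regions such as the mLH/lLH, not the densely stained cH).
#'
#' Stacks with more than one z-plane are labeled in 3-D (so cells spanning
#' planes are counted once); single-plane input is labeled in 2-D.
#'
#' @param stack A [stained_stack()].
#' @param rois A [roi_set()].
#' @param roi ROI name to count within.
#' @param params A [cell_count_params()].
#' @param channel Channel role (default `"pERK"`).
#' @return A list with `count` (integer) and `objects` (tibble of 0-based
#'   `(z, y, x)` centroids, voxel counts and physical sizes).
#' @export
count_active_cells <- function(stack, rois, roi,
                               params = cell_count_params(),
                               channel = "pERK") {
  stopifnot(inherits(stack, "stained_stack"), inherits(params, "cell_count_params"))
  ch <- stack$channels[[channel]]
  if (is.null(ch)) abort(sprintf("Channel '%s' not in stack.", channel))
  m <- roi_mask(rois, roi)
  d <- dim(ch)
  vs <- stack$voxel_size
  two_d <- d[1] == 1L
  bg_w <- 2 * params$background_radius / vs
  th_w <- params$threshold_window / vs
  if (all(floor(bg_w[if (two_d) 2:3 else 1:3]) < 1) ||
      all(floor(th_w[if (two_d) 2:3 else 1:3]) < 1)) {
    abort("Window parameters are smaller than the voxel size; supply larger windows.")
  }
  bg_w <- pmax(round(bg_w), 1); th_w <- pmax(round(th_w), 1)
  if (two_d) { bg_w[1] <- 1; th_w[1] <- 1 }

  ## 1) background reduction
  img <- ch - local_mean_filter(ch, bg_w)
  img[img < 0] <- 0

  ## 2) adaptive threshold: local mean + absolute offset
  fg <- img > local_mean_filter(img, th_w) + params$threshold_offset
  fg <- fg & m

  ## 3) particle analysis: connected components + size filter
  lab <- label_components(fg, params$connectivity)
  unit <- if (two_d) prod(vs[2:3]) else prod(vs)
  size_range <- params$size_range %||%
    if (two_d) c(4, 500) else c(10, 1500)
  objects <- tibble::tibble(z = numeric(0), y = numeric(0), x = numeric(0),
                            n_voxels = integer(0), size = numeric(0))
  if (length(lab$idx)) {
    coords <- arrayInd(lab$idx, d)
    df <- tibble::tibble(
      id = lab$ids,
      z = coords[, 1] - 1, y = coords[, 2] - 1, x = coords[, 3] - 1
    )
    objects <- df |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(z = mean(.data$z), y = mean(.data$y), x = mean(.data$x),
                       n_voxels = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(size = .data$n_voxels * unit) |>
      dplyr::filter(.data$size >= size_range[1], .data$size <= size_range[2]) |>
      dplyr::select(-"id")
  }
  list(count = nrow(objects), objects = objects)
}
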