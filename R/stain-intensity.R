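## ROI fluorescence quantification and group normalization.

#' Mean fluorescence over an ROI, optionally background-subtracted
#'
#' Averages a channel over all mask voxels of an ROI (respecting its z-range
#' restriction), optionally subtracting the mean over a `background` mask.
#' The result is reported as-is and may be negative after subtraction.
#'
#' @param stack A [stained_stack()].
#' @param rois A [roi_set()] containing `roi` (and `background` when
#'   `subtract_background = TRUE`).
#' @param roi ROI name.
#' @param channel Channel role (default `"pERK"`).
#' @param subtract_background Subtract the background-mask mean?
#' @return A single number (intensity units).
#' @export
roi_mean_intensity <- function(stack, rois, roi, channel = "pERK",
                               subtract_background = FALSE) {
  stopifnot(inherits(stack, "stained_stack"), inherits(rois, "roi_set"),
            is_flag(subtract_background))
  if (!channel %in% names(stack$channels)) {
    abort(sprintf("Channel '%s' not in stack (have: %s).", channel,
                  paste(names(stack$channels), collapse = ", ")))
  }
  ch <- stack$channels[[channel]]
  m <- roi_mask(rois, roi)
  if (!identical(dim(m), dim(ch))) abort("ROI masks do not match the stack shape.")
  val <- mean(ch[m])
  if (subtract_background) {
    bg <- roi_mask(rois, "background")
    val <- val - mean(ch[bg])
  }
  val
}

#' Normalize per-fish values to the mean of a control group
#'
#' Divides every value by the arithmetic mean of the control group's values
#' for the same ROI, so the control group has normalized mean exactly 1.
#'
#' @param values Tibble (or data frame) with at least a `value` column;
#'   extra columns (fish_id, group, roi) are carried through. A bare numeric
#'   vector is also accepted.
#' @param control_values Numeric vector of the control group's raw values.
#' @return A tibble with a `normalized` column added (input columns kept).
#' @export
normalize_to_control <- function(values, control_values) {
  if (!is.numeric(control_values) || length(control_values) == 0) {
    abort("`control_values` must be a non-empty numeric vector.")
  }
  ctrl_mean <- mean(control_values)
  if (!is.finite(ctrl_mean) || abs(ctrl_mean) < .Machine$double.eps * 100) {
    abort("Control mean is numerically degenerate; cannot normalize.")
  }
  if (is.numeric(values)) values <- tibble::tibble(value = values)
  values <- tibble::as_tibble(values)
  if (!"value" %in% names(values)) abort("`values` needs a `value` column.")
  dplyr::mutate(values, normalized = .data$value / ctrl_mean)
}

#' Mean pERK intensity in a sphere around annotated points
#'
#' For semi-automated overlap quantification: returns the mean pERK-channel
#' intensity within a sphere of physical radius `radius_um` (respecting the
#' anisotropic voxel size) around each annotated cell position.
#'
#' @param stack A [stained_stack()].
#' @param points Numeric matrix of 0-based `(z, y, x)` voxel coordinates,
#'   one row per point.
#' @param radius_um Sphere radius in micrometres; at `radius_um = 0` the
#'   single voxel value at the point is returned.
#' @param channel Channel role (default `"pERK"`).
#' @return A tibble with columns `z`, `y`, `x` (as supplied) and `mean_perk`.
#' @export
perk_at_points <- function(stack, points, radius_um, channel = "pERK") {
  stopifnot(inherits(stack, "stained_stack"))
  check_scalar_pos(radius_um, "radius_um", strict = FALSE)
  ch <- stack$channels[[channel]]
  if (is.null(ch)) abort(sprintf("Channel '%s' not in stack.", channel))
  points <- matrix(as.numeric(points), ncol = 3)
  d <- dim(ch)
  oob <- which(points[, 1] < 0 | points[, 1] > d[1] - 1 |
               points[, 2] < 0 | points[, 2] > d[2] - 1 |
               points[, 3] < 0 | points[, 3] > d[3] - 1)
  if (length(oob)) {
    abort(sprintf("Points out of bounds at rows: %s.",
                  paste(oob, collapse = ", ")))
  }
  vs <- stack$voxel_size
  half <- pmax(floor(radius_um / vs), 0)
  vals <- vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ] + 1  # to 1-based
    rng <- lapply(1:3, function(ax) {
      max(1, round(p[ax]) - half[ax]):min(d[ax], round(p[ax]) + half[ax])
    })
    sub <- ch[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    dz <- (rng[[1]] - p[1]) * vs[1]
    dy <- (rng[[2]] - p[2]) * vs[2]
    dx <- (rng[[3]] - p[3]) * vs[3]
    dist2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
    keep <- dist2 <= radius_um^2 + 1e-9
    if (!any(keep)) sub[which.min(dist2)] else mean(sub[keep])
  }, numeric(1))
  tibble::tibble(z = points[, 1], y = points[, 2], x = points[, 3],
                 mean_perk = vals)
}

#' Prey-type activity-change ratio (theta_A / theta_P)
#'
#' Compares the activity change induced by artemia (hunted but too large to
#' ingest) with that induced by paramecia (hunted and ingested), each
#' relative to an unfed control: `theta_X = mean(metric_X) -
#' mean(metric_control)`. Works for normalized-intensity or active-cell-count
#' metrics. The ratio is reported as `NA` when `|theta_P|` falls below
#' `floor`.
#'
#' @param metric_artemia,metric_control,metric_paramecia Per-fish metric
#'   vectors for the three groups (non-empty).
#' @param floor Smallest `|theta_P|` for which the ratio is defined.
#' @return A one-row tibble with `theta_A`, `theta_P`, and `ratio`
#'   (class `theta_result`).
#' @export
theta_ratio <- function(metric_artemia, metric_control, metric_paramecia,
                        floor = 1e-12) {
  for (v in list(metric_artemia, metric_control, metric_paramecia)) {
    if (!is.numeric(v) || length(v) == 0) abort("All three groups must be non-empty numeric vectors.")
  }
  theta_a <- mean(metric_artemia) - mean(metric_control)
  theta_p <- mean(metric_paramecia) - mean(metric_control)
  ratio <- if (abs(theta_p) < floor) NA_real_ else theta_a / theta_p
  out <- tibble::tibble(theta_A = theta_a, theta_P = theta_p, ratio = ratio)
  class(out) <- c("theta_result", class(out))
  out
}
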