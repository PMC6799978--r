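#' Stained brain stack
#'
#' A registered multi-channel 3-D fluorescence volume. Channels are stored as
#' named numeric arrays with dimensions `(z, y, x)`; channel names declare
#' their role (e.g. `"pERK"`, `"tERK"`, `"reporter"`). All coordinates in the
#' package are 0-based and ordered `(z, y, x)`; physical parameters are in
#' micrometres and converted through `voxel_size`.
#'
#' @param channels Named list of numeric `(z, y, x)` arrays, one per channel
#'   role. All arrays must share a shape and hold finite, non-negative
#'   intensities.
#' @param voxel_size Numeric length-3 vector: voxel edge lengths in um,
#'   `(z, y, x)` order.
#' @return An object of class `stained_stack`.
#' @export
stained_stack <- function(channels, voxel_size = c(2, 0.8, 0.8)) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == "") || anyDuplicated(names(channels))) {
    abort("`channels` must be a named list with unique channel roles.")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    abort("Each channel must be a 3-D (z, y, x) array.")
  }
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    abort("All channels must share the same shape.")
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(is.finite(ch)) || any(ch < 0)) {
      abort(sprintf("Channel '%s' must hold finite, non-negative intensities.", nm))
    }
  }
  stopifnot(is.numeric(voxel_size), length(voxel_size) == 3L, all(voxel_size > 0))
  structure(
    list(channels = channels, voxel_size = as.numeric(voxel_size)),
    class = "stained_stack"
  )
}

#' @export
print.stained_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<stained_stack> %d x %d x %d (z,y,x), channels: %s, voxel %s um\n",
    d[1], d[2], d[3], paste(names(x$channels), collapse = ", "),
    paste(signif(x$voxel_size, 3), collapse = " x ")
  ))
  invisible(x)
}

#' Named ROI mask set
#'
#' Named boolean volumes delimiting brain regions (cH, mLH, lLH, background,
#' or custom), optionally with a per-mask inclusive z-slab restriction.
#' The caudal hypothalamus is conventionally restricted to its most ventral
#' planes via `z_range`.
#'
#' @param masks Named list of logical `(z, y, x)` arrays; each mask must be
#'   non-empty.
#' @param z_range Optional named list of inclusive 1-based `(lo, hi)` z-plane
#'   ranges; names must match mask names.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks, z_range = list()) {
  if (!is.list(masks) || is.null(names(masks)) || anyDuplicated(names(masks))) {
    abort("`masks` must be a named list with unique names.")
  }
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || length(dim(m)) != 3L) {
      abort(sprintf("Mask '%s' must be a logical 3-D array.", nm))
    }
    if (!any(m)) abort(sprintf("Mask '%s' is empty.", nm))
  }
  if (length(z_range)) {
    bad <- setdiff(names(z_range), names(masks))
    if (length(bad)) abort(sprintf("z_range names not in masks: %s",
                                   paste(bad, collapse = ", ")))
  }
  structure(list(masks = masks, z_range = z_range), class = "roi_set")
}

## Effective mask after applying any z-slab restriction.
roi_mask <- function(rois, roi) {
  if (!roi %in% names(rois$masks)) {
    abort(sprintf("ROI '%s' not found (have: %s).", roi,
                  paste(names(rois$masks), collapse = ", ")))
  }
  m <- rois$masks[[roi]]
  zr <- rois$z_range[[roi]]
  if (!is.null(zr)) {
    keep <- seq(zr[1], zr[2])
    sel <- array(FALSE, dim(m))
    sel[keep, , ] <- TRUE
    m <- m & sel
  }
  if (!any(m)) abort(sprintf("ROI '%s' is empty after z-range restriction.", roi))
  m
}

#' Calcium trace set
#'
#' Time-by-ROI fluorescence traces with acquisition metadata. `raw` holds
#' as-acquired fluorescence; `dff` holds delta-F/F as a fraction (multiply by
#' 100 for percent). ROI labels follow the `region_side` convention
#' (e.g. `"lLH_left"`) so that left/right lobes can be paired.
#'
#' @param raw,dff Numeric time-by-ROI matrices (either may be `NULL`, not
#'   both). Column names are the ROI labels.
#' @param fps Frames per second (> 0).
#' @param events Named numeric vector of event times in seconds (e.g. water
#'   or paramecia delivery).
#' @param epochs Named list of `c(start, end)` second pairs (e.g. a 300 s
#'   food-deprived baseline).
#' @param params List of processing parameters recorded along the way.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(raw = NULL, dff = NULL, fps, events = c(),
                      epochs = list(), params = list()) {
  check_scalar_pos(fps, "fps")
  ref <- if (!is.null(dff)) dff else raw
  if (is.null(ref)) abort("Provide at least one of `raw` or `dff`.")
  for (m in list(raw, dff)) {
    if (!is.null(m)) {
      if (!is.matrix(m) || is.null(colnames(m))) {
        abort("Trace matrices must be time-by-ROI matrices with column names.")
      }
      if (anyDuplicated(colnames(m))) abort("ROI labels must be unique.")
    }
  }
  n <- nrow(ref)
  dur <- n / fps
  if (length(epochs)) {
    for (nm in names(epochs)) {
      ep <- epochs[[nm]]
      if (length(ep) != 2 || ep[1] < 0 || ep[2] > dur + 1e-9 || ep[2] <= ep[1]) {
        abort(sprintf("Epoch '%s' must lie within the trace.", nm))
      }
    }
  }
  structure(
    list(raw = raw, dff = dff, fps = fps, roi_labels = colnames(ref),
         events = events, epochs = epochs, params = params),
    class = "trace_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  ref <- if (!is.null(x$dff)) x$dff else x$raw
  cat(sprintf(
    "<trace_set> %d frames @ %g fps (%.1f s), %d ROIs [%s]%s\n",
    nrow(ref), x$fps, nrow(ref) / x$fps, ncol(ref),
    paste(head(colnames(ref), 4), collapse = ", "),
    if (is.null(x$dff)) " (raw only)" else ""
  ))
  invisible(x)
}

n_frames <- function(ts) nrow(if (!is.null(ts$dff)) ts$dff else ts$raw)

#' Tidy a trace set into long format
#'
#' @param x A [trace_set()].
#' @param ... Unused.
#' @return A tibble with `time`, `roi`, and `dff` (or `raw`) columns.
#' @export
tidy.trace_set <- function(x, ...) {
  m <- if (!is.null(x$dff)) x$dff else x$raw
  value_name <- if (!is.null(x$dff)) "dff" else "raw"
  tibble::tibble(
    time = rep((seq_len(nrow(m)) - 1) / x$fps, times = ncol(m)),
    roi = rep(colnames(m), each = nrow(m)),
    !!value_name := as.vector(m)
  )
}

#' Optogenetic stimulation session
#'
#' A trace set plus the laser pulse schedule and the length of the pre/post
#' analysis windows (90 s by default, matching a 10 s illumination repeated
#' every 120-180 s).
#'
#' @param ts A [trace_set()].
#' @param pulses Data frame with `onset_s` and `duration_s` columns; pulses
#'   must be sorted and non-overlapping.
#' @param window_s Analysis window length in seconds (default 90).
#' @param target_rois ROI labels to analyze (default: all).
#' @return An object of class `stim_session`.
#' @export
stim_session <- function(ts, pulses, window_s = 90, target_rois = NULL) {
  stopifnot(inherits(ts, "trace_set"))
  pulses <- tibble::as_tibble(pulses)
  if (!all(c("onset_s", "duration_s") %in% names(pulses))) {
    abort("`pulses` needs columns onset_s and duration_s.")
  }
  if (nrow(pulses) > 1) {
    if (is.unsorted(pulses$onset_s, strictly = TRUE)) {
      abort("Pulses must be sorted by onset.")
    }
    ends <- pulses$onset_s + pulses$duration_s
    if (any(pulses$onset_s[-1] < ends[-nrow(pulses)])) {
      abort("Pulses must not overlap.")
    }
  }
  check_scalar_pos(window_s, "window_s")
  if (is.null(target_rois)) target_rois <- ts$roi_labels
  structure(
    list(ts = ts, pulses = pulses, window_s = window_s,
         target_rois = target_rois),
    class = "stim_session"
  )
}
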