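## Shared I/O: TIFF stacks, CSV traces/tables with JSON sidecars, and the
## reproducible pipeline runner.

#' Read a multi-page TIFF into a stained stack
#'
#' Pages are mapped to channels via `layout`: either `"pages"` (all pages of
#' one file belong to one channel, `channel_roles` names them) or a named
#' list of per-channel file paths whose shapes must agree.
#'
#' @param path TIFF path (single-channel z-stack) or named character vector
#'   of per-channel paths.
#' @param channel_roles Channel names when `path` is a single file.
#' @param voxel_size Voxel size in um `(z, y, x)`.
#' @return A [stained_stack()].
#' @export
read_stack <- function(path, channel_roles = "pERK",
                       voxel_size = c(2, 0.8, 0.8)) {
  read_one <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(length(pages), dim(pages[[1]])))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    arr
  }
  if (length(path) > 1) {
    if (is.null(names(path))) abort("Multiple paths must be named by channel role.")
    channels <- lapply(path, read_one)
    shapes <- unique(lapply(channels, dim))
    if (length(shapes) != 1) abort("Channel files disagree in shape.")
    return(stained_stack(channels, voxel_size))
  }
  arr <- read_one(path)
  stained_stack(setNames(list(arr), channel_roles[1]), voxel_size)
}

#' Write a stained stack channel as a 16-bit multi-page TIFF
#'
#' @param stack A [stained_stack()].
#' @param path Output path.
#' @param channel Channel role to write.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, channel = "pERK") {
  stopifnot(inherits(stack, "stained_stack"))
  ch <- stack$channels[[channel]]
  if (is.null(ch)) abort(sprintf("Channel '%s' not in stack.", channel))
  if (any(ch < 0) || any(ch > 65535)) {
    abort("Intensities must lie in [0, 65535] for 16-bit output.")
  }
  pages <- lapply(seq_len(dim(ch)[1]), function(z) ch[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Write a trace set as CSV with a JSON sidecar
#'
#' The CSV holds `time` plus one column per ROI (dff when present, else
#' raw); events, epochs, fps and processing parameters go into
#' `<path>.json`. Values round-trip losslessly to full double precision.
#'
#' @param ts A [trace_set()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  m <- ts$dff %||% ts$raw
  df <- tibble::as_tibble(m)
  df <- dplyr::mutate(df, time = (dplyr::row_number() - 1) / ts$fps,
                      .before = 1)
  readr::write_csv(df, path)
  meta <- list(fps = ts$fps, kind = if (is.null(ts$dff)) "raw" else "dff",
               events = as.list(ts$events), epochs = ts$epochs,
               params = ts$params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trace set written by [write_traces()]
#'
#' @param path CSV path; `<path>.json` is read when present.
#' @param fps Frame rate override when no sidecar exists.
#' @return A [trace_set()].
#' @export
read_traces <- function(path, fps = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, locale = readr::locale())
  if (!"time" %in% names(df)) {
    abort(sprintf("Malformed trace CSV: expected columns time, <roi...>; got %s.",
                  paste(names(df), collapse = ", ")))
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  if (is.null(fps)) {
    fps <- as.numeric(meta$fps %||%
      (if (nrow(df) > 1) 1 / diff(df$time[1:2]) else abort("Cannot infer fps.")))
  }
  m <- as.matrix(df[setdiff(names(df), "time")])
  events <- unlist(meta$events) %||% c()
  epochs <- lapply(meta$epochs %||% list(), as.numeric)
  if (identical(meta$kind, "raw")) {
    trace_set(raw = m, fps = fps, events = events, epochs = epochs)
  } else {
    trace_set(dff = m, fps = fps, events = events, epochs = epochs)
  }
}

#' Write any tabular result to CSV
#'
#' @param obj A data frame or tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) {
  readr::write_csv(tibble::as_tibble(obj), path)
  invisible(path)
}

#' Run a configured analysis end to end
#'
#' Executes the requested stages in dependency order on synthetic inputs and
#' writes every product — metric CSVs, a stats JSON, and the resolved
#' configuration (including the seed) — into `out_dir`, so a run can be
#' reproduced exactly from its own output directory. Identical config and
#' seed give identical outputs.
#'
#' @param config A list with elements `seed`, `out_dir`, and `stages`
#'   (subset of `"traces"`, `"spikes"`, `"xcorr"`, `"rankstat"`, `"opto"`,
#'   `"bouts"`, `"gut"`); stage parameters may be supplied under a matching
#'   name (e.g. `config$traces$duration_s`).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("traces", "spikes")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  needs_traces <- any(c("traces", "spikes") %in% stages)
  if (needs_traces) {
    p <- config$traces %||% list()
    model <- latent_model(seed = substream_seed(seed, "pipeline"))
    gen <- generate_traces(model, p$duration_s %||% 300, p$fps %||% 2)
    ts <- compute_dff(gen$traces)
    ts <- detrend_quadratic(ts)
    write_traces(ts, file.path(config$out_dir, "traces.csv"))
    if ("spikes" %in% stages) {
      spk <- purrr::map_dfr(colnames(ts$dff), function(rg) {
        detect_spikes(ts$dff[, rg], ts$fps, roi = rg)
      })
      write_table(spk, file.path(config$out_dir, "spikes.csv"))
      out$n_spikes <- nrow(spk)
    }
  }

  if (any(c("xcorr", "rankstat") %in% stages)) {
    p <- config$xcorr %||% list()
    if (!is.null(p$traces_csv)) {
      ts <- read_traces(p$traces_csv)
      vox <- list(traces = ts$dff %||% ts$raw,
                  labels = colnames(ts$dff %||% ts$raw), coords = NULL)
    } else {
      model <- latent_model(seed = substream_seed(seed, "pipeline-movie"))
      mv <- generate_movie(model, p$duration_s %||% 300, p$fps %||% 2)
      vox <- downsample_movie(mv$movie, p$cell_size_px %||% 6, mv$region_map)
      vox$traces <- apply(vox$traces, 2, detrend_quadratic)
    }
    cmap <- crosscorrelogram(vox$traces, vox$labels, vox$coords)
    write_table(tibble::as_tibble(cmap$r, .name_repair = "minimal"),
                file.path(config$out_dir, "corrmap.csv"))
    writeLines(cmap$labels, file.path(config$out_dir, "corrmap_labels.txt"))
    if ("rankstat" %in% stages) {
      rs <- anticorr_rank_stat(cmap, max_rank = config$rankstat$max_rank %||% 5)
      write_table(rs, file.path(config$out_dir, "rank_enrichment.csv"))
      out$rank1_max_ratio <- max(rs$ratio[rs$rank == 1])
    }
  }

  if ("opto" %in% stages) {
    p <- config$opto %||% list()
    model <- latent_model(n_regions = 1, latent_corr = diag(1),
                          region_names = "lLH",
                          seed = substream_seed(seed, "pipeline-opto"))
    pulses <- tibble::tibble(
      onset_s = 90 + (seq_len(p$n_pulses %||% 10) - 1) * 190,
      duration_s = 10
    )
    gen <- generate_opto_session(model, pulses, effect = p$effect %||% 0.3,
                                 window_s = 90)
    gen$session$ts <- compute_dff(gen$session$ts)
    res <- opto_summary(gen$session, tail = p$tail %||% "two")
    write_table(res, file.path(config$out_dir, "opto_stats.csv"))
    out$opto <- res
  }

  if ("bouts" %in% stages) {
    p <- config$bouts %||% list()
    gen <- generate_bout_stream(p$p_hunt %||% 0.2, p$bout_rate_hz %||% 1,
                                p$duration_s %||% 2700,
                                seed = substream_seed(seed, "pipeline-bouts"))
    bs <- hunting_probability(gen$bouts)
    write_table(bs, file.path(config$out_dir, "bin_stats.csv"))
    out$bins <- nrow(bs)
  }

  if ("gut" %in% stages) {
    p <- config$gut %||% list()
    gen <- generate_gut_image(p$total_signal %||% 1000,
                              seed = substream_seed(seed, "pipeline-gut"))
    gf <- gut_fluorescence(gen$image, gen$gut_mask, gen$background_mask)
    write_table(gf, file.path(config$out_dir, "gut.csv"))
    out$gut_integrated <- gf$integrated
  }

  resolved <- config
  resolved$seed <- seed
  resolved$stages <- stages
  resolved$package_version <- as.character(utils::packageVersion("hypoquant"))
  jsonlite::write_json(resolved, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  jsonlite::write_json(out, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(config$out_dir)
}
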