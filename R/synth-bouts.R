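## Synthetic swim-bout streams with label-conditioned posture features.

bout_label_set <- c("j-turn", "pursuit", "abort", "strike", "exploratory")
hunting_label_probs <- c("j-turn" = 0.25, "pursuit" = 0.45,
                         "abort" = 0.20, "strike" = 0.10)

## Deterministic 220-dim posture template per bout type: hunting bouts carry
## larger, asymmetric tail curvature and converged eyes.
bout_template <- function(label, n_frames = 10, n_segments = 20) {
  amp <- switch(label,
    "j-turn" = 0.9, "pursuit" = 0.4, "abort" = 0.5, "strike" = 0.7,
    "exploratory" = 0.12)
  eye <- switch(label,
    "exploratory" = c(5, 5), c(32, 32)) * pi / 180
  unlist(lapply(seq_len(n_frames), function(fr) {
    phase <- fr / n_frames
    tail <- amp * sin(seq_len(n_segments) / n_segments * pi) * sin(2 * pi * phase)
    c(tail, eye)
  }))
}

#' Generate a Bernoulli bout-label stream with time-varying hunting rate
#'
#' Bout onset times follow a homogeneous Poisson process at `bout_rate_hz`;
#' each bout is labeled hunting with probability `p_hunt(t)` and then
#' assigned a hunting bout type (j-turn / pursuit / abort / strike) or
#' `exploratory`. Each bout carries a 220-dimensional posture vector drawn
#' from a label-conditioned Gaussian around a deterministic template.
#'
#' @param p_hunt Hunting probability: a single number in `[0, 1]` or a
#'   function of time (s) returning values in `[0, 1]`.
#' @param bout_rate_hz Bout rate (bouts/s, >= 0).
#' @param duration_s Stream duration (s).
#' @param seed Integer seed.
#' @param fish_id,group Identifiers copied into the table.
#' @param feature_sd Per-dimension Gaussian sd around the label template.
#' @return A list with `bouts` (a tibble with `bout_start`, `label`,
#'   `hunting`, `fish_id`, `group` and a 220-column `features` matrix-column)
#'   and `truth` (the per-bout true hunting probability).
#' @export
generate_bout_stream <- function(p_hunt, bout_rate_hz, duration_s, seed = 1L,
                                 fish_id = "fish01", group = "dep",
                                 feature_sd = 0.05) {
  check_scalar_pos(bout_rate_hz, "bout_rate_hz", strict = FALSE)
  check_scalar_pos(duration_s, "duration_s")
  pfun <- if (is.function(p_hunt)) p_hunt else function(t) rep(p_hunt, length(t))
  with_seed(substream_seed(seed, "bouts"), {
    n <- rpois(1, bout_rate_hz * duration_s)
    times <- sort(runif(n, 0, duration_s))
    p <- pfun(times)
    if (length(p) != n) p <- rep_len(p, n)
    if (any(p < 0 | p > 1)) abort("p_hunt must lie in [0, 1].")
    hunting <- as.logical(rbinom(n, 1, p))
    label <- character(n)
    label[!hunting] <- "exploratory"
    n_h <- sum(hunting)
    if (n_h > 0) {
      label[hunting] <- sample(names(hunting_label_probs), n_h, replace = TRUE,
                               prob = hunting_label_probs)
    }
    feats <- matrix(0, n, 220)
    for (lb in unique(label)) {
      idx <- which(label == lb)
      tmpl <- bout_template(lb)
      feats[idx, ] <- matrix(tmpl, length(idx), 220, byrow = TRUE) +
        matrix(rnorm(length(idx) * 220, 0, feature_sd), length(idx))
    }
    bouts <- tibble::tibble(
      bout_start = times, label = label, hunting = hunting,
      fish_id = fish_id, group = group
    )
    bouts$features <- feats
    list(bouts = bouts, truth = list(p_hunt = p, labels = label))
  })
}
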