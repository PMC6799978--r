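## Internal helpers shared across modules.

#' Derive a reproducible substream seed from a user seed and a stream name
#'
#' All randomness in the package flows from a single user seed; each
#' generator draws from its own named substream so that adding a stage never
#' perturbs another stage's stream.
#'
#' @param seed Integer user seed.
#' @param name Character stream name.
#' @return An integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483647)
}

## Run code under a local RNG state so generators never disturb the caller's
## random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

## Validate a correlation matrix: symmetric, unit diagonal, PSD up to tol.
check_corr_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("`latent_corr` must be a square matrix.")
  }
  if (max(abs(m - t(m))) > 1e-12) abort("`latent_corr` must be symmetric.")
  if (max(abs(diag(m) - 1)) > 1e-12) abort("`latent_corr` must have unit diagonal.")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    abort(sprintf(
      "`latent_corr` is not positive semi-definite: smallest eigenvalue %.3e.",
      min(ev)
    ))
  }
  invisible(m)
}

## Cholesky-like factor tolerant of a PSD (possibly singular) matrix.
psd_factor <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), nrow = length(v))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

check_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a single %s number.", name,
                  if (strict) "positive" else "non-negative"))
  }
  invisible(x)
}

## Exact (uniformly-spaced) block means along one dimension are built from
## cumulative sums; used by box filters and downsampling.
running_mean <- function(x, width) {
  n <- length(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Separable box-filter local mean for 2-D or 3-D arrays, window given in
## voxels per axis (odd lengths enforced by rounding up).
local_mean_filter <- function(a, width) {
  d <- dim(a)
  width <- pmax(as.integer(width), 1L)
  if (length(width) == 1L) width <- rep(width, length(d))
  out <- a
  for (ax in seq_along(d)) {
    if (width[ax] <= 1L) next
    out <- apply(out, setdiff(seq_along(d), ax), running_mean, width = width[ax])
    ## apply() puts the filtered axis first; restore original order
    perm <- order(c(ax, setdiff(seq_along(d), ax)))
    out <- aperm(array(out, dim = c(d[ax], d[-ax])), perm)
  }
  out
}
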