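#' Derive a reproducible sub-stream seed
#'
#' Maps a top-level seed and a stream identifier (e.g. a session id or a
#' `(session, roi)` pair) to a deterministic 31-bit integer seed, so that
#' every simulated session and ROI gets an independent but reproducible
#' random stream.
#'
#' @param seed Top-level integer seed.
#' @param ... One or more identifiers (coerced to character) naming the stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

#' Z-score a numeric vector
#'
#' Constant vectors (zero variance) are returned as all zeros rather than
#' NaN, so that reaction-time regressors from degenerate sessions stay usable.
#'
#' @param x Numeric vector.
#' @return Centered, unit-variance vector.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Truncated-normal sampler (lower bound only) via inverse CDF.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  pmin(stats::qnorm(u, mean, sd), mean + 8 * sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

check_prob <- function(p, name) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_param(sprintf("'%s' must be a probability in [0, 1]", name))
  }
  invisible(p)
}

#' Side coding helpers
#'
#' Sides are stored as the strings `"left"`/`"right"` and coded numerically
#' as -1/+1 for all regression models (symmetric coding, so a side-bias
#' intercept is interpretable and relabeling left/right only flips slope
#' signs).
#'
#' @param side Character vector of `"left"`/`"right"`.
#' @return Numeric vector of -1/+1 (`side_code`); character vector
#'   (`code_side`).
#' @export
side_code <- function(side) {
  out <- ifelse(side == "right", 1, ifelse(side == "left", -1, NA_real_))
  out
}

#' @rdname side_code
#' @param code Numeric vector of -1/+1.
#' @export
code_side <- function(code) ifelse(code > 0, "right", "left")
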