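# Internal helpers: classed conditions, weighted moments, misc numerics.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("deatonuv_config_error", "deatonuv_error")))
}

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("deatonuv_validation_error", "deatonuv_error")))
}

stop_estimation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("deatonuv_estimation_error", "deatonuv_error")))
}

stop_generation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("deatonuv_generation_error", "deatonuv_error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Weighted mean, standard deviation and quantiles
#'
#' Survey-weighted moments used by [survey_descriptives()]. The quantile is the
#' value at which the weighted empirical CDF first reaches the target
#' probability, which reduces to the type-1 sample quantile under unit weights.
#'
#' @param x numeric vector.
#' @param w non-negative weights, recycled to `length(x)`.
#' @param probs quantile probabilities in `[0, 1]`.
#' @param na.rm drop missing `x` (and their weights) first.
#' @return `weighted_mean`/`weighted_sd`: a scalar. `weighted_quantile`: a
#'   named vector of the same length as `probs`.
#' @keywords internal
#' @name weighted-moments
NULL

#' @rdname weighted-moments
weighted_mean <- function(x, w = NULL, na.rm = FALSE) {
  if (is.null(w)) w <- rep(1, length(x))
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]; w <- w[keep]
  }
  sw <- sum(w)
  if (sw <= 0) stop_validation("weights sum to zero; cannot form weighted mean")
  sum(w * x) / sw
}

#' @rdname weighted-moments
weighted_sd <- function(x, w = NULL, na.rm = FALSE) {
  if (is.null(w)) w <- rep(1, length(x))
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]; w <- w[keep]
  }
  sw <- sum(w)
  if (sw <= 0) stop_validation("weights sum to zero; cannot form weighted SD")
  m <- sum(w * x) / sw
  # frequency-weight convention with (n-1)-style correction via effective n
  neff <- sw^2 / sum(w^2)
  v <- sum(w * (x - m)^2) / sw * neff / max(neff - 1, 1)
  sqrt(v)
}

#' @rdname weighted-moments
weighted_quantile <- function(x, w = NULL, probs = c(0.1, 0.9), na.rm = FALSE) {
  if (is.null(w)) w <- rep(1, length(x))
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]; w <- w[keep]
  }
  if (sum(w) <= 0) stop_validation("weights sum to zero; cannot form quantiles")
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  out <- vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
  names(out) <- paste0("q", format(100 * probs, trim = TRUE))
  out
}

harmonic_mean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (!length(x)) return(NA_real_)
  length(x) / sum(1 / x)
}

# Run `expr` under a given seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}
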