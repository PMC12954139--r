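# Internal condition helpers and shared numerics.

stop_domain <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("omam_domain_error", "omam_error", "error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("omam_format_error", "omam_error", "error")))
}

stop_usage <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("omam_usage_error", "omam_error", "error")))
}

check_positive_finite <- function(x, what) {
  if (length(x) == 0L) stop_domain("'%s' is empty", what)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_domain("'%s' must be finite and numeric", what)
  }
  if (any(x <= 0)) stop_domain("'%s' must be strictly positive", what)
  invisible(x)
}

# Per-stream seed derivation: one user-facing seed expands into independent
# substream seeds so adding a new draw never perturbs existing streams.
# Kept below 2^31 - 1 so set.seed() always accepts the result.
derive_seed <- function(seed, stream) {
  v <- ((as.numeric(seed) %% 2147483647) * 7919 + 104729 * as.numeric(stream)) %% 2147483647
  as.integer(v)
}

#' Empirical quantile under the package's configurable estimator
#'
#' The default rule is the weighted average at rank `(n + 1) * p` on the
#' sorted sample (R's `type = 6`), clamped to the observed extremes. The rule
#' is shared by demographic summaries and reference-threshold derivation so
#' that both report consistent percentiles.
#'
#' @param x numeric vector, finite.
#' @param probs probabilities in (0, 1).
#' @param type quantile estimator, an integer passed to [stats::quantile()]
#'   (default 6, the `(n + 1) p` interpolation rule).
#' @return numeric vector of quantiles.
#' @export
empirical_quantile <- function(x, probs, type = 6L) {
  if (length(x) == 0L) stop_domain("quantile of an empty sample")
  if (anyNA(x) || any(!is.finite(x))) stop_domain("quantile input must be finite")
  unname(stats::quantile(x, probs = probs, type = type, names = FALSE))
}

iqr_of <- function(x, type = 6L) {
  q <- empirical_quantile(x, c(0.25, 0.75), type = type)
  q[2] - q[1]
}

round1 <- function(x) round(x, 1)
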