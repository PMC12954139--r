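# The five test procedures the screening workflow relies on, with exact
# small-sample forms that are verifiable by full enumeration:
#   - Spearman rank correlation (exact permutation null at small n)
#   - Mann-Whitney U (exact labeling enumeration, tie-corrected normal else)
#   - Wilcoxon signed rank (exact sign enumeration, tie-corrected normal else)
#   - exact binomial (doubled smaller tail)
#   - McNemar on discordant pairs (exact binomial form or chi-square with
#     continuity correction)
# Two-sided p-values from doubled tails are capped at 1; every result
# records the method actually used. Switchover sample sizes are fixed
# defaults and overridable per call.

new_test_result <- function(test, statistic, p_value, method, sidedness, n,
                            estimate = NA_real_, status = "ok", details = list()) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 method = method, sidedness = sidedness, n = n,
                 estimate = estimate, status = status, details = details),
            class = "omam_test")
}

#' @export
print.omam_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %s (%s, %s, n = %s)%s\n",
              x$test, format(x$statistic, digits = 4),
              format(x$p_value, digits = 4), x$method, x$sidedness,
              paste(x$n, collapse = "+"),
              if (x$status != "ok") paste0(" [", x$status, "]") else ""))
  invisible(x)
}

#' Render a test result as a flat JSON record
#'
#' @param x an `omam_test`.
#' @return JSON string `{test, statistic, p, method, sidedness, n}`.
#' @export
test_result_json <- function(x) {
  stopifnot(inherits(x, "omam_test"))
  jsonlite::toJSON(list(test = x$test, statistic = x$statistic, p = x$p_value,
                        method = x$method, sidedness = x$sidedness, n = x$n,
                        status = x$status),
                   auto_unbox = TRUE, digits = NA, na = "null")
}

# All n! permutations of 1..n as a matrix (n <= 9); grown recursively.
perm_index <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_index(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

EPS <- 1e-9

#' Spearman rank correlation test
#'
#' Rho is the product-moment correlation of midranks. Two-sided p-value by
#' exact permutation enumeration for `n <= exact_limit` (default 10), else
#' by the t approximation with `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @param exact_limit largest n for the exact permutation null.
#' @return an `omam_test` with `estimate` = rho. Zero-variance input yields
#'   status `"not_computable"` with `p_value = NA`.
#' @export
spearman_test <- function(x, y, exact_limit = 10L) {
  if (length(x) != length(y)) stop_domain("x and y must be paired")
  n <- length(x)
  if (n < 4) stop_domain("spearman_test needs n >= 4")
  if (anyNA(c(x, y)) || any(!is.finite(c(x, y)))) stop_domain("inputs must be finite")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(new_test_result("spearman", NA_real_, NA_real_, "none", "two_sided",
                           n, status = "not_computable"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    # Null distribution of rho over all n! pairings, enumerated in chunks
    # over the first position to bound memory at n = 10.
    rho_of <- function(perm_mat) {
      tx <- (rx - mean(rx)) / stats::sd(rx)
      ty <- (ry - mean(ry)) / stats::sd(ry)
      as.numeric(matrix(ty[perm_mat], nrow(perm_mat)) %*% tx) / (n - 1)
    }
    if (n <= 9L) {
      rho_null <- rho_of(perm_index(n))
    } else {
      sub <- perm_index(n - 1L)
      rho_null <- unlist(lapply(seq_len(n), function(i) {
        rest <- seq_len(n)[-i]
        rho_of(cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
      }))
    }
    p <- mean(abs(rho_null) >= abs(rho) - EPS)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    method <- "normal_approx"
  }
  new_test_result("spearman", rho, p, method, "two_sided", n, estimate = rho)
}

mw_u_stat <- function(ranks_a, n_a, n_b) sum(ranks_a) - n_a * (n_a + 1) / 2

#' Mann-Whitney U test
#'
#' U counts, with midrank tie handling, the pairs in which a value from the
#' first group exceeds one from the second. Exact two-sided p by
#' enumerating all group labelings when `nA + nB <= exact_limit` (default
#' 12) and the data are tie-free; otherwise normal approximation with tie
#' and continuity corrections. `method = "exact"` forces enumeration
#' (valid with ties, conditioning on the observed midranks).
#'
#' @param a,b nonempty numeric vectors.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param exact_limit largest `nA + nB` for the automatic exact path.
#' @return an `omam_test` with statistic U (first group).
#' @export
mann_whitney_test <- function(a, b, method = c("auto", "exact", "normal"),
                              exact_limit = 12L) {
  method <- match.arg(method)
  if (!length(a) || !length(b)) stop_domain("both groups must be nonempty")
  if (anyNA(c(a, b)) || any(!is.finite(c(a, b)))) stop_domain("inputs must be finite")
  na <- length(a); nb <- length(b); nn <- na + nb
  r <- rank(c(a, b))
  u <- mw_u_stat(r[seq_len(na)], na, nb)
  mu <- na * nb / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (method == "auto") {
    method <- if (nn <= exact_limit && !has_ties) "exact" else "normal"
  }
  if (method == "exact") {
    combs <- utils::combn(nn, na)
    u_null <- apply(combs, 2, function(idx) mw_u_stat(r[idx], na, nb))
    p <- mean(abs(u_null - mu) >= abs(u - mu) - EPS)
  } else {
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma <- sqrt(na * nb / 12 * ((nn + 1) - tie_term))
    if (sigma == 0) {
      return(new_test_result("mann_whitney", u, NA_real_, "normal_approx",
                             "two_sided", c(na, nb), status = "not_computable"))
    }
    z <- (u - mu - 0.5 * sign(u - mu)) / sigma
    if (u == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  new_test_result("mann_whitney", u, p, method, "two_sided", c(na, nb))
}

#' Wilcoxon signed-rank test
#'
#' W+ is the sum of midranks of |d| over positive differences. Zero
#' differences are dropped (classical treatment) with the count recorded in
#' `details$n_zeros`. Exact two-sided p by enumerating all 2^n sign vectors
#' for `n <= exact_limit` (default 15), else normal approximation with tie
#' and continuity corrections.
#'
#' @param d numeric vector of paired differences.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param exact_limit largest n (after dropping zeros) for the exact path.
#' @return an `omam_test` with statistic W+. All-zero differences yield
#'   status `"not_computable"`.
#' @export
wilcoxon_signed_rank_test <- function(d, method = c("auto", "exact", "normal"),
                                      exact_limit = 15L) {
  method <- match.arg(method)
  if (!length(d)) stop_domain("differences must be nonempty")
  if (anyNA(d) || any(!is.finite(d))) stop_domain("differences must be finite")
  n_zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(new_test_result("wilcoxon_signed_rank", NA_real_, NA_real_, "none",
                           "two_sided", 0L, status = "not_computable",
                           details = list(n_zeros = n_zeros)))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (method == "auto") method <- if (n <= exact_limit) "exact" else "normal"
  if (method == "exact") {
    signs <- matrix(as.integer(intToBits(seq_len(2^n) - 1L)), nrow = 32L)[seq_len(n), , drop = FALSE]
    w_null <- as.numeric(crossprod(signs, r))
    p <- mean(abs(w_null - mu) >= abs(w - mu) - EPS)
  } else {
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    if (sigma == 0) {
      return(new_test_result("wilcoxon_signed_rank", w, NA_real_, "normal_approx",
                             "two_sided", n, status = "not_computable",
                             details = list(n_zeros = n_zeros)))
    }
    z <- (w - mu - 0.5 * sign(w - mu)) / sigma
    if (w == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  new_test_result("wilcoxon_signed_rank", w, p, method, "two_sided", n,
                  details = list(n_zeros = n_zeros))
}

#' Exact binomial test
#'
#' Two-sided p-value by the doubled-smaller-tail rule, capped at 1 (not the
#' minimum-likelihood convention). Both one-sided tails are reported in
#' `details`.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials.
#' @param p0 null proportion in (0, 1).
#' @return an `omam_test` with `estimate` = k/n.
#' @export
binomial_test <- function(k, n, p0) {
  if (!(is.numeric(k) && is.numeric(n) && k >= 0 && n >= 1 && k <= n &&
        k == round(k) && n == round(n))) {
    stop_domain("need integer counts with 0 <= k <= n")
  }
  if (!(p0 > 0 && p0 < 1)) stop_domain("p0 must lie in (0, 1)")
  p_lower <- stats::pbinom(k, n, p0)
  p_upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  p <- min(1, 2 * min(p_lower, p_upper))
  new_test_result("binomial", k, p, "exact", "two_sided", n, estimate = k / n,
                  details = list(p_lower = p_lower, p_upper = p_upper, p0 = p0))
}

#' McNemar test on discordant pairs
#'
#' For discordant counts `b` and `c`: exact binomial form (doubled tail of
#' `min(b, c)` against Binomial(b + c, 1/2), capped at 1) when
#' `b + c < exact_limit` (default 25); otherwise the chi-square statistic
#' with continuity correction, `(|b - c| - 1)^2 / (b + c)`, on 1 degree of
#' freedom.
#'
#' @param b,c non-negative discordant counts.
#' @param exact_limit smallest `b + c` at which the chi-square form is used.
#' @return an `omam_test`; `b + c = 0` yields `p = 1` with status
#'   `"no_discordance"`.
#' @export
mcnemar_test <- function(b, c, exact_limit = 25L) {
  if (!(is.numeric(b) && is.numeric(c) && b >= 0 && c >= 0 &&
        b == round(b) && c == round(c))) {
    stop_domain("discordant counts must be non-negative integers")
  }
  m <- b + c
  if (m == 0) {
    return(new_test_result("mcnemar", 0, 1, "exact", "two_sided", 0L,
                           status = "no_discordance",
                           details = list(b = b, c = c)))
  }
  if (m < exact_limit) {
    x <- min(b, c)
    p <- min(1, 2 * stats::pbinom(x, m, 0.5))
    new_test_result("mcnemar", x, p, "exact", "two_sided", m,
                    details = list(b = b, c = c))
  } else {
    stat <- (abs(b - c) - 1)^2 / m
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    new_test_result("mcnemar", stat, p, "chi_square_cc", "two_sided", m,
                    details = list(b = b, c = c))
  }
}
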