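# Independent brute-force oracles for the exact statistics and the quantile
# estimator. These deliberately share no code with the package: direct
# definition-level computation, full enumeration at tiny n.

# (n + 1) p rank interpolation on the sorted sample, clamped to extremes.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n + 1) * p
  if (h <= 1) return(s[1])
  if (h >= n) return(s[n])
  lo <- floor(h)
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# all permutations of 1..n, plain recursion
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# U by direct pair counting (ties count 1/2)
oracle_u <- function(a, b) {
  sum(outer(a, b, function(u, v) (u > v) + 0.5 * (u == v)))
}

oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_obs <- oracle_u(a, b)
  mu <- na * length(b) / 2
  labelings <- utils::combn(length(pooled), na)
  u_all <- apply(labelings, 2, function(idx) oracle_u(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

oracle_wsr_stat <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  sum(r[d > 0])
}

oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

oracle_binom_p <- function(k, n, p0) {
  pmf <- stats::dbinom(0:n, n, p0)
  lower <- sum(pmf[seq_len(k + 1)])
  upper <- sum(pmf[(k + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

oracle_mcnemar_p <- function(b, c) {
  m <- b + c
  if (m == 0) return(1)
  x <- min(b, c)
  min(1, 2 * sum(stats::dbinom(0:x, m, 0.5)))
}

oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  rhos <- vapply(oracle_perms(length(x)),
                 function(p) stats::cor(rx, ry[p]), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-9)
}

# small in-memory cohort builder
make_cohort <- function(n = 12, seed = 99, sexes = NULL) {
  set.seed(seed)
  sex <- if (is.null(sexes)) sample(c("male", "female"), n, replace = TRUE) else sexes
  cohort(subject_id = sprintf("T%03d", seq_len(n)),
         sex = sex,
         age_years = runif(n, 20, 75),
         height_m = rnorm(n, ifelse(sex == "male", 1.71, 1.60), 0.05),
         weight_kg = runif(n, 45, 80))
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
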