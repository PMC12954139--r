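test_that("spearman handles perfect, reversed and degenerate association", {
  x <- c(3, 9, 1, 7, 5)
  expect_equal(spearman_test(x, x)$estimate, 1)
  expect_equal(spearman_test(x, -x)$estimate, -1)
  flat <- spearman_test(x, rep(1, 5))
  expect_equal(flat$status, "not_computable")
  expect_true(is.na(flat$p_value))
  expect_error(spearman_test(1:3, 1:3), class = "omam_domain_error")
})

test_that("small-n spearman equals full permutation enumeration", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  res <- spearman_test(x, y)
  expect_equal(res$estimate, 0.8)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, oracle_spearman_p(x, y))
  withr::with_seed(71, {
    for (i in 1:8) {
      n <- sample(4:7, 1)
      a <- rnorm(n)
      b <- if (i %% 2) rnorm(n) else round(rnorm(n))  # ties half the time
      expect_equal(spearman_test(a, b)$p_value, oracle_spearman_p(a, b))
    }
  })
  # t approximation beyond the exact limit
  big <- spearman_test(rnorm(60), rnorm(60))
  expect_equal(big$method, "normal_approx")
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("mann-whitney exact p matches labeling enumeration, ties use midranks", {
  res <- mann_whitney_test(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / 6)
  expect_equal(res$method, "exact")

  same <- mann_whitney_test(c(1, 2, 3), c(1, 2, 3), method = "exact")
  expect_equal(same$p_value, 1)
  tied <- mann_whitney_test(1, 1, method = "exact")
  expect_equal(tied$statistic, 0.5)
  expect_error(mann_whitney_test(numeric(0), 1), class = "omam_domain_error")
})

test_that("wilcoxon signed-rank enumerates signs exactly and drops zeros", {
  res <- wilcoxon_signed_rank_test(1:5)
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 2 / 32)
  sym <- wilcoxon_signed_rank_test(c(1, -1))
  expect_equal(sym$p_value, 1)
  withz <- wilcoxon_signed_rank_test(c(0, 1, 2, 3))
  expect_equal(withz$n, 3)
  expect_equal(withz$details$n_zeros, 1)
  allz <- wilcoxon_signed_rank_test(c(0, 0))
  expect_equal(allz$status, "not_computable")
})

test_that("binomial doubled-tail p matches pmf summation", {
  res <- binomial_test(0, 40, 0.025)
  expect_equal(res$details$p_lower, 0.975^40)
  expect_equal(res$p_value, min(1, 2 * 0.975^40))
  expect_equal(res$p_value, oracle_binom_p(0, 40, 0.025))
  # boundary sanity: observing all successes under a near-1 null
  expect_gt(binomial_test(40, 40, 0.999)$p_value, 0.9)
  # the reference coverage check: 9 of 367 vs 2.5% is non-significant
  cov9 <- binomial_test(9, 367, 0.025)
  expect_equal(round(100 * cov9$estimate, 2), 2.45)
  expect_gt(cov9$p_value, 0.05)
  expect_error(binomial_test(5, 4, 0.5), class = "omam_domain_error")
})

test_that("mcnemar uses the exact binomial form then chi-square with correction", {
  expect_equal(mcnemar_test(0, 0)$p_value, 1)
  expect_equal(mcnemar_test(0, 0)$status, "no_discordance")
  res <- mcnemar_test(5, 1)
  expect_equal(res$p_value, 14 / 64)
  expect_equal(res$method, "exact")
  expect_equal(mcnemar_test(7, 7)$p_value, 1)
  big <- mcnemar_test(30, 10)
  expect_equal(big$method, "chi_square_cc")
  expect_equal(big$statistic, (abs(30 - 10) - 1)^2 / 40)
  expect_equal(big$p_value, pchisq(big$statistic, 1, lower.tail = FALSE))
})

test_that("every exact procedure equals brute-force enumeration at n <= 8", {
  withr::with_seed(88, {
    for (i in 1:25) {
      na <- sample(1:4, 1); nb <- sample(1:4, 1)
      vals <- if (i %% 3 == 0) sample(1:4, na + nb, replace = TRUE) else rnorm(na + nb)
      a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
      expect_equal(mann_whitney_test(a, b, method = "exact")$p_value,
                   oracle_mw_p(a, b), info = sprintf("mw case %d", i))

      n <- sample(2:8, 1)
      d <- if (i %% 4 == 0) sample(-3:3, n, replace = TRUE) else rnorm(n)
      if (any(d != 0)) {
        expect_equal(wilcoxon_signed_rank_test(d, method = "exact")$p_value,
                     oracle_wsr_p(d), info = sprintf("wsr case %d", i))
      }
      nn <- sample(1:8, 1); k <- sample(0:nn, 1); p0 <- runif(1, 0.05, 0.95)
      expect_equal(binomial_test(k, nn, p0)$p_value, oracle_binom_p(k, nn, p0))
    }
    for (bb in 0:8) for (cc in 0:(8 - bb)) {
      expect_equal(mcnemar_test(bb, cc)$p_value, oracle_mcnemar_p(bb, cc))
    }
  })
})

test_that("rank tests are invariant under strictly monotone transforms", {
  trans <- list(function(z) exp(z), function(z) z^3, function(z) atan(z) * 5)
  withr::with_seed(17, {
    for (f in trans) {
      x <- rnorm(15); y <- rnorm(15)
      expect_equal(spearman_test(f(x), f(y))$estimate, spearman_test(x, y)$estimate)
      a <- rnorm(6); b <- rnorm(6)
      expect_equal(mann_whitney_test(f(a), f(b))$p_value,
                   mann_whitney_test(a, b)$p_value)
    }
  })
})

test_that("two-sided p-values stay in [0, 1] under doubling", {
  withr::with_seed(5, {
    ps <- c(
      replicate(30, binomial_test(rbinom(1, 20, 0.5), 20, 0.5)$p_value),
      replicate(30, {b <- rbinom(1, 10, 0.5); mcnemar_test(b, 10 - b)$p_value}),
      replicate(30, wilcoxon_signed_rank_test(rnorm(8))$p_value),
      replicate(30, mann_whitney_test(rnorm(4), rnorm(4))$p_value))
    expect_true(all(ps >= 0 & ps <= 1))
  })
})

test_that("all tests hold their nominal 5% size under null simulation", {
  withr::with_seed(2718, {
    r_sp <- mean(replicate(1000, spearman_test(rnorm(50), rnorm(50))$p_value < 0.05))
    r_mw <- mean(replicate(1000, mann_whitney_test(rnorm(40), rnorm(40))$p_value < 0.05))
    r_ws <- mean(replicate(1000, wilcoxon_signed_rank_test(rnorm(60))$p_value < 0.05))
    r_bi <- mean(replicate(1000, binomial_test(rbinom(1, 500, 0.5), 500, 0.5)$p_value < 0.05))
    r_mc <- mean(replicate(1000, {b <- rbinom(1, 40, 0.5); mcnemar_test(b, 40 - b)$p_value < 0.05}))
  })
  for (r in c(r_sp, r_mw, r_ws, r_bi, r_mc)) {
    expect_gte(r, 0.03)
    expect_lte(r, 0.07)
  }
})

test_that("results render to flat JSON records", {
  j <- jsonlite::fromJSON(test_result_json(binomial_test(2, 10, 0.3)))
  expect_equal(j$test, "binomial")
  expect_equal(j$n, 10)
  expect_true(j$p >= 0 && j$p <= 1)
})
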