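# Equation-validation protocol: a balanced 7:3 random split of the
# reference cohort, the three predefined acceptance conditions applied to
# the held-out subgroup, and binomial coverage verification of the derived
# threshold.

#' Split a cohort 7:3 with covariate balance
#'
#' Random partition at `ratio`, re-drawn (with a derived seed per attempt)
#' until no balance test is significant at `alpha`: Mann-Whitney for age,
#' height, weight and BMI, and a two-proportion chi-square for the sex
#' ratio. Re-randomization reproduces the published protocol's guarantee of
#' no significant between-subgroup difference, with the seed and attempt
#' count recorded.
#'
#' @param x an `omam_cohort` with at least 20 subjects.
#' @param ratio fraction allocated to subgroup A (default 0.7).
#' @param seed integer seed; the same seed yields the same partition.
#' @param max_attempts maximum re-draws before failing.
#' @param alpha balance significance level (default 0.05).
#' @return an `omam_split`: list with `subgroup_a`, `subgroup_b`,
#'   `balance_report` (tibble: variable, p_value), `seed`, `attempts`.
#' @export
split_cohort <- function(x, ratio = 0.7, seed = 1L, max_attempts = 100L,
                         alpha = 0.05) {
  stopifnot(inherits(x, "omam_cohort"))
  n <- nrow(x)
  if (n < 20) stop_domain("splitting needs n >= 20 (got %d)", n)
  if (!(ratio > 0 && ratio < 1)) stop_domain("ratio must lie in (0, 1)")
  n_a <- round(n * ratio)
  bmi <- body_mass_index(x$weight_kg, x$height_m)
  worst <- c(variable = "none", p = "1")
  for (attempt in seq_len(max_attempts)) {
    idx_a <- withr::with_seed(derive_seed(seed, 700 + attempt),
                              sort(sample.int(n, n_a)))
    in_a <- seq_len(n) %in% idx_a
    balance <- tibble::tibble(
      variable = c("sex", "age", "height", "weight", "bmi"),
      p_value = c(
        suppressWarnings(stats::prop.test(
          c(sum(x$sex[in_a] == "male"), sum(x$sex[!in_a] == "male")),
          c(n_a, n - n_a))$p.value),
        mann_whitney_test(x$age_years[in_a], x$age_years[!in_a])$p_value,
        mann_whitney_test(x$height_m[in_a], x$height_m[!in_a])$p_value,
        mann_whitney_test(x$weight_kg[in_a], x$weight_kg[!in_a])$p_value,
        mann_whitney_test(bmi[in_a], bmi[!in_a])$p_value))
    if (all(balance$p_value >= alpha, na.rm = TRUE)) {
      sub_a <- x[in_a, ]; sub_b <- x[!in_a, ]
      class(sub_a) <- class(x); class(sub_b) <- class(x)
      attr(sub_a, "provenance") <- paste0(attr(x, "provenance"), " [subgroup A]")
      attr(sub_b, "provenance") <- paste0(attr(x, "provenance"), " [subgroup B]")
      return(structure(list(subgroup_a = sub_a, subgroup_b = sub_b,
                            balance_report = balance, seed = seed,
                            attempts = attempt),
                       class = "omam_split"))
    }
    i <- which.min(balance$p_value)
    worst <- c(variable = balance$variable[i], p = format(balance$p_value[i]))
  }
  stop_domain("no balanced split in %d attempts (worst variable: %s, p = %s)",
              max_attempts, worst[["variable"]], worst[["p"]])
}

#' @export
print.omam_split <- function(x, ...) {
  cat(sprintf("Balanced cohort split: %d + %d subjects (seed %d, %d attempt%s)\n",
              nrow(x$subgroup_a), nrow(x$subgroup_b), x$seed, x$attempts,
              if (x$attempts == 1) "" else "s"))
  print(x$balance_report)
  invisible(x)
}

#' Validate allometric equations on an independent subgroup
#'
#' Applies the three predefined conditions for an acceptable weight
#' equation to the corrected weights of a held-out subgroup:
#' \enumerate{
#'   \item the central WC is close to 1 — operationalized as a
#'     non-significant Wilcoxon signed-rank test of `ln WC` against 0
#'     (the protocol reports medians and uses rank tests throughout, so a
#'     rank-based location test is the consistent reading of "close to 1";
#'     the raw median and its distance from 1 are also reported);
#'   \item WC is positively correlated with measured weight
#'     (Spearman, p < alpha and rho > 0);
#'   \item WC is independent of the covariates the model corrects for:
#'     Spearman against age and height both non-significant, and no
#'     Mann-Whitney sex difference.
#' }
#'
#' @param x an `omam_cohort` containing both sexes, n >= 30.
#' @param coeffs an `omam_coefficients` (fitted on the other subgroup).
#' @param alpha significance level (default 0.05).
#' @return an `omam_validation`: medians, the per-condition test results
#'   and pass flags, and `overall_pass`.
#' @export
validate_equations <- function(x, coeffs = published_coefficients(), alpha = 0.05) {
  stopifnot(inherits(x, "omam_cohort"))
  if (nrow(x) < 30) stop_domain("validation needs n >= 30")
  if (length(unique(x$sex)) < 2) stop_domain("validation needs both sexes")
  wp <- predict_weight(coeffs, x$sex, x$age_years, x$height_m)
  wc <- corrected_weight(x$weight_kg, wp)
  not_comp <- function(t) !is.null(t$status) && t$status != "ok"

  t1 <- wilcoxon_signed_rank_test(log(wc))
  cond1 <- list(test = t1, median_wc = stats::median(wc),
                distance_from_1 = abs(stats::median(wc) - 1),
                pass = not_comp(t1) || t1$p_value > alpha)
  # all differences zero means WC == 1 exactly: location condition holds

  t2 <- spearman_test(wc, x$weight_kg)
  cond2 <- list(test = t2,
                pass = !not_comp(t2) && t2$p_value < alpha && t2$estimate > 0)

  t3a <- spearman_test(wc, x$age_years)
  t3h <- spearman_test(wc, x$height_m)
  t3s <- mann_whitney_test(wc[x$sex == "male"], wc[x$sex == "female"])
  p_ok <- function(t) !not_comp(t) && t$p_value > alpha
  cond3 <- list(age = t3a, height = t3h, sex = t3s,
                pass = (p_ok(t3a) || not_comp(t3a)) &&
                       (p_ok(t3h) || not_comp(t3h)) &&
                       (p_ok(t3s) || not_comp(t3s)))

  structure(list(n = nrow(x),
                 median_wc = stats::median(wc),
                 iqr_wc = iqr_of(wc),
                 condition1 = cond1, condition2 = cond2, condition3 = cond3,
                 overall_pass = cond1$pass && cond2$pass && cond3$pass,
                 alpha = alpha),
            class = "omam_validation")
}

#' @export
print.omam_validation <- function(x, ...) {
  cat(sprintf("Equation validation on n = %d (alpha = %g)\n", x$n, x$alpha))
  cat(sprintf("  WC median (IQR): %.4f (%.4f)\n", x$median_wc, x$iqr_wc))
  cat(sprintf("  1. central WC close to 1:        %s (signed-rank p = %s)\n",
              if (x$condition1$pass) "pass" else "FAIL",
              format(x$condition1$test$p_value, digits = 3)))
  cat(sprintf("  2. WC correlated with weight:    %s (rho = %s, p = %s)\n",
              if (x$condition2$pass) "pass" else "FAIL",
              format(x$condition2$test$estimate, digits = 3),
              format(x$condition2$test$p_value, digits = 3)))
  cat(sprintf("  3. WC free of age/height/sex:    %s (p = %s, %s, %s)\n",
              if (x$condition3$pass) "pass" else "FAIL",
              format(x$condition3$age$p_value, digits = 3),
              format(x$condition3$height$p_value, digits = 3),
              format(x$condition3$sex$p_value, digits = 3)))
  cat(sprintf("  overall: %s\n", if (x$overall_pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param x an `omam_validation`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @export
validation_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "omam_validation"))
  flat <- function(t) list(statistic = t$statistic, p = t$p_value,
                           method = t$method, status = t$status)
  obj <- list(n = x$n, median_wc = x$median_wc, iqr_wc = x$iqr_wc,
              condition1 = c(flat(x$condition1$test),
                             list(pass = x$condition1$pass,
                                  median_wc = x$condition1$median_wc)),
              condition2 = c(flat(x$condition2$test),
                             list(pass = x$condition2$pass,
                                  rho = x$condition2$test$estimate)),
              condition3 = list(age = flat(x$condition3$age),
                                height = flat(x$condition3$height),
                                sex = flat(x$condition3$sex),
                                pass = x$condition3$pass),
              overall_pass = x$overall_pass, alpha = x$alpha)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
  }
}

#' Threshold coverage test
#'
#' Exact binomial test of the number of subjects above the overweight
#' cutoff against the nominal upper-tail probability (default 2.5%).
#'
#' @param wc numeric WC scores, or a scored cohort tibble with a `wc`
#'   column.
#' @param threshold an `omam_threshold`.
#' @param expected nominal exceedance probability (default 0.025).
#' @return an `omam_test` with `details$observed_percent`.
#' @export
coverage_test <- function(wc, threshold = published_threshold(), expected = 0.025) {
  if (is.data.frame(wc)) {
    if (!"wc" %in% names(wc)) stop_domain("scored cohort must have a 'wc' column")
    wc <- wc$wc
  }
  if (!length(wc)) stop_domain("empty WC sample")
  stopifnot(inherits(threshold, "omam_threshold"))
  k <- sum(wc > threshold$cutoff)
  n <- length(wc)
  res <- binomial_test(k, n, expected)
  res$details$observed_percent <- 100 * k / n
  res$details$cutoff <- threshold$cutoff
  res
}

#' Paired shift test of measured against predicted weight
#'
#' Wilcoxon signed-rank test on `measured - predicted`, with the direction
#' of the median shift reported.
#'
#' @param measured_kg,predicted_kg aligned positive vectors, n >= 5.
#' @return an `omam_test` with `details$direction` one of
#'   `"predicted_below_measured"`, `"predicted_above_measured"`, `"none"`.
#' @export
paired_shift_test <- function(measured_kg, predicted_kg) {
  if (length(measured_kg) != length(predicted_kg)) stop_domain("pairs must be aligned")
  if (length(measured_kg) < 5) stop_domain("paired shift test needs n >= 5")
  d <- measured_kg - predicted_kg
  res <- wilcoxon_signed_rank_test(d)
  med <- stats::median(d)
  res$details$direction <- if (med > 0) "predicted_below_measured"
                           else if (med < 0) "predicted_above_measured" else "none"
  res
}
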