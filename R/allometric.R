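# The allometric weight model W = c * A^x * H^y with a sex-specific
# constant c, handled throughout on its log-linear form
#   ln W = a + x ln A + y ln H + b G,   G = 1 for men, 0 for women,
# so that ordinary least squares applies. Natural logarithms everywhere.

#' Allometric model coefficients
#'
#' @param a intercept on the log-kg scale (female constant is `exp(a)`).
#' @param b additive sex effect on the log scale, applied when sex is male
#'   (male constant is `exp(a + b)`).
#' @param x age exponent (dimensionless).
#' @param y height exponent (dimensionless).
#' @param label free-text provenance label.
#' @return an `omam_coefficients` object.
#' @export
omam_coefficients <- function(a, b, x, y, label = "custom") {
  for (v in list(a = a, b = b, x = x, y = y)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_domain("coefficients must be finite scalars")
    }
  }
  structure(list(a = a, b = b, x = x, y = y, label = label),
            class = "omam_coefficients")
}

#' @export
print.omam_coefficients <- function(x, digits = 4, ...) {
  cons <- sex_constants(x)
  cat(sprintf("Allometric weight coefficients [%s]\n", x$label))
  cat(sprintf("  ln W = %.*f + %.*f ln A + %.*f ln H + %.*f G\n",
              digits, x$a, digits, x$x, digits, x$y, digits, x$b))
  cat(sprintf("  men:   W = %.*f * A^%.*f * H^%.*f\n",
              digits, cons[["male"]], digits, x$x, digits, x$y))
  cat(sprintf("  women: W = %.*f * A^%.*f * H^%.*f\n",
              digits, cons[["female"]], digits, x$x, digits, x$y))
  invisible(x)
}

#' Published reference coefficients
#'
#' The coefficient set estimated in the healthy Chinese Han reference cohort
#' (subgroup A, n = 857): a = 2.7895, x = 0.0526, y = 2.1659, b = 0.0326.
#' Shipped as a packaged JSON resource and returned exactly as printed.
#'
#' @return an `omam_coefficients` object.
#' @export
published_coefficients <- function() {
  path <- system.file("extdata", "published_coefficients.json", package = "omam",
                      mustWork = TRUE)
  read_coefficients(path)
}

#' Sex-specific multiplicative constants
#'
#' @param coeffs an `omam_coefficients` object.
#' @return named numeric: `female = exp(a)`, `male = exp(a + b)`.
#' @export
sex_constants <- function(coeffs) {
  stopifnot(inherits(coeffs, "omam_coefficients"))
  c(female = exp(coeffs$a), male = exp(coeffs$a + coeffs$b))
}

#' Serialize / deserialize coefficient sets
#'
#' Coefficients travel as a JSON document `{a, b, x, y, label}`.
#'
#' @param coeffs an `omam_coefficients` object.
#' @param path file path.
#' @return `read_coefficients` returns an `omam_coefficients`.
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "omam_coefficients"))
  jsonlite::write_json(unclass(coeffs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop_format("no such coefficients file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("a", "b", "x", "y")
  if (!all(need %in% names(obj))) {
    stop_format("coefficients JSON must contain fields a, b, x, y")
  }
  omam_coefficients(obj$a, obj$b, obj$x, obj$y,
                    label = if (is.null(obj$label)) "file" else obj$label)
}

#' Log-scale design matrix of a cohort
#'
#' @param x an `omam_cohort`.
#' @return data frame with columns `lnW`, `lnA`, `lnH`, `G` (1 = male).
#' @export
log_design <- function(x) {
  stopifnot(inherits(x, "omam_cohort"))
  check_positive_finite(x$age_years, "age_years")
  check_positive_finite(x$height_m, "height_m")
  check_positive_finite(x$weight_kg, "weight_kg")
  data.frame(lnW = log(x$weight_kg), lnA = log(x$age_years),
             lnH = log(x$height_m), G = as.numeric(x$sex == "male"))
}

#' Fit the allometric weight model
#'
#' Ordinary least squares of `ln W` on `ln A`, `ln H` and the sex dummy `G`
#' (QR decomposition via [stats::lm()]). Under `selection = "stepwise"`,
#' forward selection with entry threshold `enter` and backward elimination
#' with removal threshold `remove` over the candidate set
#' `{lnA, lnH, G}`; under `"full"` all three terms are kept.
#'
#' @param x an `omam_cohort` with at least 10 subjects and, for the full
#'   model, both sexes.
#' @param selection `"stepwise"` (default) or `"full"`.
#' @param enter forward-entry p-value threshold (default 0.05).
#' @param remove backward-removal p-value threshold (default 0.10).
#' @return an `omam_fit`: list with `coefficients` (unselected terms are
#'   exactly 0), `selected_terms`, `r2`, `adjusted_r2`, `residual_sd`
#'   (log scale), `p_values`, `n_used`.
#' @export
fit_omam <- function(x, selection = c("stepwise", "full"),
                     enter = 0.05, remove = 0.10) {
  selection <- match.arg(selection)
  d <- log_design(x)
  n <- nrow(d)
  if (n < 10) stop_domain("fitting needs n >= 10 (got %d)", n)
  candidates <- c("lnA", "lnH", "G")
  degen <- vapply(candidates, function(v) stats::var(d[[v]]) == 0, logical(1))
  if (any(degen)) {
    stop_domain("degenerate design: constant predictor(s) %s%s",
                paste(candidates[degen], collapse = ", "),
                if (degen[["G"]]) " (single-sex cohort)" else "")
  }
  term_p <- function(fit, term) {
    s <- stats::coef(summary(fit))
    if (!term %in% rownames(s)) return(NA_real_)
    s[term, "Pr(>|t|)"]
  }
  fit_terms <- function(terms) {
    fml <- stats::reformulate(if (length(terms)) terms else "1", response = "lnW")
    stats::lm(fml, data = d)
  }
  if (selection == "full") {
    selected <- candidates
  } else {
    selected <- character(0)
    repeat {
      changed <- FALSE
      pool <- setdiff(candidates, selected)
      if (length(pool)) {
        entry_p <- vapply(pool, function(v) term_p(fit_terms(c(selected, v)), v),
                          numeric(1))
        if (any(is.finite(entry_p)) && min(entry_p, na.rm = TRUE) <= enter) {
          selected <- c(selected, pool[which.min(entry_p)])
          changed <- TRUE
        }
      }
      repeat {
        if (!length(selected)) break
        cur <- fit_terms(selected)
        pv <- vapply(selected, function(v) term_p(cur, v), numeric(1))
        if (max(pv) >= remove) {
          selected <- setdiff(selected, selected[which.max(pv)])
          changed <- TRUE
        } else break
      }
      if (!changed) break
    }
  }
  fit <- fit_terms(selected)
  s <- summary(fit)
  cf <- stats::coef(fit)
  get0c <- function(nm) if (nm %in% names(cf)) unname(cf[nm]) else 0
  coeffs <- omam_coefficients(a = unname(cf[["(Intercept)"]]),
                              b = get0c("G"), x = get0c("lnA"), y = get0c("lnH"),
                              label = sprintf("fitted (%s, n = %d)", selection, n))
  pv <- stats::coef(s)[, "Pr(>|t|)"]
  structure(list(coefficients = coeffs,
                 selected_terms = selected,
                 r2 = s$r.squared,
                 adjusted_r2 = s$adj.r.squared,
                 residual_sd = s$sigma,
                 p_values = pv,
                 n_used = n,
                 selection = selection),
            class = "omam_fit")
}

#' @export
print.omam_fit <- function(x, ...) {
  cat(sprintf("Allometric model fit (%s selection, n = %d)\n", x$selection, x$n_used))
  cat(sprintf("  selected terms: %s\n",
              if (length(x$selected_terms)) paste(x$selected_terms, collapse = ", ")
              else "(intercept only)"))
  cat(sprintf("  R^2 = %.4f, adjusted R^2 = %.4f, residual sd (log) = %.4f\n",
              x$r2, x$adjusted_r2, x$residual_sd))
  print(x$coefficients)
  invisible(x)
}

#' Predict weight from the allometric model
#'
#' `WP = exp(a + b G) * A^x * H^y`, strictly positive.
#'
#' @param coeffs an `omam_coefficients` object.
#' @param sex sex tokens (see [cohort()]).
#' @param age_years,height_m positive finite numerics.
#' @return predicted weight in kg.
#' @export
predict_weight <- function(coeffs, sex, age_years, height_m) {
  stopifnot(inherits(coeffs, "omam_coefficients"))
  check_positive_finite(age_years, "age_years")
  check_positive_finite(height_m, "height_m")
  g <- parse_sex(sex)
  if (anyNA(g)) stop_domain("unrecognized sex token")
  exp(coeffs$a + coeffs$b * (g == "male")) * age_years^coeffs$x * height_m^coeffs$y
}
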