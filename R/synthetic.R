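# Seeded synthetic-cohort generators with the statistical structure the
# allometric model assumes: sex-balanced adults, uniform ages over the
# reference inclusion window, per-sex normal heights, and log-scale weights
# from the allometric equation plus Gaussian noise. All generators are pure
# functions of (params, seed): one user seed expands into fixed per-stream
# seeds, so adding a generator never perturbs existing draws.

# Log-scale residual sd calibrated once (calibrate_sigma, target adjusted
# R^2 0.6634 under the default covariate models); see the methods vignette.
OMAM_DEFAULT_RESIDUAL_SD <- 0.0809

.streams <- c(sex = 1L, age = 2L, height = 3L, noise = 4L, inflation = 5L,
              disease = 10L, calibrate = 20L)

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the healthy reference population: equal sexes, ages
#' uniform on 18-79 years, heights normal per sex with means 1.71 m (men)
#' and 1.60 m (women) and sd 0.052 m (the reported IQR of 0.07 m divided
#' by 1.349 under a normal model), truncated to (1.2, 2.2) m, and weights
#' from the published allometric coefficients with log-scale Gaussian
#' noise whose default sd is calibrated to an adjusted R² of about 0.6634
#' on refit.
#'
#' @param n number of subjects.
#' @param seed integer seed; generation is deterministic given it.
#' @param sex_ratio proportion male (default 0.5).
#' @param age_range uniform age bounds in years.
#' @param height_mean named per-sex height means in meters.
#' @param height_sd per-sex height sd in meters.
#' @param height_bounds truncation bounds in meters.
#' @param coefficients generating `omam_coefficients`.
#' @param residual_sd log-scale noise sd (>= 0).
#' @return an `omam_generator_params` list.
#' @export
generator_params <- function(n, seed = 1L, sex_ratio = 0.5,
                             age_range = c(18, 79),
                             height_mean = c(male = 1.71, female = 1.60),
                             height_sd = 0.052,
                             height_bounds = c(1.2, 2.2),
                             coefficients = published_coefficients(),
                             residual_sd = OMAM_DEFAULT_RESIDUAL_SD) {
  if (!(is.numeric(n) && n >= 1)) stop_domain("n must be a positive count")
  if (!(sex_ratio >= 0 && sex_ratio <= 1)) stop_domain("sex_ratio must lie in [0, 1]")
  if (residual_sd < 0) stop_domain("residual_sd must be non-negative")
  if (!all(c("male", "female") %in% names(height_mean))) {
    stop_domain("height_mean must name male and female components")
  }
  stopifnot(inherits(coefficients, "omam_coefficients"))
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 sex_ratio = sex_ratio, age_range = age_range,
                 height_mean = height_mean, height_sd = height_sd,
                 height_bounds = height_bounds, coefficients = coefficients,
                 residual_sd = residual_sd),
            class = "omam_generator_params")
}

draw_covariates <- function(params, n, seed_offset = 0L) {
  p <- params
  sex <- withr::with_seed(derive_seed(p$seed, .streams[["sex"]] + seed_offset),
                          ifelse(stats::runif(n) < p$sex_ratio, "male", "female"))
  age <- withr::with_seed(derive_seed(p$seed, .streams[["age"]] + seed_offset),
                          stats::runif(n, p$age_range[1], p$age_range[2]))
  height <- withr::with_seed(derive_seed(p$seed, .streams[["height"]] + seed_offset), {
    h <- stats::rnorm(n, p$height_mean[sex], p$height_sd)
    bad <- h <= p$height_bounds[1] | h >= p$height_bounds[2]
    while (any(bad)) {
      h[bad] <- stats::rnorm(sum(bad), p$height_mean[sex[bad]], p$height_sd)
      bad <- h <= p$height_bounds[1] | h >= p$height_bounds[2]
    }
    h
  })
  list(sex = sex, age = age, height = height)
}

#' Generate a synthetic normal-weight cohort
#'
#' Draws sex, age and height from the generator's covariate models and
#' weights from the allometric equation
#' `ln W = a + x ln A + y ln H + b G + e`, `e ~ N(0, residual_sd^2)`.
#' With `residual_sd = 0` every subject's corrected weight under the
#' generating coefficients is exactly 1.
#'
#' @param params an `omam_generator_params`.
#' @return an `omam_cohort` of `params$n` subjects.
#' @export
generate_normal_cohort <- function(params) {
  stopifnot(inherits(params, "omam_generator_params"))
  n <- params$n
  cv <- draw_covariates(params, n)
  eps <- withr::with_seed(derive_seed(params$seed, .streams[["noise"]]),
                          stats::rnorm(n, 0, params$residual_sd))
  co <- params$coefficients
  lnw <- co$a + co$x * log(cv$age) + co$y * log(cv$height) +
    co$b * (cv$sex == "male") + eps
  df <- data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                   sex = cv$sex, age_years = cv$age, height_m = cv$height,
                   weight_kg = exp(lnw), stringsAsFactors = FALSE)
  new_cohort(df, provenance = sprintf("synthetic normal-weight (seed %d)", params$seed))
}

#' Calibrate the log-scale residual sd to a target adjusted R-squared
#'
#' Estimates the variance `V` of the linear predictor
#' `a + x ln A + y ln H + b G` by Monte Carlo under the generator's
#' covariate models and returns `sqrt(V * (1 - target) / target)`, the
#' noise sd at which a refit on generated data attains approximately the
#' target adjusted R².
#'
#' @param params an `omam_generator_params` (its `residual_sd` is ignored).
#' @param target_adj_r2 target adjusted R² in (0, 1); default 0.6634, the
#'   reference fit's goodness of fit.
#' @param n_mc Monte Carlo draw size.
#' @return the calibrated residual sd.
#' @export
calibrate_sigma <- function(params, target_adj_r2 = 0.6634, n_mc = 200000L) {
  stopifnot(inherits(params, "omam_generator_params"))
  if (!(target_adj_r2 > 0 && target_adj_r2 < 1)) {
    stop_domain("target_adj_r2 must lie in (0, 1)")
  }
  cv <- draw_covariates(params, n_mc, seed_offset = .streams[["calibrate"]])
  co <- params$coefficients
  lp <- co$a + co$x * log(cv$age) + co$y * log(cv$height) + co$b * (cv$sex == "male")
  v <- stats::var(lp)
  if (v <= 0) stop_domain("degenerate covariate models: zero signal variance")
  sqrt(v * (1 - target_adj_r2) / target_adj_r2)
}

#' Generate a synthetic overweight cohort
#'
#' Draws from the normal-weight generator, multiplies weights by an
#' inflation factor (constant, uniform range, or sampling function) and
#' retains subjects meeting the BMI criterion until the requested count —
#' optionally per-sex quotas — is filled.
#'
#' @param params an `omam_generator_params`; `params$n` is the target size.
#' @param inflation multiplicative weight excess >= 1: a scalar, a length-2
#'   uniform range (default `c(1.15, 1.35)`), or `function(n)` returning
#'   draws.
#' @param bmi_cutoff retention criterion (default 25.0 kg/m²).
#' @param sex_quota optional named counts `c(male = , female = )` summing
#'   to `params$n`.
#' @return an `omam_cohort` in which every subject has BMI >= `bmi_cutoff`.
#' @export
generate_overweight_cohort <- function(params, inflation = c(1.15, 1.35),
                                       bmi_cutoff = 25, sex_quota = NULL) {
  stopifnot(inherits(params, "omam_generator_params"))
  n_target <- params$n
  if (!is.null(sex_quota)) {
    if (!all(c("male", "female") %in% names(sex_quota)) ||
        sum(sex_quota) != n_target) {
      stop_domain("sex_quota must name male and female counts summing to n")
    }
  }
  draw_inflation <- if (is.function(inflation)) {
    inflation
  } else if (length(inflation) == 1L) {
    if (inflation < 1) stop_domain("inflation must be >= 1")
    function(n) rep(inflation, n)
  } else {
    if (any(inflation < 1)) stop_domain("inflation range must be >= 1")
    function(n) stats::runif(n, min(inflation), max(inflation))
  }
  kept <- NULL
  n_drawn <- 0L
  batch_n <- max(1000L, 2L * n_target)
  for (batch in seq_len(50L)) {
    bp <- params
    bp$n <- batch_n
    bp$seed <- derive_seed(params$seed, .streams[["inflation"]] + 100L * batch)
    base <- generate_normal_cohort(bp)
    infl <- withr::with_seed(derive_seed(bp$seed, .streams[["inflation"]]),
                             draw_inflation(batch_n))
    base$weight_kg <- base$weight_kg * infl
    keep <- body_mass_index(base$weight_kg, base$height_m) >= bmi_cutoff
    n_drawn <- n_drawn + batch_n
    kept <- rbind(as.data.frame(kept), as.data.frame(base[keep, ]))
    if (batch == 1L && nrow(kept) / n_drawn < 0.01) {
      stop_domain("overweight acceptance rate below 1%%; increase the inflation factor")
    }
    take <- function(df) {
      if (is.null(sex_quota)) return(nrow(df) >= n_target)
      sum(df$sex == "male") >= sex_quota[["male"]] &&
        sum(df$sex == "female") >= sex_quota[["female"]]
    }
    if (take(kept)) break
  }
  enough <- if (is.null(sex_quota)) nrow(kept) >= n_target else {
    sum(kept$sex == "male") >= sex_quota[["male"]] &&
      sum(kept$sex == "female") >= sex_quota[["female"]]
  }
  if (!enough) stop_domain("could not collect %d overweight subjects", n_target)
  if (!is.null(sex_quota)) {
    males <- kept[kept$sex == "male", ][seq_len(sex_quota[["male"]]), ]
    females <- kept[kept$sex == "female", ][seq_len(sex_quota[["female"]]), ]
    kept <- rbind(males, females)
  } else {
    kept <- kept[seq_len(n_target), ]
  }
  kept$subject_id <- sprintf("OW%06d", seq_len(nrow(kept)))
  new_cohort(kept, provenance = sprintf("synthetic overweight (seed %d)", params$seed))
}

#' Logistic disease-label link parameters
#'
#' Per-disease logistic models on the corrected weight:
#' `P(disease) = plogis(intercept + slope * WC)`.
#'
#' @param intercepts,slopes named numerics over a subset of
#'   `c("dm", "htn", "cad", "mets")`.
#' @return an `omam_disease_link` list.
#' @export
disease_link_params <- function(intercepts, slopes) {
  dz <- names(intercepts)
  if (is.null(dz) || !all(dz %in% DISEASE_COLS)) {
    stop_domain("intercepts must be named with diseases among dm, htn, cad, mets")
  }
  if (!identical(sort(dz), sort(names(slopes)))) {
    stop_domain("intercepts and slopes must name the same diseases")
  }
  structure(list(intercepts = intercepts, slopes = slopes[dz]),
            class = "omam_disease_link")
}

#' Tune link intercepts to target disease prevalences
#'
#' Solves, per disease, for the logistic intercept at which the expected
#' prevalence under the generator's WC distribution matches the target.
#'
#' @param prevalence named target prevalences in (0, 1).
#' @param slopes named logistic slopes on WC.
#' @param params an `omam_generator_params` (supplies the WC distribution).
#' @param n_mc Monte Carlo size for the expectation.
#' @return an `omam_disease_link`.
#' @export
calibrate_link_intercepts <- function(prevalence, slopes, params, n_mc = 100000L) {
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop_domain("prevalences must lie strictly in (0, 1)")
  }
  # Under the generating coefficients WC = exp(noise)
  wc_mc <- withr::with_seed(derive_seed(params$seed, .streams[["calibrate"]] + 1L),
                            exp(stats::rnorm(n_mc, 0, params$residual_sd)))
  ints <- vapply(names(prevalence), function(dz) {
    stats::uniroot(function(b0) mean(stats::plogis(b0 + slopes[[dz]] * wc_mc)) - prevalence[[dz]],
                   interval = c(-30, 30))$root
  }, numeric(1))
  disease_link_params(ints, slopes[names(prevalence)])
}

#' Generate a synthetic cohort with disease labels
#'
#' Draws a cohort from the normal-weight generator and assigns each
#' disease label Bernoulli with probability
#' `plogis(intercept + slope * WC)`, where WC is the subject's corrected
#' weight under the generating coefficients.
#'
#' @param params an `omam_generator_params`.
#' @param link an `omam_disease_link`.
#' @return an `omam_cohort` with logical disease flag columns.
#' @export
generate_disease_cohort <- function(params, link) {
  stopifnot(inherits(params, "omam_generator_params"),
            inherits(link, "omam_disease_link"))
  x <- generate_normal_cohort(params)
  wp <- predict_weight(params$coefficients, x$sex, x$age_years, x$height_m)
  wc <- corrected_weight(x$weight_kg, wp)
  df <- as.data.frame(x)
  for (i in seq_along(link$intercepts)) {
    dz <- names(link$intercepts)[i]
    pr <- stats::plogis(link$intercepts[[i]] + link$slopes[[i]] * wc)
    df[[dz]] <- withr::with_seed(derive_seed(params$seed, .streams[["disease"]] + i),
                                 stats::runif(nrow(df)) < pr)
  }
  new_cohort(df, provenance = sprintf("synthetic disease-labelled (seed %d)", params$seed))
}
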