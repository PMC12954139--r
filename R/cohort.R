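# Cohort container: one row per subject with sex, age (years), height (m),
# weight (kg) and optional cardiometabolic disease flags.

DISEASE_COLS <- c("dm", "htn", "cad", "mets")
REQUIRED_COLS <- c("subject_id", "sex", "age_years", "height_m", "weight_kg")

parse_sex <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(tok))
  out[tok %in% c("m", "male", "1")] <- "male"
  out[tok %in% c("f", "female", "0")] <- "female"
  out
}

#' Construct a subject cohort
#'
#' A cohort is a tibble with one row per subject, validated for positive,
#' finite anthropometry, unique subject identifiers, a plausible age range
#' and heights given in meters. Disease flags (diabetes `dm`, hypertension
#' `htn`, coronary artery disease `cad`, metabolic syndrome `mets`) are
#' optional logicals; screening operations require them and fail loudly when
#' absent.
#'
#' @param subject_id character, unique per subject.
#' @param sex accepted tokens: `M`, `F`, `male`, `female`, `1`, `0`
#'   (case-insensitive; `1` maps to male, the model's dummy coding).
#' @param age_years,height_m,weight_kg positive finite numerics. Heights
#'   above 3 m are rejected as probable centimeter entries.
#' @param dm,htn,cad,mets optional logical (or 0/1) disease indicators.
#' @param age_range plausible age bounds; rows outside are invalid.
#' @param provenance free-text label carried as an attribute.
#' @return an `omam_cohort` tibble.
#' @export
cohort <- function(subject_id, sex, age_years, height_m, weight_kg,
                   dm = NULL, htn = NULL, cad = NULL, mets = NULL,
                   age_range = c(18, 79), provenance = "in-memory") {
  df <- data.frame(subject_id = as.character(subject_id),
                   sex = as.character(sex),
                   age_years = as.numeric(age_years),
                   height_m = as.numeric(height_m),
                   weight_kg = as.numeric(weight_kg),
                   stringsAsFactors = FALSE)
  for (dcol in DISEASE_COLS) {
    v <- switch(dcol, dm = dm, htn = htn, cad = cad, mets = mets)
    if (!is.null(v)) df[[dcol]] <- as.logical(v)
  }
  bad <- cohort_row_problems(df, age_range = age_range)
  if (any(nzchar(bad))) {
    stop_format("invalid cohort rows: %s",
                paste(utils::head(paste0("row ", which(nzchar(bad)), ": ", bad[nzchar(bad)]), 5),
                      collapse = "; "))
  }
  new_cohort(df, provenance = provenance)
}

new_cohort <- function(df, provenance = "in-memory") {
  if (nrow(df) == 0L) stop_domain("a cohort must be nonempty")
  if (anyDuplicated(df$subject_id)) stop_format("subject_id values must be unique")
  df$sex <- parse_sex(df$sex)
  out <- tibble::as_tibble(df)
  class(out) <- c("omam_cohort", class(out))
  attr(out, "provenance") <- provenance
  out
}

# Per-row validation messages; "" marks a valid row.
cohort_row_problems <- function(df, age_range = c(18, 79), height_unit = "m") {
  n <- nrow(df)
  msg <- character(n)
  sex <- parse_sex(df$sex)
  num_ok <- function(x) is.finite(x) & x > 0
  msg[is.na(sex)] <- "unrecognized sex token"
  for (col in c("age_years", "height_m", "weight_kg")) {
    bad <- !num_ok(df[[col]])
    msg[bad & !nzchar(msg)] <- sprintf("non-positive or non-finite %s", col)
  }
  if (identical(height_unit, "m")) {
    cmish <- is.finite(df$height_m) & df$height_m > 3
    msg[cmish & !nzchar(msg)] <-
      "height > 3 m (probable centimeters; re-read with height_unit = \"cm\")"
  }
  age_bad <- is.finite(df$age_years) &
    (df$age_years < age_range[1] | df$age_years > age_range[2])
  msg[age_bad & !nzchar(msg)] <-
    sprintf("age outside plausible range [%g, %g]", age_range[1], age_range[2])
  msg
}

#' Read a cohort from delimited text
#'
#' Expects a header row with columns
#' `subject_id,sex,age_years,height_m,weight_kg` and optionally the 0/1
#' disease columns `dm,htn,cad,mets`. Under the `"drop"` policy rows failing
#' validation are removed with a message reporting the count; under
#' `"strict"` the first invalid row aborts the read.
#'
#' @param path file path.
#' @param policy `"drop"` (default) or `"strict"`.
#' @param delim field delimiter (default comma).
#' @param height_unit `"m"` (default) or `"cm"`; with `"cm"` heights are
#'   divided by 100 on input.
#' @param age_range plausible age bounds (default 18-79, the reference
#'   cohort's inclusion window).
#' @return an `omam_cohort`.
#' @export
read_cohort <- function(path, policy = c("drop", "strict"), delim = ",",
                        height_unit = c("m", "cm"), age_range = c(18, 79)) {
  policy <- match.arg(policy)
  height_unit <- match.arg(height_unit)
  if (!file.exists(path)) stop_format("no such file: %s", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character"),
    error = function(e) stop_format("cannot parse '%s': %s", path, conditionMessage(e)))
  missing_cols <- setdiff(REQUIRED_COLS, names(df))
  if (length(missing_cols)) {
    stop_format("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_format("'%s' contains no data rows", path)
  for (col in c("age_years", "height_m", "weight_kg")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  if (height_unit == "cm") df$height_m <- df$height_m / 100
  for (dcol in intersect(DISEASE_COLS, names(df))) {
    v <- trimws(df[[dcol]])
    flag <- rep(NA, nrow(df))
    flag[v %in% c("1", "TRUE", "true")] <- TRUE
    flag[v %in% c("0", "FALSE", "false")] <- FALSE
    df[[dcol]] <- flag
  }
  df <- df[c(REQUIRED_COLS, intersect(DISEASE_COLS, names(df)))]
  msg <- cohort_row_problems(df, age_range = age_range)
  if (any(nzchar(msg))) {
    if (policy == "strict") {
      i <- which(nzchar(msg))[1]
      stop_format("row %d: %s", i, msg[i])
    }
    message(sprintf("read_cohort: dropped %d invalid row(s)", sum(nzchar(msg))))
    df <- df[!nzchar(msg), , drop = FALSE]
    if (nrow(df) == 0L) stop_format("no valid rows remain in '%s'", path)
  }
  new_cohort(df, provenance = path)
}

#' Write a cohort (or scored cohort) to delimited text
#'
#' @param x an `omam_cohort` or scored tibble.
#' @param path output file path.
#' @param delim field delimiter.
#' @export
write_cohort <- function(x, path, delim = ",") {
  df <- as.data.frame(x)
  for (dcol in intersect(DISEASE_COLS, names(df))) df[[dcol]] <- as.integer(df[[dcol]])
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Body mass index
#'
#' Weight in kilograms divided by the square of height in meters.
#'
#' @param weight_kg,height_m positive finite numerics (recycled).
#' @return BMI in kg/m².
#' @export
body_mass_index <- function(weight_kg, height_m) {
  check_positive_finite(weight_kg, "weight_kg")
  check_positive_finite(height_m, "height_m")
  weight_kg / height_m^2
}

#' Demographic summary of a cohort
#'
#' Medians and interquartile ranges of age, height, weight and BMI, overall
#' and per sex, in the layout customarily used for cohort description
#' tables.
#'
#' @param x an `omam_cohort`.
#' @param quantile_type quantile estimator shared with
#'   [empirical_quantile()].
#' @return tibble with columns `group`, `variable`, `n`, `median`, `iqr`.
#' @export
cohort_summary <- function(x, quantile_type = 6L) {
  stopifnot(inherits(x, "omam_cohort"))
  vars <- list(age = x$age_years, height = x$height_m, weight = x$weight_kg,
               bmi = body_mass_index(x$weight_kg, x$height_m))
  groups <- list(overall = rep(TRUE, nrow(x)),
                 male = x$sex == "male",
                 female = x$sex == "female")
  rows <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (!any(sel)) next
    for (v in names(vars)) {
      vals <- vars[[v]][sel]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, variable = v, n = sum(sel),
        median = stats::median(vals),
        iqr = if (sum(sel) > 1) iqr_of(vals, type = quantile_type) else 0)
    }
  }
  do.call(rbind, rows)
}

#' Audit an index against the covariates it should have removed
#'
#' Spearman correlations of a per-subject index (e.g. BMI or the corrected
#' weight WC) against weight, height and age, overall and within each sex.
#' A successful indexation leaves the index correlated with weight but
#' uncorrelated with height and age.
#'
#' @param x an `omam_cohort`.
#' @param index numeric vector aligned with `x`.
#' @return tibble with columns `stratum`, `variable`, `n`, `rho`,
#'   `p_value`, `status` (`"ok"`, `"not_computable"` for zero-variance
#'   input, `"insufficient_n"` below n = 4).
#' @export
correlate_index <- function(x, index) {
  stopifnot(inherits(x, "omam_cohort"))
  if (length(index) != nrow(x)) stop_domain("index length must match the cohort")
  if (nrow(x) < 4) stop_domain("correlation audit needs n >= 4")
  strata <- list(overall = rep(TRUE, nrow(x)),
                 male = x$sex == "male",
                 female = x$sex == "female")
  vars <- list(weight = x$weight_kg, height = x$height_m, age = x$age_years)
  rows <- list()
  for (s in names(strata)) {
    sel <- strata[[s]]
    if (!any(sel)) next
    for (v in names(vars)) {
      n <- sum(sel)
      if (n < 4) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          stratum = s, variable = v, n = n, rho = NA_real_,
          p_value = NA_real_, status = "insufficient_n")
        next
      }
      res <- spearman_test(index[sel], vars[[v]][sel])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        stratum = s, variable = v, n = n, rho = res$estimate,
        p_value = res$p_value, status = res$status)
    }
  }
  do.call(rbind, rows)
}
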