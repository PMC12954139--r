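# Corrected weight WC = measured W / predicted WP, reference-range
# thresholds by empirical percentile, and the two overweight criteria:
#   WC  > cutoff   (strict; the published cutoff is 1.1440)
#   BMI >= cutoff  (inclusive; conventional 25.0 kg/m²)
# The inequality asymmetry follows the criteria's published definitions.

#' Corrected weight score
#'
#' Dimensionless ratio of measured to model-predicted weight; close to 1 in
#' the reference population.
#'
#' @param measured_kg,predicted_kg positive finite numerics (recycled).
#' @return numeric vector `measured_kg / predicted_kg`.
#' @export
corrected_weight <- function(measured_kg, predicted_kg) {
  check_positive_finite(measured_kg, "measured_kg")
  check_positive_finite(predicted_kg, "predicted_kg")
  measured_kg / predicted_kg
}

new_threshold <- function(level, cutoff, lower_cutoff, n_source, quantile_rule, label) {
  structure(list(level = level, cutoff = cutoff, lower_cutoff = lower_cutoff,
                 n_source = n_source, quantile_rule = quantile_rule, label = label),
            class = "omam_threshold")
}

#' Derive an overweight threshold from a reference WC sample
#'
#' The cutoff is the empirical percentile at `level` (default the 97.5th)
#' of the corrected-weight scores of a reference sample, under the shared
#' quantile rule (interpolation at rank `(n + 1) * level`, clamped to the
#' extremes). The complementary lower percentile (underweight bound) is
#' computed and reported for reference but plays no role in classification.
#'
#' @param wc numeric vector of corrected-weight scores.
#' @param level upper percentile in (0, 1), default 0.975.
#' @param quantile_type estimator passed to [empirical_quantile()].
#' @param label provenance label recorded in the result.
#' @return an `omam_threshold`.
#' @export
derive_threshold <- function(wc, level = 0.975, quantile_type = 6L,
                             label = "derived") {
  if (length(wc) == 0L) stop_domain("cannot derive a threshold from an empty sample")
  if (anyNA(wc) || any(!is.finite(wc))) stop_domain("WC sample must be finite")
  if (length(wc) < 40) {
    warning("threshold derived from fewer than 40 subjects; the upper 2.5% tail is unstable")
  }
  if (!(level > 0 && level < 1)) stop_domain("level must lie in (0, 1)")
  new_threshold(level = level,
                cutoff = empirical_quantile(wc, level, type = quantile_type),
                lower_cutoff = empirical_quantile(wc, 1 - level, type = quantile_type),
                n_source = length(wc),
                quantile_rule = sprintf("type%d", quantile_type),
                label = label)
}

#' Published overweight threshold
#'
#' The 97.5th percentile of WC in the reference cohort's fitting subgroup
#' (subgroup A, n = 857): overweight is WC > 1.1440. Applied at exactly the
#' four printed decimals.
#'
#' @return an `omam_threshold`.
#' @export
published_threshold <- function() {
  path <- system.file("extdata", "published_threshold.json", package = "omam",
                      mustWork = TRUE)
  read_threshold(path)
}

#' Serialize / deserialize thresholds
#'
#' @param threshold an `omam_threshold`.
#' @param path file path.
#' @export
write_threshold <- function(threshold, path) {
  stopifnot(inherits(threshold, "omam_threshold"))
  jsonlite::write_json(unclass(threshold), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold
#' @export
read_threshold <- function(path) {
  if (!file.exists(path)) stop_format("no such threshold file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("level", "cutoff") %in% names(obj))) {
    stop_format("threshold JSON must contain fields level and cutoff")
  }
  new_threshold(level = obj$level, cutoff = obj$cutoff,
                lower_cutoff = if (is.null(obj$lower_cutoff)) NA_real_ else obj$lower_cutoff,
                n_source = if (is.null(obj$n_source)) NA_integer_ else obj$n_source,
                quantile_rule = if (is.null(obj$quantile_rule)) "unknown" else obj$quantile_rule,
                label = if (is.null(obj$label)) "file" else obj$label)
}

#' @export
print.omam_threshold <- function(x, ...) {
  cat(sprintf("WC overweight threshold [%s]\n", x$label))
  cat(sprintf("  %.1fth percentile cutoff: WC > %.4f  (n = %s, rule %s)\n",
              100 * x$level, x$cutoff, format(x$n_source), x$quantile_rule))
  if (is.finite(x$lower_cutoff)) {
    cat(sprintf("  lower %.1fth percentile (reference only): %.4f\n",
                100 * (1 - x$level), x$lower_cutoff))
  }
  invisible(x)
}

#' Classify by corrected weight
#'
#' Overweight iff `wc > cutoff` (strict inequality; a subject exactly at
#' the cutoff is normal).
#'
#' @param wc positive numeric vector of corrected-weight scores.
#' @param threshold an `omam_threshold` (default the published cutoff).
#' @return factor with levels `normal`, `overweight`.
#' @export
classify_wc <- function(wc, threshold = published_threshold()) {
  check_positive_finite(wc, "wc")
  stopifnot(inherits(threshold, "omam_threshold"))
  factor(ifelse(wc > threshold$cutoff, "overweight", "normal"),
         levels = c("normal", "overweight"))
}

#' Classify by body mass index
#'
#' Overweight iff `BMI >= cutoff` (inclusive), default cutoff 25.0 kg/m².
#'
#' @param weight_kg,height_m positive finite numerics.
#' @param cutoff BMI cutoff in kg/m².
#' @return factor with levels `normal`, `overweight`.
#' @export
classify_bmi <- function(weight_kg, height_m, cutoff = 25) {
  bmi <- body_mass_index(weight_kg, height_m)
  factor(ifelse(bmi >= cutoff, "overweight", "normal"),
         levels = c("normal", "overweight"))
}

#' Score a cohort under both criteria
#'
#' Appends the predicted weight `wp_kg`, corrected weight `wc`, WC class,
#' BMI and BMI class to the cohort, row for row in input order.
#'
#' @param x an `omam_cohort`.
#' @param coeffs an `omam_coefficients` (default published).
#' @param threshold an `omam_threshold` (default published).
#' @param bmi_cutoff BMI overweight cutoff (default 25.0 kg/m²).
#' @return tibble: the cohort columns plus `wp_kg`, `wc`, `wc_class`,
#'   `bmi`, `bmi_class`.
#' @export
score_cohort <- function(x, coeffs = published_coefficients(),
                         threshold = published_threshold(), bmi_cutoff = 25) {
  stopifnot(inherits(x, "omam_cohort"))
  out <- tibble::as_tibble(as.data.frame(x))
  out$wp_kg <- predict_weight(coeffs, x$sex, x$age_years, x$height_m)
  out$wc <- corrected_weight(x$weight_kg, out$wp_kg)
  out$wc_class <- classify_wc(out$wc, threshold)
  out$bmi <- body_mass_index(x$weight_kg, x$height_m)
  out$bmi_class <- classify_bmi(x$weight_kg, x$height_m, cutoff = bmi_cutoff)
  out
}
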