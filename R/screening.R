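# Screening evaluation: reclassification of BMI-overweight subjects under
# the WC criterion, and paired comparison of the two criteria against
# cardiometabolic disease labels. "Positive" means classified overweight
# for both criteria.

#' Confusion counts of an overweight criterion against a disease label
#'
#' @param predicted_overweight,diseased aligned logical vectors.
#' @return an `omam_confusion`: list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predicted_overweight, diseased) {
  if (length(predicted_overweight) != length(diseased)) {
    stop_domain("prediction and label vectors must be aligned")
  }
  if (!length(diseased)) stop_domain("empty input")
  p <- as.logical(predicted_overweight); y <- as.logical(diseased)
  if (anyNA(p) || anyNA(y)) stop_domain("missing values in predictions or labels")
  structure(list(tp = sum(p & y), fp = sum(p & !y),
                 tn = sum(!p & !y), fn = sum(!p & y)),
            class = "omam_confusion")
}

#' Sensitivity, specificity and accuracy
#'
#' @param counts an `omam_confusion`.
#' @return an `omam_performance`: list with `sensitivity`, `specificity`,
#'   `accuracy` (proportions in \[0, 1\]; `NA` with a status note when a
#'   denominator is zero).
#' @export
performance_metrics <- function(counts) {
  stopifnot(inherits(counts, "omam_confusion"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  pos <- counts$tp + counts$fn
  neg <- counts$tn + counts$fp
  structure(list(
    sensitivity = if (pos > 0) counts$tp / pos else NA_real_,
    specificity = if (neg > 0) counts$tn / neg else NA_real_,
    accuracy = (counts$tp + counts$tn) / total,
    n = total,
    status = if (pos > 0 && neg > 0) "ok" else "not_computable"),
    class = "omam_performance")
}

#' Compare WC-based and BMI-based overweight criteria against disease labels
#'
#' For each disease label present in the cohort and each stratum (total,
#' male, female, as available), computes sensitivity, specificity and
#' accuracy of both criteria and the McNemar test of their paired
#' difference: accuracy is compared on per-subject correctness over all
#' subjects, sensitivity on positive calls among diseased subjects, and
#' specificity on negative calls among healthy subjects.
#'
#' @param x an `omam_cohort` with at least one disease flag column among
#'   `dm`, `htn`, `cad`, `mets`.
#' @param coeffs,threshold,bmi_cutoff classification settings as in
#'   [score_cohort()].
#' @return tibble: `disease`, `stratum`, `metric`, `bmi`, `wc`,
#'   `discordant_b`, `discordant_c`, `p_value`, `method`, `n`.
#' @export
compare_criteria <- function(x, coeffs = published_coefficients(),
                             threshold = published_threshold(), bmi_cutoff = 25) {
  stopifnot(inherits(x, "omam_cohort"))
  diseases <- intersect(DISEASE_COLS, names(x))
  if (!length(diseases)) stop_domain("cohort has no disease flag columns (dm, htn, cad, mets)")
  scored <- score_cohort(x, coeffs = coeffs, threshold = threshold,
                         bmi_cutoff = bmi_cutoff)
  bmi_pos <- scored$bmi_class == "overweight"
  wc_pos <- scored$wc_class == "overweight"
  strata <- list(total = rep(TRUE, nrow(x)),
                 male = x$sex == "male",
                 female = x$sex == "female")
  strata <- strata[vapply(strata, any, logical(1))]
  rows <- list()
  for (dz in diseases) {
    y <- x[[dz]]
    if (anyNA(y)) stop_domain("disease flag '%s' has missing values", dz)
    for (st in names(strata)) {
      sel <- strata[[st]]
      yb <- y[sel]; pb <- bmi_pos[sel]; pw <- wc_pos[sel]
      perf_b <- performance_metrics(confusion_counts(pb, yb))
      perf_w <- performance_metrics(confusion_counts(pw, yb))
      paired <- list(
        accuracy = list(a = pb == yb, b = pw == yb, keep = rep(TRUE, length(yb))),
        sensitivity = list(a = pb, b = pw, keep = yb),
        specificity = list(a = !pb, b = !pw, keep = !yb))
      for (metric in names(paired)) {
        pr <- paired[[metric]]
        ok_a <- pr$a[pr$keep]; ok_b <- pr$b[pr$keep]
        disc_b <- sum(ok_a & !ok_b); disc_c <- sum(!ok_a & ok_b)
        mc <- mcnemar_test(disc_b, disc_c)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          disease = dz, stratum = st, metric = metric,
          bmi = perf_b[[metric]], wc = perf_w[[metric]],
          discordant_b = disc_b, discordant_c = disc_c,
          p_value = mc$p_value, method = mc$method, n = sum(pr$keep))
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a criteria comparison as a delimited table
#'
#' Rows are metric-by-stratum, columns the two criteria (as percentages to
#' one decimal) and the McNemar p-value, one block per disease.
#'
#' @param comparison output of [compare_criteria()].
#' @param path output file path.
#' @param delim field delimiter (default tab).
#' @export
write_comparison <- function(comparison, path, delim = "\t") {
  df <- as.data.frame(comparison)
  df$bmi <- sprintf("%.1f%%", 100 * df$bmi)
  df$wc <- sprintf("%.1f%%", 100 * df$wc)
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reclassification of BMI-overweight subjects under the WC criterion
#'
#' Every subject must already satisfy the BMI criterion (callers pre-filter
#' to the overweight group). Reports how many fall at or below the WC
#' cutoff — reclassified as normal — overall and by sex, with rates as
#' percentages; the remaining overweight rate is the complement.
#'
#' @param x an `omam_cohort`, all subjects with BMI >= `bmi_cutoff`.
#' @param coeffs,threshold,bmi_cutoff classification settings as in
#'   [score_cohort()].
#' @return an `omam_reclassification`: totals, by-sex tibble, rates in
#'   percent (full precision; printed to one decimal).
#' @export
reclassification_summary <- function(x, coeffs = published_coefficients(),
                                     threshold = published_threshold(),
                                     bmi_cutoff = 25) {
  stopifnot(inherits(x, "omam_cohort"))
  scored <- score_cohort(x, coeffs = coeffs, threshold = threshold,
                         bmi_cutoff = bmi_cutoff)
  if (any(scored$bmi < bmi_cutoff)) {
    stop_domain("%d subject(s) fall below the BMI cutoff %.1f; pre-filter to the overweight group",
                sum(scored$bmi < bmi_cutoff), bmi_cutoff)
  }
  recl <- scored$wc_class == "normal"
  by_sex <- do.call(rbind, lapply(c("male", "female"), function(s) {
    sel <- x$sex == s
    if (!any(sel)) return(NULL)
    tibble::tibble(sex = s, n = sum(sel), n_reclassified = sum(recl[sel]),
                   rate_percent = 100 * sum(recl[sel]) / sum(sel),
                   remaining_percent = 100 * (1 - sum(recl[sel]) / sum(sel)))
  }))
  structure(list(n_overweight_bmi = nrow(x),
                 n_reclassified_normal = sum(recl),
                 rate_percent = 100 * sum(recl) / nrow(x),
                 remaining_percent = 100 * (1 - sum(recl) / nrow(x)),
                 by_sex = by_sex),
            class = "omam_reclassification")
}

#' @export
print.omam_reclassification <- function(x, ...) {
  cat(sprintf("Reclassification under the WC criterion: %d of %d (%.1f%%) BMI-overweight subjects are WC-normal\n",
              x$n_reclassified_normal, x$n_overweight_bmi, x$rate_percent))
  cat(sprintf("  remaining overweight rate: %.1f%%\n", x$remaining_percent))
  if (!is.null(x$by_sex)) {
    for (i in seq_len(nrow(x$by_sex))) {
      cat(sprintf("  %s: %d of %d reclassified (%.1f%%), remaining overweight %.1f%%\n",
                  x$by_sex$sex[i], x$by_sex$n_reclassified[i], x$by_sex$n[i],
                  x$by_sex$rate_percent[i], x$by_sex$remaining_percent[i]))
    }
  }
  invisible(x)
}
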