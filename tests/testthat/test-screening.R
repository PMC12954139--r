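test_that("confusion counts tabulate and conserve totals", {
  cc <- confusion_counts(rep(TRUE, 7), rep(TRUE, 7))
  expect_equal(cc$tp, 7)
  expect_equal(cc$fp + cc$tn + cc$fn, 0)
  withr::with_seed(12, {
    for (i in 1:20) {
      n <- sample(5:50, 1)
      p <- runif(n) > 0.5; y <- runif(n) > 0.5
      cc <- confusion_counts(p, y)
      expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, n)
      expect_equal(cc$tp, sum(p & y))
    }
  })
  expect_error(confusion_counts(c(TRUE), c(TRUE, FALSE)), class = "omam_domain_error")
})

test_that("performance ratios match their definitions, with zero-denominator guards", {
  pm <- performance_metrics(structure(list(tp = 5, fp = 5, tn = 5, fn = 5),
                                      class = "omam_confusion"))
  expect_equal(pm$sensitivity, 0.5)
  expect_equal(pm$specificity, 0.5)
  expect_equal(pm$accuracy, 0.5)
  perfect <- performance_metrics(structure(list(tp = 10, fp = 0, tn = 10, fn = 0),
                                           class = "omam_confusion"))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1))
  nopos <- performance_metrics(confusion_counts(c(TRUE, FALSE), c(FALSE, FALSE)))
  expect_true(is.na(nopos$sensitivity))
  expect_equal(nopos$status, "not_computable")
  withr::with_seed(13, {
    for (i in 1:20) {
      k <- sample(0:20, 4, replace = TRUE) + 1
      cc <- structure(list(tp = k[1], fp = k[2], tn = k[3], fn = k[4]),
                      class = "omam_confusion")
      pm <- performance_metrics(cc)
      expect_equal(pm$sensitivity, k[1] / (k[1] + k[4]))
      expect_equal(pm$specificity, k[3] / (k[3] + k[2]))
      expect_equal(pm$accuracy, (k[1] + k[3]) / sum(k))
    }
  })
})

test_that("random predictions score near chance accuracy", {
  withr::with_seed(14, {
    p <- runif(4000) > 0.5
    y <- runif(4000) > 0.5
  })
  pm <- performance_metrics(confusion_counts(p, y))
  expect_lt(abs(pm$accuracy - 0.5), 0.03)
})

disease_fixture <- function(n = 1200, seed = 400, residual_sd = 0.12) {
  params <- generator_params(n = n, seed = seed, residual_sd = residual_sd)
  link <- disease_link_params(
    intercepts = c(dm = -6, htn = -3, cad = -6, mets = -6),
    slopes = c(dm = 4.5, htn = 2.5, cad = 4.5, mets = 4.5))
  generate_disease_cohort(params, link)
}

test_that("criteria comparison pairs subjects and degenerates gracefully", {
  coh <- disease_fixture()
  cmp <- compare_criteria(coh)
  expect_setequal(unique(cmp$metric), c("accuracy", "sensitivity", "specificity"))
  expect_setequal(unique(cmp$stratum), c("total", "male", "female"))
  expect_setequal(unique(cmp$disease), c("dm", "htn", "cad", "mets"))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1, na.rm = TRUE))

  # identical criteria (nobody positive under either): zero discordance, p = 1
  thr_inf <- derive_threshold(rep(c(1, 2), 25), level = 0.5)
  thr_inf$cutoff <- 1e9
  same <- compare_criteria(coh, threshold = thr_inf, bmi_cutoff = 1e9)
  expect_true(all(same$p_value == 1))
  expect_equal(same$bmi, same$wc)
  expect_true(all(same$discordant_b + same$discordant_c == 0))

  noflag <- make_cohort(30)
  expect_error(compare_criteria(noflag), class = "omam_domain_error")

  males <- coh[coh$sex == "male", ]
  class(males) <- class(coh)
  cmp_m <- compare_criteria(males)
  expect_setequal(unique(cmp_m$stratum), c("total", "male"))
})

test_that("a stricter WC cutoff trades sensitivity for specificity", {
  coh <- disease_fixture(seed = 401)
  strict <- published_threshold()
  strict$cutoff <- 1.10
  # BMI cutoff lowered so the BMI criterion is the laxer screen
  cmp <- compare_criteria(coh, threshold = strict, bmi_cutoff = 23)
  tot <- cmp[cmp$stratum == "total", ]
  expect_true(all(tot$wc[tot$metric == "specificity"] >
                  tot$bmi[tot$metric == "specificity"]))
  expect_true(all(tot$wc[tot$metric == "sensitivity"] <
                  tot$bmi[tot$metric == "sensitivity"]))
})

test_that("comparison table writes a delimited file", {
  cmp <- compare_criteria(disease_fixture(n = 400, seed = 402))
  path <- tempfile(fileext = ".tsv")
  write_comparison(cmp, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(cmp))
  expect_match(back$bmi[1], "%")
})

test_that("reclassification arithmetic reproduces printed rates from printed counts", {
  # 274 BMI-overweight subjects of whom 60 (53 men, 7 women) are WC-normal
  mk <- function(n, sex, wc_normal) {
    age <- 46; h <- if (sex == "M") 1.71 else 1.60
    wp <- predict_weight(published_coefficients(), sex, age, h)
    w <- wp * ifelse(wc_normal, 1.10, 1.20)  # strictly below / above 1.1440
    list(sex = rep(sex, n), age = rep(age, n), h = rep(h, n), w = w)
  }
  men <- mk(137, "M", c(rep(TRUE, 53), rep(FALSE, 84)))
  women <- mk(137, "F", c(rep(TRUE, 7), rep(FALSE, 130)))
  coh <- cohort(sprintf("ow%d", 1:274),
                c(men$sex, women$sex), c(men$age, women$age),
                c(men$h, women$h), c(men$w, women$w))
  # force everyone past the BMI cutoff without moving WC membership:
  # use a lenient BMI cutoff instead of altering weights
  bmi_min <- min(body_mass_index(coh$weight_kg, coh$height_m))
  rs <- reclassification_summary(coh, bmi_cutoff = floor(bmi_min))
  expect_equal(rs$n_overweight_bmi, 274)
  expect_equal(rs$n_reclassified_normal, 60)
  expect_equal(round(rs$rate_percent, 1), 21.9)
  expect_equal(round(rs$remaining_percent, 1), 78.1)
  bs <- rs$by_sex
  expect_equal(round(bs$remaining_percent[bs$sex == "male"], 1), 61.3)
  expect_equal(round(bs$remaining_percent[bs$sex == "female"], 1), 94.9)
  expect_equal(round(bs$rate_percent[bs$sex == "female"], 1), 5.1)
  expect_equal(sum(bs$n_reclassified), rs$n_reclassified_normal)

  # pre-filter contract: any below-cutoff subject aborts
  expect_error(reclassification_summary(coh, bmi_cutoff = 25),
               class = "omam_domain_error")
})
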