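test_that("expected calibration error matches hand computations", {
  expect_identical(expected_calibration_error(c(0, 1, 1, 0), c(0, 1, 1, 0)), 0)
  scores <- c(0.05, 0.05, 0.05, 0.05, 0.95, 0.95, 0.95, 0.95)
  outcomes <- c(0, 0, 0, 1, 1, 1, 1, 0)
  # two occupied bins, each with |mean(y) - mean(s)| = 0.2
  expect_equal(expected_calibration_error(scores, outcomes), 0.2,
               tolerance = 1e-12)
  expect_error(expected_calibration_error(numeric(0), numeric(0)), "empty")
  expect_error(expected_calibration_error(c(NA, 0.5), c(0, 1)), "NA")
})

test_that("error rates and balanced accuracy match their definitions", {
  expect_identical(false_negative_rate(c(1, 1), c(1, 1)), 0)
  expect_equal(false_negative_rate(c(0.6, 0.4), c(1, 1)), 0.5)
  expect_true(is.na(false_negative_rate(c(0.2, 0.9), c(0, 0))))
  expect_true(is.na(false_positive_rate(c(0.2, 0.9), c(1, 1))))
  expect_identical(balanced_accuracy(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(balanced_accuracy(c(0, 0, 0, 0), c(1, 0, 1, 0)), 0.5)
  # one positive hit, one missed; one negative called, one not
  expect_equal(balanced_accuracy(c(0.9, 0.1, 0.9, 0.1), c(1, 1, 0, 0)), 0.5)
  expect_error(balanced_accuracy(c(0.1, 0.9), c(1, 1)), "both")
  # FNR is the sensitivity complement and is monotone in the threshold
  set.seed(42)
  s <- runif(60)
  y <- rbinom(60, 1, 0.5)
  for (thr in c(0.2, 0.5, 0.8)) {
    sens <- mean(s[y == 1] >= thr)
    expect_equal(false_negative_rate(s, y, thr), 1 - sens)
  }
  fnrs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(t)
    false_negative_rate(s, y, t), numeric(1))
  expect_true(all(diff(fnrs) >= 0))
})

test_that("ranking metrics match brute-force pair enumeration", {
  expect_identical(rank_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auroc, 1)
  expect_identical(rank_metrics(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auroc, 0.5)
  set.seed(7)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    s <- round(runif(n), sample(1:2, 1))  # rounding induces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    rm_ <- rank_metrics(s, y)
    expect_equal(rm_$auroc, oracle_auroc(s, y), tolerance = 1e-12)
    expect_equal(rm_$auprc, oracle_auprc(s, y), tolerance = 1e-12)
  }
})

test_that("ECE agrees with a groupwise brute-force oracle on random draws", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(1:12, 1)
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.4)
    expect_equal(expected_calibration_error(s, y), oracle_ece(s, y),
                 tolerance = 1e-12)
  }
})

test_that("subgroup metric tables conserve counts and surface planted bias", {
  cohort <- generate_cohort(cohort_preset("adult_ed", 8000, seed = 14))
  base_coll <- build_collection(cohort, scenario = "base")
  tbl0 <- subgroup_metric_table(cohort$true_risk, cohort$admitted, base_coll)
  expect_identical(tbl0$group, "overall")

  coll <- build_collection(cohort, scenario = "single:gender")
  tbl <- subgroup_metric_table(cohort$true_risk, cohort$admitted, coll)
  grp <- tbl[!tbl$group %in% c("overall", "mean_over_groups", "max_over_groups"), ]
  expect_identical(sum(grp$count), nrow(cohort))
  expect_identical(sum(grp$positives), sum(cohort$admitted))

  shifted <- perturb_scores(cohort$true_risk, coll, c("gender=Men" = 0.15))
  tbl_s <- subgroup_metric_table(shifted, cohort$admitted, coll)
  expect_gt(tbl_s$ece[tbl_s$group == "gender=Men"],
            tbl_s$ece[tbl_s$group == "gender=Women"])
})

test_that("multicalibration audits flag planted violations and only those", {
  cohort <- generate_cohort(cohort_preset("adult_ed", 100000, seed = 17))
  coll <- prevalence_filter(build_collection(cohort, scenario = "intersectional"),
                            0.001)
  # oracle scores pass the audit where cells are large enough that sampling
  # noise (3 SD of a mean over >= 0.01 * n records) sits below alpha
  clean <- audit_multicalibration(cohort$true_risk, cohort$admitted, coll,
                                  alpha = 0.05, gamma = 0.01)
  expect_identical(nrow(clean$violations), 0L)

  shifted <- perturb_scores(cohort$true_risk, coll,
                            c("ethnoracial=White; gender=Women" = 0.2))
  flagged <- audit_multicalibration(shifted, cohort$admitted, coll,
                                    alpha = 0.01, gamma = 0.001)
  expect_true("ethnoracial=White; gender=Women" %in% flagged$violations$group)
  expect_true(all(flagged$violations$prevalence >= 0.001))
  expect_true(all(abs(flagged$violations$residual) > 0.01))

  vacuous <- audit_multicalibration(shifted, cohort$admitted, coll,
                                    alpha = 0.99, gamma = 0.001)
  expect_identical(nrow(vacuous$violations), 0L)
})

test_that("overall rows are computed on the union of records", {
  cohort <- generate_cohort(cohort_preset("adult_ed", 3000, seed = 19))
  coll <- build_collection(cohort, scenario = "intersectional")
  tbl <- subgroup_metric_table(cohort$true_risk, cohort$admitted, coll)
  expect_equal(tbl$ece[tbl$group == "overall"],
               expected_calibration_error(cohort$true_risk, cohort$admitted),
               tolerance = 1e-15)
})

test_that("optional metric variants follow their formulas", {
  s <- c(0.05, 0.05, 0.95, 0.95)
  y <- c(0, 1, 1, 0)
  # occupied-bin gaps are both 0.45; max and weighted mean coincide here
  expect_equal(expected_calibration_error(s, y, aggregate = "max"), 0.45,
               tolerance = 1e-12)
  s2 <- c(0.05, 0.05, 0.05, 0.05, 0.95, 0.95)
  y2 <- c(0, 0, 0, 1, 1, 1)
  expect_equal(expected_calibration_error(s2, y2, aggregate = "max"),
               max(abs(0.25 - 0.05), abs(1 - 0.95)), tolerance = 1e-12)
  # prior smoothing: (FN + c*pi) / (P + c)
  expect_equal(false_negative_rate(c(0.2, 0.9), c(1, 1), 0.5,
                                   prior_strength = 2, prior_rate = 0.25),
               (1 + 2 * 0.25) / (2 + 2), tolerance = 1e-12)
  expect_true(is.na(false_negative_rate(c(0.2), c(0), 0.5,
                                        prior_strength = 2, prior_rate = 0.25)))
})
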