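test_that("already-calibrated scores are a fixed point", {
  # deterministic construction: every (group, bin) cell's outcome rate
  # equals its score exactly, so no cell exceeds any alpha
  data <- tibble::tibble(
    g = rep(c("a", "b"), each = 100),
    admitted = c(rep(c(1L, 0L), c(30, 70)), rep(c(1L, 0L), c(60, 40))))
  attr(data, "protected") <- "g"
  coll <- build_collection(data, scenario = "intersectional")
  scores <- rep(c(0.3, 0.6), each = 100)
  fit <- fit_multicalibration(scores, data$admitted, coll,
                              multicalib_config(alpha = 0.01))
  expect_identical(nrow(fit$post$updates), 0L)
  expect_identical(fit$scores, scores)
  expect_true(fit$post$converged)
})

test_that("a single miscalibrated cell is repaired in one hand-checkable update", {
  n <- 100
  data <- tibble::tibble(g = rep("a", n),
                         admitted = rep(c(1L, 0L), c(50, 50)))
  attr(data, "protected") <- "g"
  coll <- build_collection(data, scenario = "intersectional")
  scores <- rep(0.3, n)  # one bin; mean(y) = 0.5 -> residual +0.2
  fit <- fit_multicalibration(scores, data$admitted, coll)
  expect_identical(nrow(fit$post$updates), 1L)
  expect_equal(fit$post$updates$delta, 0.2, tolerance = 1e-12)
  expect_equal(fit$scores, rep(0.5, n), tolerance = 1e-12)
  expect_true(fit$post$converged)
})

test_that("planted per-cell shifts are repaired and the certificate holds", {
  cohort <- generate_cohort(cohort_preset("adult_ed", 20000, seed = 29))
  coll <- prevalence_filter(build_collection(cohort, scenario = "intersectional"),
                            0.001)
  shifts <- c("ethnoracial=Black; gender=Women" = 0.15,
              "ethnoracial=White; gender=Men" = -0.1,
              "ethnoracial=Asian; gender=Men" = 0.2)
  shifted <- perturb_scores(cohort$true_risk, coll, shifts)
  pre <- subgroup_metric_table(shifted, cohort$admitted, coll)
  fit <- fit_multicalibration(shifted, cohort$admitted, coll)
  post <- subgroup_metric_table(fit$scores, cohort$admitted, coll)
  expect_true(fit$post$converged)
  expect_identical(nrow(fit$post$audit$violations), 0L)
  expect_lt(post$ece[post$group == "mean_over_groups"],
            pre$ece[pre$group == "mean_over_groups"])
})

test_that("replaying recorded updates reproduces the fitted scores exactly", {
  cohort <- generate_cohort(cohort_preset("adult_ed", 10000, seed = 31))
  coll <- prevalence_filter(build_collection(cohort, scenario = "marginal"),
                            0.001)
  shifted <- perturb_scores(cohort$true_risk, coll,
                            c("gender=Men" = 0.12, "ethnoracial=Black" = -0.08))
  fit <- fit_multicalibration(shifted, cohort$admitted, coll)
  replayed <- apply_postprocessor(fit$post, shifted, coll)
  expect_identical(replayed, fit$scores)
})

test_that("an empty collection yields the identity postprocessor", {
  cohort <- generate_cohort(cohort_preset("adult_ed", 500, seed = 3))
  base <- build_collection(cohort, scenario = "base")
  fit <- fit_multicalibration(cohort$true_risk, cohort$admitted, base)
  expect_identical(nrow(fit$post$updates), 0L)
  expect_identical(fit$scores, as.numeric(cohort$true_risk))
  expect_identical(apply_postprocessor(fit$post, cohort$true_risk, base),
                   as.numeric(cohort$true_risk))
})

test_that("updates respect the record's current bin during replay", {
  # record 1 sits in bin 4 (score 0.35); the first update moves it to bin 6;
  # a later update aimed at (g2, bin 4) must then leave it alone.
  post <- structure(list(
    config = multicalib_config(),
    updates = tibble::tibble(group = c("g1", "g2"), bin = c(4L, 4L),
                             delta = c(0.2, 0.1), sweep = c(1L, 1L)),
    converged = TRUE, sweeps = 1L, audit = NULL,
    group_labels = c("g1", "g2")), class = "postprocessor")
  membership <- matrix(TRUE, nrow = 1, ncol = 2,
                       dimnames = list(NULL, c("g1", "g2")))
  coll <- fairadmit:::new_group_collection("marginal",
                                           list(c(a = "x"), c(b = "y")),
                                           c("g1", "g2"), membership, 1L)
  expect_equal(apply_postprocessor(post, 0.35, coll), 0.55, tolerance = 1e-12)
})

test_that("refitting adjusted scores is idempotent and scores stay bounded", {
  cohort <- generate_cohort(cohort_preset("adult_ed", 20000, seed = 37))
  coll <- prevalence_filter(build_collection(cohort, scenario = "intersectional"),
                            0.001)
  shifted <- perturb_scores(cohort$true_risk, coll,
                            c("ethnoracial=White; gender=Women" = 0.3,
                              "ethnoracial=Hispanic; gender=Men" = -0.25))
  fit <- fit_multicalibration(shifted, cohort$admitted, coll)
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  refit <- fit_multicalibration(fit$scores, cohort$admitted, coll,
                                fit$post$config)
  expect_identical(nrow(refit$post$updates), 0L)
})

test_that("hitting the sweep cap warns and reports non-convergence", {
  cohort <- generate_cohort(cohort_preset("adult_ed", 20000, seed = 41))
  coll <- prevalence_filter(build_collection(cohort, scenario = "intersectional"),
                            0.001)
  shifted <- perturb_scores(cohort$true_risk, coll,
                            c("ethnoracial=Black; gender=Women" = 0.2))
  expect_warning(
    fit <- fit_multicalibration(shifted, cohort$admitted, coll,
                                multicalib_config(max_sweeps = 1, step = 0.1)),
    "did not converge")
  expect_false(fit$post$converged)
})

test_that("postprocessors serialize with their ordered update list", {
  cohort <- generate_cohort(cohort_preset("adult_ed", 5000, seed = 43))
  coll <- prevalence_filter(build_collection(cohort, scenario = "intersectional"),
                            0.001)
  shifted <- perturb_scores(cohort$true_risk, coll,
                            c("ethnoracial=Black; gender=Men" = 0.15))
  fit <- fit_multicalibration(shifted, cohort$admitted, coll)
  parsed <- jsonlite::fromJSON(postprocessor_to_json(fit$post))
  expect_identical(parsed$alpha, 0.01)
  expect_identical(nrow(parsed$updates), nrow(fit$post$updates))
  expect_equal(parsed$updates$delta, fit$post$updates$delta, tolerance = 1e-12)
})

test_that("random sweep order still converges with a clean certificate and
           exact replay", {
  cohort <- generate_cohort(cohort_preset("adult_ed", 10000, seed = 47))
  coll <- prevalence_filter(build_collection(cohort, scenario = "intersectional"),
                            0.001)
  shifted <- perturb_scores(cohort$true_risk, coll,
                            c("ethnoracial=Black; gender=Women" = 0.18,
                              "ethnoracial=White; gender=Men" = -0.12))
  cfg <- multicalib_config(sweep_order = "random", order_seed = 9)
  fit <- fit_multicalibration(shifted, cohort$admitted, coll, cfg)
  expect_true(fit$post$converged)
  expect_identical(nrow(fit$post$audit$violations), 0L)
  expect_identical(apply_postprocessor(fit$post, shifted, coll), fit$scores)
  # and the random order is itself reproducible
  fit2 <- fit_multicalibration(shifted, cohort$admitted, coll, cfg)
  expect_identical(fit$post$updates, fit2$post$updates)
})
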