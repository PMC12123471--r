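# Small problem sizes throughout: the optimizer's correctness properties
# (dominance, elitism, determinism) do not depend on scale.

make_small_problem <- function(n = 3000, seed = 51) {
  cohort <- generate_cohort(cohort_preset("adult_ed_biased", n, seed = seed))
  coll <- prevalence_filter(build_collection(cohort, scenario = "intersectional"),
                            0.01)
  list(cohort = cohort, coll = coll)
}

test_that("the all-ones genome reproduces the unweighted base learner", {
  pr <- make_small_problem()
  n <- nrow(pr$cohort)
  idx <- seq_len(n)
  train <- pr$cohort[idx[idx %% 2 == 1], ]
  val <- pr$cohort[idx[idx %% 2 == 0], ]
  attr(train, "protected") <- attr(val, "protected") <- c("ethnoracial", "gender")
  w_coll <- fairadmit:::collection_subset(pr$coll, which(idx %% 2 == 1))
  e_coll <- fairadmit:::collection_subset(pr$coll, which(idx %% 2 == 0))
  ones <- rep(1, length(w_coll$labels))
  obj_ones <- evaluate_genome(ones, train, val, w_coll, e_coll,
                              threshold = 0.3)
  # unweighted fit through the same learner interface
  both <- rbind(train, val)
  dm <- fairadmit:::design_matrix(both)
  i_tr <- seq_len(nrow(train))
  fit <- fairadmit:::fit_learner(dm$x[i_tr, ], dm$y[i_tr], learner_spec("logistic"))
  p <- pmin(1, pmax(0, fairadmit:::predict_learner(fit, dm$x[-i_tr, ])))
  expect_equal(unname(obj_ones["error"]),
               1 - balanced_accuracy(p, dm$y[-i_tr], 0.3), tolerance = 1e-9)
  expect_error(evaluate_genome(c(1, 1), train, val, w_coll, e_coll),
               "does not match")
})

test_that("weight expansion multiplies across overlapping groups", {
  data <- tibble::tibble(eth = c("A", "A", "B"), gender = c("M", "F", "M"),
                         admitted = c(1L, 0L, 1L))
  attr(data, "protected") <- c("eth", "gender")
  marg <- build_collection(data, scenario = "marginal")
  # labels sorted: eth=A, eth=B, gender=F, gender=M
  w <- fairadmit:::expand_weights(c(2, 3, 5, 7), marg)
  expect_equal(w, c(2 * 7, 2 * 5, 3 * 7))
  base <- build_collection(data, scenario = "base")
  expect_equal(fairadmit:::expand_weights(4, base), rep(4, 3))
})

test_that("nondominated sorting and selection policies follow their definitions", {
  obj <- rbind(c(0.2, 0.10), c(0.3, 0.05), c(0.35, 0.20))
  r <- fairadmit:::nondominated_rank(obj)
  expect_identical(r[1:2], c(1L, 1L))
  expect_gt(r[3], 1L)  # dominated by both others? (by #1 only) -> rank 2
  # pure dominance: A better in both than B
  expect_identical(fairadmit:::nondominated_rank(rbind(c(0.1, 0.1), c(0.2, 0.2))),
                   c(1L, 2L))

  front <- structure(list(
    genomes = diag(3), baseline = c(error = 0.5, fairness = 0.5, auroc = 0.5),
    val_auroc = c(0.70, 0.69, 0.68),
    objectives = cbind(error = c(0.2, 0.25, 0.4),
                       fairness = c(0.10, 0.07, 0.05))),
    class = "pareto_front")
  expect_identical(select_solution(front, "min_fairness")$index, 3L)
  # knee: normalized distances favor the middle point
  expect_identical(select_solution(front, "knee")$index, 2L)
  singleton <- structure(list(genomes = matrix(1), val_auroc = 0.7,
                              baseline = c(error = 1, fairness = 1, auroc = 0.5),
                              objectives = cbind(error = 0.3, fairness = 0.2)),
                         class = "pareto_front")
  for (pol in c("guarded", "min_fairness", "knee")) {
    expect_identical(select_solution(singleton, pol)$index, 1L)
  }
  # guarded: only solutions within the AUROC band are eligible
  guarded_front <- structure(list(
    genomes = diag(2), baseline = c(error = 0.3, fairness = 0.4, auroc = 0.75),
    val_auroc = c(0.748, 0.70),
    objectives = cbind(error = c(0.3, 0.25), fairness = c(0.3, 0.1))),
    class = "pareto_front")
  expect_identical(select_solution(guarded_front, "guarded")$index, 1L)
})

test_that("the optimizer is deterministic and never loses the baseline's
           fairness level", {
  pr <- make_small_problem()
  cfg <- fomo_config(pop_size = 8, generations = 3, threshold = 0.3, seed = 77)
  f1 <- fomo_optimize(pr$cohort, pr$coll, cfg)
  f2 <- fomo_optimize(pr$cohort, pr$coll, cfg)
  expect_identical(f1$objectives, f2$objectives)
  expect_identical(f1$genomes, f2$genomes)
  # elitism: some front member is at least as fair as the all-ones baseline
  expect_lte(min(f1$objectives[, "fairness"]), f1$baseline["fairness"])
  # front validity: pairwise nondominance
  r <- fairadmit:::nondominated_rank(f1$objectives)
  expect_true(all(r == 1L))
})

test_that("upweighting a high-FNR group does not hurt its worst-case FNR", {
  pr <- make_small_problem(n = 4000, seed = 53)
  n <- nrow(pr$cohort)
  odd <- which(seq_len(n) %% 2 == 1)
  even <- which(seq_len(n) %% 2 == 0)
  train <- pr$cohort[odd, ]
  val <- pr$cohort[even, ]
  attr(train, "protected") <- attr(val, "protected") <- c("ethnoracial", "gender")
  w_coll <- fairadmit:::collection_subset(pr$coll, odd)
  e_coll <- fairadmit:::collection_subset(pr$coll, even)
  ones <- rep(1, length(w_coll$labels))
  obj_ones <- evaluate_genome(ones, train, val, w_coll, e_coll, threshold = 0.3)
  # find the worst group under the base learner and upweight it 10x
  both <- rbind(train, val)
  dm <- fairadmit:::design_matrix(both)
  i_tr <- seq_len(nrow(train))
  fit <- fairadmit:::fit_learner(dm$x[i_tr, ], dm$y[i_tr], learner_spec("logistic"))
  p <- pmin(1, pmax(0, fairadmit:::predict_learner(fit, dm$x[-i_tr, ])))
  fnrs <- vapply(seq_along(e_coll$labels), function(j) {
    m <- e_coll$membership[, j]
    false_negative_rate(p[m], dm$y[-i_tr][m], 0.3)
  }, numeric(1))
  worst <- which.max(fnrs)
  genome <- ones
  genome[worst] <- 10
  obj_up <- evaluate_genome(genome, train, val, w_coll, e_coll, threshold = 0.3)
  expect_lte(obj_up["fairness"], obj_ones["fairness"])
})

test_that("configuration invariants are enforced", {
  expect_error(fomo_config(pop_size = 1), "at least 2")
  expect_error(fomo_config(validation_fraction = 1.2), "in \\(0, 1\\)")
  expect_error(fomo_config(w_min = -1), "w_min")
})
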