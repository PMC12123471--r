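#' Specify one experimental scenario
#'
#' A scenario bundles the debiasing group construction (`base`,
#' `single:<attr>`, `marginal`, `intersectional`), the fairness task
#' (`calibration` = multicalibration postprocessing, `fnr` = multiobjective
#' reweighting for worst-case subgroup FNR), the base learner, and the trial
#' design (number of paired trials and train/test split fraction). Whatever
#' the debiasing scenario, evaluation is always carried out over the
#' gamma-filtered intersectional collection - that shared yardstick is the
#' marginal-versus-intersectional comparison axis.
#'
#' @param scenario Scenario tag.
#' @param task `"calibration"` or `"fnr"` (ignored for scenario `"base"`,
#'   which applies no debiasing but is still evaluated under the task's
#'   pairing).
#' @param learner `"logistic"` or `"random_forest"`.
#' @param grid Optional list of [learner_spec()] candidates for tuning;
#'   defaults to the learner's standard grid.
#' @param n_trials Number of independently seeded trials (default 100).
#' @param split_fraction Fraction of rows assigned to training (default 0.5).
#' @param base_seed Base integer seed; trial `t` uses `base_seed + t`.
#' @param alpha,gamma Multicalibration bound and prevalence cutoff.
#' @param threshold Classification threshold for FNR/FPR/balanced accuracy.
#' @param tune `"per_trial"` retunes hyperparameters inside every trial;
#'   `"once"` reuses the first trial's winner.
#' @param fomo A [fomo_config()] used when `task = "fnr"`.
#' @param selection_policy Solution-selection policy for the `fnr` task.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = "base",
                          task = c("calibration", "fnr"),
                          learner = c("logistic", "random_forest"),
                          grid = NULL,
                          n_trials = 100L, split_fraction = 0.5,
                          base_seed = 1L, alpha = 0.01, gamma = 0.001,
                          threshold = 0.5,
                          tune = c("per_trial", "once"),
                          fomo = NULL,
                          selection_policy = "guarded") {
  task <- match.arg(task)
  learner <- match.arg(learner)
  tune <- match.arg(tune)
  valid <- scenario %in% c("base", "marginal", "intersectional") ||
    startsWith(scenario, "single:")
  if (!valid) stopf("invalid scenario tag '%s'", scenario)
  if (n_trials < 1) stopf("`n_trials` must be at least 1")
  if (split_fraction <= 0 || split_fraction >= 1) {
    stopf("`split_fraction` must be in (0, 1)")
  }
  structure(list(scenario = scenario, task = task, learner = learner,
                 grid = grid, n_trials = as.integer(n_trials),
                 split_fraction = split_fraction,
                 base_seed = as.integer(base_seed),
                 alpha = alpha, gamma = gamma, threshold = threshold,
                 tune = tune, fomo = fomo,
                 selection_policy = selection_policy),
            class = "scenario_spec")
}

# Seeded row split with retry on degenerate (single-class) training halves.
split_rows <- function(y, split_fraction, trial_seed, max_retries = 10L) {
  for (r in 0:max_retries) {
    seed <- trial_seed + r * 1000003
    idx <- with_seed(seed, sample.int(length(y)))
    n_train <- round(split_fraction * length(y))
    train <- sort(idx[seq_len(n_train)])
    test <- sort(idx[-seq_len(n_train)])
    if (length(unique(y[train])) == 2L && length(unique(y[test])) == 2L) {
      if (r > 0) message(sprintf("degenerate split retried %d time(s)", r))
      return(list(train = train, test = test))
    }
  }
  stopf("could not produce a two-class split after %d retries", max_retries)
}

#' Run one trial of a scenario
#'
#' One trial = one seeded 50/50 row split, hyperparameter tuning on the
#' training half (successive-halving grid search, stratified 3-fold CV on
#' balanced accuracy), the scenario's fairness intervention, and evaluation
#' of the test half over the gamma-filtered intersectional collection
#' (built on the full data before splitting so the group list is identical
#' across trials).
#'
#' @param data Cohort tibble with declared protected attributes.
#' @param spec A [scenario_spec()].
#' @param trial_seed Integer seed for this trial's split and tuning.
#' @param tuned Optional pre-tuned [learner_spec()] (used by
#'   [run_experiment()] in `"once"` mode).
#' @return An object of class `trial_result`: list with `metrics` (the
#'   [subgroup_metric_table()] on test), `auroc`, `auprc`,
#'   `mean_group_ece`, `max_group_ece`, `mean_group_fnr`, `max_group_fnr`,
#'   `converged`, `n_violations` (test-set audit), and bookkeeping fields.
#' @export
run_trial <- function(data, spec, trial_seed, tuned = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  protected <- protected_attributes(data)
  y_all <- data$admitted
  if (length(unique(y_all)) < 2L) stopf("data must contain both classes")

  eval_coll <- prevalence_filter(
    build_collection(data, protected, "intersectional"), spec$gamma)
  debias_coll <- prevalence_filter(
    build_collection(data, protected, spec$scenario), spec$gamma)

  split <- split_rows(y_all, spec$split_fraction, trial_seed)
  train <- data[split$train, , drop = FALSE]
  attr(train, "protected") <- protected
  dm <- design_matrix(data)
  x_train <- dm$x[split$train, , drop = FALSE]
  x_test <- dm$x[split$test, , drop = FALSE]
  y_train <- y_all[split$train]
  y_test <- y_all[split$test]
  debias_train <- collection_subset(debias_coll, split$train)
  eval_test <- collection_subset(eval_coll, split$test)

  if (is.null(tuned)) {
    tuned <- halving_grid_search(train, grid = spec$grid,
                                 model = spec$learner,
                                 seed = substream_seed(trial_seed, "tune"),
                                 threshold = spec$threshold)
  }

  converged <- NA
  if (spec$scenario == "base" || spec$task == "calibration") {
    fit <- fit_learner(x_train, y_train, tuned)
    s_test <- clip01(predict_learner(fit, x_test))
    if (spec$scenario != "base") {
      s_train <- clip01(predict_learner(fit, x_train))
      mc <- fit_multicalibration(
        s_train, y_train, debias_train,
        multicalib_config(alpha = spec$alpha, gamma = spec$gamma))
      converged <- mc$post$converged
      s_test <- apply_postprocessor(mc$post, s_test,
                                    collection_subset(debias_coll, split$test))
    }
  } else {
    fcfg <- spec$fomo %||% fomo_config(learner = tuned,
                                       threshold = spec$threshold,
                                       gamma = spec$gamma)
    fcfg$learner <- tuned
    fcfg$seed <- substream_seed(trial_seed, "fomo")
    front <- fomo_optimize(train, debias_train, fcfg,
                           eval_collection = collection_subset(eval_coll,
                                                               split$train))
    sol <- select_solution(front, spec$selection_policy)
    w <- expand_weights(sol$genome, debias_train)
    fit <- fit_learner(x_train, y_train, tuned, weights = w)
    s_test <- clip01(predict_learner(fit, x_test))
    converged <- TRUE
  }

  metrics <- subgroup_metric_table(s_test, y_test, eval_test,
                                   threshold = spec$threshold)
  rm_ <- rank_metrics(s_test, y_test)
  audit <- audit_multicalibration(s_test, y_test, eval_test,
                                  alpha = spec$alpha, gamma = spec$gamma)
  pick <- function(metric, row) metrics[[metric]][metrics$group == row]
  structure(list(
    scenario = spec$scenario, task = spec$task, learner = spec$learner,
    trial_seed = trial_seed,
    metrics = metrics, auroc = rm_$auroc, auprc = rm_$auprc,
    mean_group_ece = pick("ece", "mean_over_groups"),
    max_group_ece = pick("ece", "max_over_groups"),
    mean_group_fnr = pick("fnr", "mean_over_groups"),
    max_group_fnr = pick("fnr", "max_over_groups"),
    overall_ece = pick("ece", "overall"),
    overall_fnr = pick("fnr", "overall"),
    converged = converged,
    n_violations = nrow(audit$violations),
    tuned = tuned,
    n_train = length(split$train), n_test = length(split$test)
  ), class = "trial_result")
}

#' Run the paired multi-trial experiment
#'
#' Executes every scenario spec for `n_trials` trials. Trial `t` of every
#' scenario shares the same split seed (`base_seed + t`), so scenarios are
#' compared on identical train/test partitions - the paired design the
#' signed-rank tests require.
#'
#' @param data Cohort tibble.
#' @param specs List of [scenario_spec()]; all must share `n_trials` and
#'   `base_seed`.
#' @param progress Emit per-trial progress messages (default `FALSE`).
#' @return A tibble in long format: one row per (scenario, task, learner,
#'   trial) with the summary metrics and a `result` list-column holding the
#'   full `trial_result`.
#' @export
run_experiment <- function(data, specs, progress = FALSE) {
  if (length(specs) == 0L) {
    return(tibble::tibble(scenario = character(0), task = character(0),
                          learner = character(0), trial = integer(0)))
  }
  n_trials <- unique(vapply(specs, `[[`, integer(1), "n_trials"))
  base_seed <- unique(vapply(specs, `[[`, integer(1), "base_seed"))
  if (length(n_trials) != 1L || length(base_seed) != 1L) {
    stopf("all specs must share `n_trials` and `base_seed` for pairing")
  }
  rows <- list()
  tuned_cache <- list()
  for (t in seq_len(n_trials)) {
    trial_seed <- base_seed + t
    for (spec in specs) {
      key <- paste(spec$scenario, spec$task, spec$learner)
      tuned <- NULL
      if (spec$tune == "once" && !is.null(tuned_cache[[key]])) {
        tuned <- tuned_cache[[key]]
      }
      res <- run_trial(data, spec, trial_seed, tuned = tuned)
      if (spec$tune == "once") tuned_cache[[key]] <- res$tuned
      if (progress) {
        message(sprintf("trial %d/%d %s/%s: mean group ECE %.4f, mean group FNR %.4f",
                        t, n_trials, spec$scenario, spec$task,
                        res$mean_group_ece, res$mean_group_fnr))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scenario = spec$scenario, task = spec$task, learner = spec$learner,
        trial = t, trial_seed = trial_seed,
        mean_group_ece = res$mean_group_ece,
        max_group_ece = res$max_group_ece,
        mean_group_fnr = res$mean_group_fnr,
        max_group_fnr = res$max_group_fnr,
        overall_ece = res$overall_ece, overall_fnr = res$overall_fnr,
        auroc = res$auroc, auprc = res$auprc,
        converged = res$converged, n_violations = res$n_violations,
        result = list(res)
      )
    }
  }
  do.call(rbind, rows)
}

#' Paired scenario comparisons with multiplicity correction
#'
#' For each scenario pair, forms the per-trial paired differences of a
#' summary metric (first scenario minus second), runs the two-sided
#' Wilcoxon signed-rank test, and adjusts the p values across all pairs in
#' the report with Holm-Bonferroni. Significance is declared at adjusted
#' p <= 0.05.
#'
#' @param results Tibble from [run_experiment()].
#' @param pairs List of length-2 character vectors of scenario tags.
#' @param metric Summary metric column, e.g. `"mean_group_ece"` or
#'   `"mean_group_fnr"`.
#' @param task Optional task filter when `results` holds several tasks.
#' @return A tibble: one row per pair with medians of both scenarios, the
#'   signed-rank statistic, raw and adjusted p, and a significance flag.
#' @export
summarize_report <- function(results, pairs, metric = "mean_group_ece",
                             task = NULL) {
  if (!metric %in% names(results)) stopf("unknown metric '%s'", metric)
  if (!is.null(task)) results <- results[results$task == task, , drop = FALSE]
  rows <- list()
  for (pr in pairs) {
    a <- results[results$scenario == pr[1], , drop = FALSE]
    b <- results[results$scenario == pr[2], , drop = FALSE]
    a <- a[order(a$trial), , drop = FALSE]
    b <- b[order(b$trial), , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L || !identical(a$trial, b$trial)) {
      stopf("scenarios '%s' and '%s' do not have paired trials", pr[1], pr[2])
    }
    d <- a[[metric]] - b[[metric]]
    wt <- suppressWarnings(wilcoxon_signed_rank(d))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      scenario_a = pr[1], scenario_b = pr[2], metric = metric,
      n_trials = nrow(a),
      median_a = stats::median(a[[metric]]),
      median_b = stats::median(b[[metric]]),
      median_diff = stats::median(d),
      statistic = wt$statistic, p_value = wt$p_value
    )
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_bonferroni(out$p_value)
  out$significant <- out$p_adjusted <= 0.05
  out
}
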