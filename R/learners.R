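#' Base learner specification
#'
#' The two learner families used throughout: penalized logistic regression
#' (elastic-net logistic via glmnet; `penalty` selects the l1 or l2 norm and
#' `C` is the inverse regularization strength, mapped to
#' `lambda = 1 / (C * n)`) and a random forest (`ranger`, probability
#' forest). Defaults follow common clinical tabular baselines: logistic l2
#' with `C = 1`; forest with 100 trees of depth 4.
#'
#' @param model `"logistic"` or `"random_forest"`.
#' @param penalty `"l1"` or `"l2"` (logistic only).
#' @param C Inverse regularization strength (logistic only).
#' @param num_trees,max_depth Forest size controls (random forest only).
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(model = c("logistic", "random_forest"),
                         penalty = "l2", C = 1.0,
                         num_trees = 100L, max_depth = 4L) {
  model <- match.arg(model)
  if (!penalty %in% c("l1", "l2")) stopf("`penalty` must be 'l1' or 'l2'")
  if (C <= 0) stopf("`C` must be positive")
  structure(list(model = model, penalty = penalty, C = C,
                 num_trees = as.integer(num_trees),
                 max_depth = as.integer(max_depth)),
            class = "learner_spec")
}

# Numeric design matrix for a cohort: every column except the outcome and
# the generator's true_risk oracle; protected attributes enter as main-effect
# dummies only (no interactions), mirroring a fairness-agnostic tabular
# model that cannot absorb intersectional structure.
design_matrix <- function(data, outcome = "admitted") {
  drop_cols <- intersect(c(outcome, "true_risk"), names(data))
  x_df <- data[, setdiff(names(data), drop_cols), drop = FALSE]
  x_df <- as.data.frame(lapply(x_df, function(col) {
    if (is.character(col)) factor(col) else col
  }), stringsAsFactors = FALSE)
  x <- stats::model.matrix(~ . - 1, data = x_df)
  list(x = x, y = data[[outcome]])
}

# Fit a learner spec on a numeric design matrix with optional per-record
# weights; returns a handle usable by predict_learner().
fit_learner <- function(x, y, spec, weights = NULL) {
  stopifnot(inherits(spec, "learner_spec"))
  if (is.null(weights)) weights <- rep(1, length(y))
  if (spec$model == "logistic") {
    lambda <- 1 / (spec$C * length(y))
    fit <- glmnet::glmnet(
      x, y, family = "binomial",
      alpha = if (spec$penalty == "l1") 1 else 0,
      weights = weights,
      lambda = lambda * c(64, 16, 4, 1),
      standardize = TRUE
    )
    structure(list(model = "logistic", fit = fit, lambda = lambda),
              class = "fitted_learner")
  } else {
    if (!requireNamespace("ranger", quietly = TRUE)) {
      stopf("the random forest learner requires the 'ranger' package")
    }
    df <- data.frame(x, check.names = FALSE)
    df$.outcome <- factor(y, levels = c(0, 1))
    fit <- ranger::ranger(
      dependent.variable.name = ".outcome", data = df,
      probability = TRUE, num.trees = spec$num_trees,
      max.depth = spec$max_depth, case.weights = weights,
      num.threads = 1, seed = 1
    )
    structure(list(model = "random_forest", fit = fit,
                   feature_names = colnames(x)),
              class = "fitted_learner")
  }
}

predict_learner <- function(fit, x) {
  if (fit$model == "logistic") {
    as.numeric(stats::predict(fit$fit, newx = x, s = fit$lambda,
                              type = "response"))
  } else {
    df <- data.frame(x, check.names = FALSE)
    p <- stats::predict(fit$fit, data = df, num.threads = 1)$predictions
    as.numeric(p[, "1"])
  }
}

# Default hyperparameter grids, as lists of learner_spec.
default_grid <- function(model) {
  if (model == "logistic") {
    grid <- list()
    for (pen in c("l1", "l2")) {
      for (C in c(0.01, 0.1, 1, 10)) {
        grid[[length(grid) + 1L]] <- learner_spec("logistic", penalty = pen, C = C)
      }
    }
    grid
  } else {
    list(learner_spec("random_forest"))
  }
}

# Stratified fold assignment: within each outcome class, records are dealt
# round-robin into k folds after a seeded shuffle.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    folds <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

# Mean cross-validated balanced accuracy of one candidate on (x, y).
cv_balanced_accuracy <- function(x, y, spec, k = 3L, seed = 1L,
                                 threshold = 0.5) {
  folds <- stratified_folds(y, k, seed)
  scores <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
      return(NA_real_)
    }
    fit <- fit_learner(x[tr, , drop = FALSE], y[tr], spec)
    p <- predict_learner(fit, x[!tr, , drop = FALSE])
    balanced_accuracy(clip01(p), y[!tr], threshold)
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Successive-halving hyperparameter search
#'
#' Tunes a learner over a candidate grid by successive halving: every
#' surviving candidate is scored by stratified 3-fold cross-validated
#' balanced accuracy on a stratified subsample of the training data, the
#' worse half is dropped, and the subsample doubles each rung until the full
#' training set is used.
#'
#' @param data Training cohort tibble (or any table with the outcome column).
#' @param grid List of [learner_spec()] candidates; defaults to the model's
#'   standard grid.
#' @param model Learner family used when `grid` is `NULL`.
#' @param seed Integer seed for fold and subsample draws.
#' @param k Number of CV folds.
#' @param threshold Classification threshold for balanced accuracy.
#' @return The winning `learner_spec`, with the rung history in
#'   `attr(, "history")`.
#' @export
halving_grid_search <- function(data, grid = NULL, model = "logistic",
                                seed = 1L, k = 3L, threshold = 0.5) {
  if (is.null(grid)) grid <- default_grid(model)
  if (length(grid) == 1L) return(grid[[1L]])
  dm <- design_matrix(data)
  n <- nrow(dm$x)
  rungs <- ceiling(log2(length(grid)))
  alive <- seq_along(grid)
  history <- list()
  for (r in seq_len(rungs)) {
    frac <- 1 / 2^(rungs - r)
    idx <- if (frac < 1) {
      with_seed(substream_seed(seed, paste0("halving:", r)), {
        unlist(lapply(unique(dm$y), function(cls) {
          pool <- which(dm$y == cls)
          sample(pool, max(2L, round(frac * length(pool))))
        }))
      })
    } else {
      seq_len(n)
    }
    scores <- vapply(alive, function(i) {
      cv_balanced_accuracy(dm$x[idx, , drop = FALSE], dm$y[idx], grid[[i]],
                           k = k, seed = substream_seed(seed, "cv"),
                           threshold = threshold)
    }, numeric(1))
    history[[r]] <- data.frame(rung = r, candidate = alive, score = scores)
    keep <- ceiling(length(alive) / 2)
    alive <- alive[order(-scores)][seq_len(keep)]
    if (length(alive) == 1L) break
  }
  best <- grid[[alive[1L]]]
  attr(best, "history") <- do.call(rbind, history)
  best
}
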