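#' Configuration for fairness-oriented multiobjective training
#'
#' Settings for the evolutionary search over per-group sample-weight
#' multipliers. Two objectives are minimized jointly: `1 - balanced
#' accuracy` of the weighted learner on an internal validation split, and
#' the worst (maximum) false-negative rate over the intersectional
#' subgroups of that split. The all-ones genome (the unweighted base
#' learner) is always injected into the initial population, so the search
#' can never lose the baseline from its nondominated set.
#'
#' @param pop_size Population size (>= 2, default 50).
#' @param generations Number of generations (default 50).
#' @param crossover_prob Probability of recombining a parent pair (simulated
#'   binary crossover, default 0.9).
#' @param mutation_prob Per-gene polynomial mutation probability; default
#'   `1 / genome length`.
#' @param eta_crossover,eta_mutation Distribution indices of the SBX and
#'   polynomial-mutation operators (defaults 15 and 20).
#' @param validation_fraction Fraction of the training data held out
#'   (stratified by outcome) for objective evaluation (default 0.25).
#' @param w_min,w_max Box constraints on each weight multiplier (defaults
#'   0.1 and 10).
#' @param learner A [learner_spec()] fitted for every genome.
#' @param threshold Classification threshold for both objectives.
#' @param gamma Prevalence cutoff applied when the intersectional evaluation
#'   collection is built internally.
#' @param seed Integer seed; identical `(data, config)` yields an identical
#'   Pareto front.
#' @return An object of class `fomo_config`.
#' @export
fomo_config <- function(pop_size = 50L, generations = 50L,
                        crossover_prob = 0.9, mutation_prob = NULL,
                        eta_crossover = 15, eta_mutation = 20,
                        validation_fraction = 0.25,
                        w_min = 0.1, w_max = 10,
                        learner = learner_spec("logistic"),
                        threshold = 0.5, gamma = 0.001, seed = 1L) {
  if (pop_size < 2) stopf("`pop_size` must be at least 2")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stopf("`validation_fraction` must be in (0, 1)")
  }
  if (w_min <= 0 || w_max < w_min) stopf("need 0 < w_min <= w_max")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 eta_crossover = eta_crossover, eta_mutation = eta_mutation,
                 validation_fraction = validation_fraction,
                 w_min = w_min, w_max = w_max, learner = learner,
                 threshold = threshold, gamma = gamma,
                 seed = as.integer(seed)),
            class = "fomo_config")
}

# Per-record weights from a genome: multipliers of all groups containing a
# record are multiplied together; records in no group keep weight 1. For an
# empty (base) collection the single gene is a global weight.
expand_weights <- function(genome, collection, idx = NULL) {
  m <- collection$membership
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  n <- nrow(m)
  if (ncol(m) == 0L) return(rep(genome[1L], n))
  w <- rep(1, n)
  for (j in seq_len(ncol(m))) w[m[, j]] <- w[m[, j]] * genome[j]
  w
}

# Objective evaluation on prepared matrices (hot path of the optimizer).
eval_genome_matrix <- function(genome, x_fit, y_fit, w_coll_fit,
                               x_val, y_val, eval_coll_val,
                               learner, threshold) {
  w <- expand_weights(genome, w_coll_fit)
  res <- tryCatch({
    fit <- fit_learner(x_fit, y_fit, learner, weights = w)
    p <- clip01(predict_learner(fit, x_val))
    err <- 1 - balanced_accuracy(p, y_val, threshold)
    fnrs <- vapply(seq_along(eval_coll_val$labels), function(j) {
      m <- eval_coll_val$membership[, j]
      false_negative_rate(p[m], y_val[m], threshold)
    }, numeric(1))
    fnrs <- fnrs[!is.na(fnrs)]
    fair <- if (length(fnrs)) max(fnrs) else false_negative_rate(p, y_val, threshold)
    # Validation AUROC is carried along for the accuracy-guarded selection
    # policy; it is bookkeeping, not an optimization objective.
    c(error = err, fairness = fair, auroc = rank_metrics(p, y_val)$auroc)
  }, error = function(e) {
    warning(sprintf("genome evaluation failed (%s); assigned worst fitness",
                    conditionMessage(e)), call. = FALSE)
    c(error = 1, fairness = 1, auroc = 0)
  })
  res
}

#' Evaluate one weight genome
#'
#' Expands a per-group weight genome to per-record sample weights, fits the
#' base learner on the training records with those weights, scores the
#' validation records, and returns the objective pair: `error` =
#' `1 - balanced accuracy` overall, `fairness` = maximum false-negative rate
#' over the intersectional evaluation subgroups (groups without positives
#' are excluded from the maximum).
#'
#' @param genome Positive weight multipliers, one per group of
#'   `weight_collection` (length 1 for an empty base collection).
#' @param train,validation Cohort tibbles (factor encodings are shared).
#' @param weight_collection `group_collection` on the training records that
#'   indexes the genome.
#' @param eval_collection `group_collection` on the validation records over
#'   which worst-case FNR is taken (typically intersectional).
#' @param learner A [learner_spec()].
#' @param threshold Classification threshold.
#' @return Named numeric vector `c(error = , fairness = , auroc = )`; the
#'   third element is the validation AUROC used by the accuracy-guarded
#'   selection policy.
#' @export
evaluate_genome <- function(genome, train, validation, weight_collection,
                            eval_collection, learner = learner_spec("logistic"),
                            threshold = 0.5) {
  d <- max(1L, length(weight_collection$labels))
  if (length(genome) != d) {
    stopf("genome length %d does not match the %d weight group(s)",
          length(genome), d)
  }
  both <- rbind(train, validation)
  dm <- design_matrix(both)
  i_tr <- seq_len(nrow(train))
  i_va <- nrow(train) + seq_len(nrow(validation))
  eval_genome_matrix(genome, dm$x[i_tr, , drop = FALSE], dm$y[i_tr],
                     weight_collection,
                     dm$x[i_va, , drop = FALSE], dm$y[i_va],
                     eval_collection, learner, threshold)
}

# --- NSGA-II machinery (minimization in both objectives) -------------------

dominates <- function(a, b) all(a <= b) && any(a < b)

# Integer front ranks, 1 = nondominated.
nondominated_rank <- function(obj) {
  n <- nrow(obj)
  rank_out <- integer(n)
  dominated_by <- vector("list", n)
  n_dom <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(obj[i, ], obj[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(obj[j, ], obj[i, ])) {
        n_dom[i] <- n_dom[i] + 1L
      }
    }
  }
  front <- which(n_dom == 0L)
  r <- 1L
  while (length(front)) {
    rank_out[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in dominated_by[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- nxt
    r <- r + 1L
  }
  rank_out
}

crowding_distance <- function(obj) {
  n <- nrow(obj)
  d <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    rng <- obj[o[n], m] - obj[o[1], m]
    d[o[1]] <- d[o[n]] <- Inf
    if (n > 2 && rng > 0) {
      for (i in 2:(n - 1)) {
        d[o[i]] <- d[o[i]] + (obj[o[i + 1], m] - obj[o[i - 1], m]) / rng
      }
    }
  }
  d
}

sbx_crossover <- function(p1, p2, eta, lo, hi) {
  u <- stats::runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  swap <- stats::runif(length(p1)) < 0.5
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  c1s <- ifelse(swap, c2, c1)
  c2s <- ifelse(swap, c1, c2)
  list(pmin(hi, pmax(lo, c1s)), pmin(hi, pmax(lo, c2s)))
}

poly_mutation <- function(x, prob, eta, lo, hi) {
  hit <- stats::runif(length(x)) < prob
  if (!any(hit)) return(x)
  u <- stats::runif(length(x))
  span <- hi - lo
  delta <- ifelse(u < 0.5,
                  (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  x[hit] <- pmin(hi, pmax(lo, x[hit] + delta[hit] * span))
  x
}

#' Search for Pareto-optimal fairness-accuracy weightings
#'
#' Runs a seeded elitist multiobjective evolutionary search (nondominated
#' sorting with crowding-distance diversity, simulated binary crossover and
#' polynomial mutation on box-constrained real genomes) over per-group
#' sample-weight multipliers for the base learner. Returns the final
#' nondominated set of (genome, objectives) solutions.
#'
#' @param train_data Training cohort tibble (protected attributes declared).
#' @param collection `group_collection` on `train_data` whose groups index
#'   the genome (the debiasing scenario); an empty collection optimizes a
#'   single global weight.
#' @param config A [fomo_config()].
#' @param eval_collection Optional `group_collection` on `train_data` used
#'   for the worst-case FNR objective; defaults to the gamma-filtered
#'   intersectional collection.
#' @return An object of class `pareto_front`: list with `genomes` (matrix,
#'   one row per solution), `objectives` (matrix with columns `error`,
#'   `fairness`), `baseline` (objectives of the all-ones genome), `config`,
#'   and `group_labels`.
#' @export
fomo_optimize <- function(train_data, collection, config = fomo_config(),
                          eval_collection = NULL) {
  stopifnot(inherits(config, "fomo_config"))
  if (is.null(eval_collection)) {
    eval_collection <- prevalence_filter(
      build_collection(train_data, scenario = "intersectional"),
      config$gamma)
  }
  n <- nrow(train_data)
  dm <- design_matrix(train_data)
  split_seed <- substream_seed(config$seed, "fomo:split")
  folds <- stratified_folds(dm$y, round(1 / config$validation_fraction),
                            split_seed)
  i_va <- which(folds == 1L)
  i_fit <- which(folds != 1L)
  x_fit <- dm$x[i_fit, , drop = FALSE]
  y_fit <- dm$y[i_fit]
  x_val <- dm$x[i_va, , drop = FALSE]
  y_val <- dm$y[i_va]
  w_coll_fit <- collection_subset(collection, i_fit)
  eval_coll_val <- collection_subset(eval_collection, i_va)

  d <- max(1L, length(collection$labels))
  mut_prob <- config$mutation_prob %||% (1 / d)
  lo <- config$w_min
  hi <- config$w_max
  np <- config$pop_size

  eval_one <- function(g) {
    eval_genome_matrix(g, x_fit, y_fit, w_coll_fit, x_val, y_val,
                       eval_coll_val, config$learner, config$threshold)
  }

  with_seed(substream_seed(config$seed, "fomo:search"), {
    pop <- matrix(stats::runif(np * d, lo, hi), nrow = np)
    pop[1L, ] <- 1  # baseline genome always present at initialization
    res <- t(apply(pop, 1L, eval_one))
    obj <- res[, 1:2, drop = FALSE]
    aux <- res[, 3L]
    baseline <- res[1L, ]

    for (gen in seq_len(config$generations)) {
      ranks <- nondominated_rank(obj)
      crowd <- numeric(np)
      for (r in unique(ranks)) {
        idx <- which(ranks == r)
        crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
      }
      pick <- function() {
        ij <- sample.int(np, 2L)
        i <- ij[1L]; j <- ij[2L]
        if (ranks[i] < ranks[j]) i
        else if (ranks[j] < ranks[i]) j
        else if (crowd[i] >= crowd[j]) i else j
      }
      children <- matrix(0, nrow = np, ncol = d)
      k <- 1L
      while (k <= np) {
        p1 <- pop[pick(), ]
        p2 <- pop[pick(), ]
        if (stats::runif(1) < config$crossover_prob) {
          cs <- sbx_crossover(p1, p2, config$eta_crossover, lo, hi)
        } else {
          cs <- list(p1, p2)
        }
        children[k, ] <- poly_mutation(cs[[1L]], mut_prob,
                                       config$eta_mutation, lo, hi)
        if (k + 1L <= np) {
          children[k + 1L, ] <- poly_mutation(cs[[2L]], mut_prob,
                                              config$eta_mutation, lo, hi)
        }
        k <- k + 2L
      }
      child_res <- t(apply(children, 1L, eval_one))
      all_pop <- rbind(pop, children)
      all_obj <- rbind(obj, child_res[, 1:2, drop = FALSE])
      all_aux <- c(aux, child_res[, 3L])
      all_rank <- nondominated_rank(all_obj)
      sel <- integer(0)
      for (r in sort(unique(all_rank))) {
        idx <- which(all_rank == r)
        if (length(sel) + length(idx) <= np) {
          sel <- c(sel, idx)
        } else {
          cd <- crowding_distance(all_obj[idx, , drop = FALSE])
          sel <- c(sel, idx[order(-cd)][seq_len(np - length(sel))])
          break
        }
      }
      pop <- all_pop[sel, , drop = FALSE]
      obj <- all_obj[sel, , drop = FALSE]
      aux <- all_aux[sel]
      np <- nrow(pop)
    }

    final_rank <- nondominated_rank(obj)
    keep <- which(final_rank == 1L)
    genomes <- pop[keep, , drop = FALSE]
    objs <- obj[keep, , drop = FALSE]
    auxs <- aux[keep]
    dup <- duplicated(cbind(round(objs, 12)))
    genomes <- genomes[!dup, , drop = FALSE]
    objs <- objs[!dup, , drop = FALSE]
    auxs <- auxs[!dup]
    ord <- order(objs[, 1L], objs[, 2L])
    colnames(objs) <- c("error", "fairness")
    structure(list(genomes = genomes[ord, , drop = FALSE],
                   objectives = objs[ord, , drop = FALSE],
                   val_auroc = auxs[ord],
                   baseline = baseline,
                   config = config,
                   group_labels = collection$labels),
              class = "pareto_front")
  })
}

#' @exportS3Method base::print
print.pareto_front <- function(x, ...) {
  cat(sprintf("<pareto_front> %d solution(s) over %d weight group(s)\n",
              nrow(x$objectives), ncol(x$genomes)))
  print(round(x$objectives, 4))
  invisible(x)
}

#' Pick one solution from a Pareto front
#'
#' Three deterministic policies. `"min_fairness"` takes the solution with
#' the smallest worst-case subgroup FNR, breaking ties by smaller error.
#' `"knee"` min-max normalizes both objectives over the front and takes the
#' solution closest (Euclidean) to the ideal point (0, 0). `"guarded"`
#' takes the smallest worst-case FNR among solutions whose validation AUROC
#' is within `guard_band` of the unweighted baseline's - i.e. the largest
#' fairness gain that costs essentially no overall discrimination ability
#' (falling back to the highest-AUROC solution if the band is empty); this
#' encodes the requirement that debiasing must not degrade overall
#' performance.
#'
#' @param front A `pareto_front`.
#' @param policy `"guarded"`, `"min_fairness"`, or `"knee"`.
#' @param guard_band Allowed validation AUROC shortfall against the
#'   baseline for the `"guarded"` policy (default 0.01).
#' @return List with `genome`, `objectives`, and the solution `index`.
#' @export
select_solution <- function(front, policy = c("guarded", "min_fairness", "knee"),
                            guard_band = 0.01) {
  policy <- match.arg(policy)
  obj <- front$objectives
  if (nrow(obj) == 0L) stopf("empty Pareto front")
  idx <- if (policy == "min_fairness") {
    order(obj[, "fairness"], obj[, "error"])[1L]
  } else if (policy == "guarded") {
    floor_auroc <- unname(front$baseline["auroc"]) - guard_band
    ok <- which(front$val_auroc >= floor_auroc)
    if (length(ok)) {
      ok[order(obj[ok, "fairness"], obj[ok, "error"])[1L]]
    } else {
      order(-front$val_auroc, obj[, "fairness"])[1L]
    }
  } else {
    norm <- apply(obj, 2L, function(col) {
      rng <- max(col) - min(col)
      if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
    })
    norm <- matrix(norm, ncol = 2L)
    order(sqrt(norm[, 1L]^2 + norm[, 2L]^2))[1L]
  }
  list(genome = front$genomes[idx, ], objectives = obj[idx, ], index = idx)
}

#' Refit a selected weighting on the full training data
#'
#' Expands the chosen genome over the full training collection, fits the
#' base learner once with those fixed weights, and returns the fitted
#' handle together with a scoring closure for new cohort tables.
#'
#' @param solution Result of [select_solution()].
#' @param train_data Full training cohort tibble.
#' @param collection `group_collection` on `train_data` indexing the genome.
#' @param learner A [learner_spec()].
#' @return List with `fit` (fitted learner handle) and `weights`.
#' @export
refit_solution <- function(solution, train_data, collection,
                           learner = learner_spec("logistic")) {
  dm <- design_matrix(train_data)
  w <- expand_weights(solution$genome, collection)
  list(fit = fit_learner(dm$x, dm$y, learner, weights = w), weights = w)
}

#' Export a Pareto front as a tidy table
#'
#' @param front A `pareto_front`.
#' @return A tibble with one row per solution: objectives then one column
#'   per weight group.
#' @export
front_to_table <- function(front) {
  g <- front$genomes
  colnames(g) <- if (length(front$group_labels)) front$group_labels else "global_weight"
  tibble::as_tibble(cbind(as.data.frame(front$objectives), as.data.frame(g)))
}
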