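#' Multicalibration boosting configuration
#'
#' @param alpha Calibration bound: a (group, bin) cell is repaired while the
#'   absolute gap between its mean outcome and mean prediction exceeds
#'   `alpha` (default 0.01).
#' @param gamma Prevalence cutoff: cells holding less than this fraction of
#'   all records are never touched (default 0.001).
#' @param binning A [binning_scheme()] (default 10 equal-width bins).
#' @param max_sweeps Maximum full passes over (group x bin) cells before
#'   giving up (default 100); non-convergence raises a warning, never fails
#'   silently.
#' @param step Update damping factor in `(0, 1]` (default 1: each repaired
#'   cell's residual is zeroed before clipping).
#' @param sweep_order `"canonical"` (groups in label order, bins ascending;
#'   deterministic, the default) or `"random"` (cells permuted each sweep
#'   under `order_seed`).
#' @param order_seed Seed for the `"random"` sweep order.
#' @return An object of class `multical_config`.
#' @export
multicalib_config <- function(alpha = 0.01, gamma = 0.001,
                              binning = binning_scheme(),
                              max_sweeps = 100L, step = 1.0,
                              sweep_order = c("canonical", "random"),
                              order_seed = 1L) {
  sweep_order <- match.arg(sweep_order)
  if (alpha <= 0 || alpha >= 1) stopf("`alpha` must be in (0, 1)")
  if (gamma < 0 || gamma > 1) stopf("`gamma` must be in [0, 1]")
  if (step <= 0 || step > 1) stopf("`step` must be in (0, 1]")
  if (max_sweeps < 1) stopf("`max_sweeps` must be positive")
  structure(list(alpha = alpha, gamma = gamma, binning = binning,
                 max_sweeps = as.integer(max_sweeps), step = step,
                 sweep_order = sweep_order,
                 order_seed = as.integer(order_seed)),
            class = "multical_config")
}

#' Fit the multicalibration boosting postprocessor
#'
#' Iteratively repairs risk scores until every sufficiently prevalent
#' (group x prediction-bin) cell satisfies the `alpha` calibration bound.
#' Each sweep visits groups in canonical label order and bins in ascending
#' order; a cell is re-evaluated against the *current* scores, and when its
#' prevalence is at least `gamma` and its residual
#' `mean(y | cell) - mean(s | cell)` exceeds `alpha` in absolute value, the
#' residual (damped by `step`) is added to every member's score and the
#' scores are clipped to `[0, 1]`. Fitting stops at the first sweep with no
#' update (converged) or after `max_sweeps` (warning). On convergence the
#' fit-set audit is violation-free by construction, and replaying the
#' recorded updates on the fit scores reproduces the fitted scores exactly.
#'
#' @param scores Initial predicted probabilities.
#' @param outcomes Binary 0/1 outcomes, same records.
#' @param collection `group_collection` built on the same records.
#' @param config A [multicalib_config()].
#' @return A list with `post` (class `postprocessor`: config, ordered update
#'   tibble, `converged`, `sweeps`, fit-set `audit`) and `scores` (the
#'   adjusted vector).
#' @examples
#' cohort <- generate_cohort(cohort_preset("adult_ed", 5000, seed = 2))
#' coll <- build_collection(cohort, scenario = "intersectional")
#' shifted <- perturb_scores(cohort$true_risk, coll,
#'   c("ethnoracial=Black; gender=Women" = 0.15))
#' fit <- fit_multicalibration(shifted, cohort$admitted, coll)
#' fit$post$converged
#' @export
fit_multicalibration <- function(scores, outcomes, collection,
                                 config = multicalib_config()) {
  check_scores_outcomes(scores, outcomes)
  if (!inherits(config, "multical_config")) stopf("`config` must be a multical_config")
  n <- length(scores)
  s <- as.numeric(scores)
  upd_group <- character(0)
  upd_bin <- integer(0)
  upd_delta <- numeric(0)
  upd_sweep <- integer(0)
  converged <- TRUE
  sweeps <- 0L

  if (length(collection$labels)) {
    converged <- FALSE
    cells_canonical <- expand.grid(bin = seq_len(config$binning$n_bins),
                                   grp = seq_along(collection$labels))
    cells_canonical <- cells_canonical[order(cells_canonical$grp,
                                             cells_canonical$bin), ]
    for (sweep in seq_len(config$max_sweeps)) {
      sweeps <- sweep
      changed <- FALSE
      visit <- if (config$sweep_order == "random") {
        with_seed(substream_seed(config$order_seed, paste0("sweep:", sweep)),
                  cells_canonical[sample.int(nrow(cells_canonical)), ])
      } else {
        cells_canonical
      }
      for (i in seq_len(nrow(visit))) {
        j <- visit$grp[i]
        k <- visit$bin[i]
        m <- collection$membership[, j]
        cell <- m & (bin_index(s, config$binning) == k)
        size <- sum(cell)
        if (size == 0L || size / n < config$gamma) next
        resid <- mean(outcomes[cell]) - mean(s[cell])
        if (abs(resid) > config$alpha) {
          delta <- config$step * resid
          s[cell] <- clip01(s[cell] + delta)
          upd_group <- c(upd_group, collection$labels[j])
          upd_bin <- c(upd_bin, k)
          upd_delta <- c(upd_delta, delta)
          upd_sweep <- c(upd_sweep, sweep)
          changed <- TRUE
        }
      }
      if (!changed) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      warning(sprintf("multicalibration did not converge in %d sweeps (%d updates)",
                      config$max_sweeps, length(upd_delta)), call. = FALSE)
    }
  }

  updates <- tibble::tibble(group = upd_group, bin = upd_bin,
                            delta = upd_delta, sweep = upd_sweep)
  audit <- audit_multicalibration(s, outcomes, collection,
                                  binning = config$binning,
                                  alpha = config$alpha, gamma = config$gamma)
  post <- structure(list(config = config, updates = updates,
                         converged = converged, sweeps = sweeps,
                         audit = audit,
                         group_labels = collection$labels),
                    class = "postprocessor")
  list(post = post, scores = s)
}

#' Replay learned calibration updates on new scores
#'
#' Applies the postprocessor's recorded updates in order: each update adds
#' its `delta` to the records currently in (group intersect bin) - bins are
#' recomputed against the evolving scores, so a record moved out of a bin by
#' an earlier update is not touched by a later update targeting the old bin
#' - and clips to `[0, 1]`. Replaying on the fit data reproduces the fitted
#' scores exactly.
#'
#' @param post A `postprocessor` from [fit_multicalibration()].
#' @param scores Predicted probabilities on the new records.
#' @param collection `group_collection` on the new records covering the
#'   fitted group labels (see [collection_on()] helpers via
#'   [build_collection()]).
#' @return Adjusted score vector.
#' @export
apply_postprocessor <- function(post, scores, collection) {
  stopifnot(inherits(post, "postprocessor"))
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) stopf("scores must lie in [0, 1]")
  need <- unique(post$updates$group)
  missing <- setdiff(need, collection$labels)
  if (length(missing)) stopf("collection lacks fitted group '%s'", missing[1])
  s <- as.numeric(scores)
  binning <- post$config$binning
  for (i in seq_len(nrow(post$updates))) {
    g <- post$updates$group[i]
    k <- post$updates$bin[i]
    cell <- collection$membership[, g] & (bin_index(s, binning) == k)
    s[cell] <- clip01(s[cell] + post$updates$delta[i])
  }
  s
}

#' @exportS3Method base::print
print.postprocessor <- function(x, ...) {
  cat(sprintf(
    "<postprocessor> alpha=%g gamma=%g bins=%d: %d update(s) in %d sweep(s), %s\n",
    x$config$alpha, x$config$gamma, x$config$binning$n_bins,
    nrow(x$updates), x$sweeps,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Serialize a fitted postprocessor to JSON
#'
#' Writes the configuration and the ordered update list so audits are
#' portable across processes.
#'
#' @param post A `postprocessor`.
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @export
postprocessor_to_json <- function(post, path = NULL) {
  obj <- list(
    alpha = post$config$alpha, gamma = post$config$gamma,
    n_bins = post$config$binning$n_bins, step = post$config$step,
    converged = post$converged, sweeps = post$sweeps,
    updates = post$updates
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
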