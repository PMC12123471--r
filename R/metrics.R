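#' Equal-width probability binning scheme
#'
#' Partition of `[0, 1]` into `n_bins` equal-width intervals
#' `[k/n, (k+1)/n)`, with the last interval closed at 1. Used for expected
#' calibration error and for the (group x bin) cells of multicalibration.
#'
#' @param n_bins Positive integer (default 10).
#' @return An object of class `binning_scheme`.
#' @export
binning_scheme <- function(n_bins = 10L) {
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 1) {
    stopf("`n_bins` must be a positive integer")
  }
  structure(list(n_bins = as.integer(n_bins)), class = "binning_scheme")
}

# Bin index in 1..n_bins; scores equal to 1 fall in the last bin.
bin_index <- function(scores, binning) {
  pmin(floor(scores * binning$n_bins) + 1L, binning$n_bins)
}

check_scores_outcomes <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) stopf("length mismatch")
  if (length(scores) == 0L) stopf("empty input")
  if (anyNA(scores) || anyNA(outcomes)) stopf("NA in scores or outcomes")
  if (any(scores < 0 | scores > 1)) stopf("scores must lie in [0, 1]")
  if (!all(outcomes %in% c(0, 1))) stopf("outcomes must be 0/1")
  invisible(TRUE)
}

#' Binned expected calibration error
#'
#' Count-weighted mean over nonempty prediction bins of the absolute gap
#' between mean outcome and mean predicted risk:
#' `ECE = sum_b (n_b / N) * |mean(y | b) - mean(s | b)|`.
#'
#' @param scores Predicted probabilities in `[0, 1]`.
#' @param outcomes Binary 0/1 outcomes, same length.
#' @param binning A [binning_scheme()].
#' @param aggregate `"weighted_mean"` (the standard ECE, default) or
#'   `"max"` (worst occupied bin, for sensitivity checks).
#' @return ECE in `[0, 1]`.
#' @examples
#' expected_calibration_error(c(0.1, 0.9, 0.9), c(0, 1, 1))
#' @export
expected_calibration_error <- function(scores, outcomes,
                                       binning = binning_scheme(),
                                       aggregate = c("weighted_mean", "max")) {
  aggregate <- match.arg(aggregate)
  check_scores_outcomes(scores, outcomes)
  b <- bin_index(scores, binning)
  n_b <- tabulate(b, binning$n_bins)
  sum_y <- vapply(seq_len(binning$n_bins), function(k) sum(outcomes[b == k]),
                  numeric(1))
  sum_s <- vapply(seq_len(binning$n_bins), function(k) sum(scores[b == k]),
                  numeric(1))
  occ <- n_b > 0
  gaps <- abs(sum_y[occ] / n_b[occ] - sum_s[occ] / n_b[occ])
  if (aggregate == "weighted_mean") {
    sum(n_b[occ] / length(scores) * gaps)
  } else {
    max(gaps)
  }
}

#' Error rates and accuracy at a decision threshold
#'
#' `false_negative_rate()` is the fraction of true positives scored below
#' `threshold` (falsely discharged, in the admission setting);
#' `false_positive_rate()` the fraction of true negatives scored at or above
#' it. Both return `NA_real_` when their denominator class is absent -
#' undefined is a value here, not an error, so empty subgroups can be
#' excluded from summaries rather than aborting them.
#' `balanced_accuracy()` is `(sensitivity + specificity) / 2` and requires
#' both classes.
#'
#' An optional prior-smoothed FNR, `(FN + c * pi) / (P + c)` with prior
#' strength `c = prior_strength` and prior rate `pi = prior_rate`, shrinks
#' tiny-group estimates toward a population rate; it is off by default
#' (`prior_strength = 0`) and still undefined when a group has no
#' positives.
#'
#' @param scores Predicted probabilities.
#' @param outcomes Binary 0/1 outcomes.
#' @param threshold Classification threshold in `[0, 1]` (default 0.5).
#' @param prior_strength,prior_rate Smoothing pseudo-count and prior FNR
#'   for the optional shrunk estimate (defaults 0 and 0: plain FNR).
#' @return A fraction, or `NA_real_` where undefined.
#' @export
false_negative_rate <- function(scores, outcomes, threshold = 0.5,
                                prior_strength = 0, prior_rate = 0) {
  pos <- outcomes == 1
  if (!any(pos)) return(NA_real_)
  (sum(scores[pos] < threshold) + prior_strength * prior_rate) /
    (sum(pos) + prior_strength)
}

#' @rdname false_negative_rate
#' @export
false_positive_rate <- function(scores, outcomes, threshold = 0.5) {
  neg <- outcomes == 0
  if (!any(neg)) return(NA_real_)
  sum(scores[neg] >= threshold) / sum(neg)
}

#' @rdname false_negative_rate
#' @export
balanced_accuracy <- function(scores, outcomes, threshold = 0.5) {
  check_scores_outcomes(scores, outcomes)
  if (length(unique(outcomes)) < 2L) {
    stopf("balanced accuracy needs both outcome classes")
  }
  sens <- 1 - false_negative_rate(scores, outcomes, threshold)
  spec <- 1 - false_positive_rate(scores, outcomes, threshold)
  (sens + spec) / 2
}

#' Threshold-free ranking metrics
#'
#' AUROC as the probability that a random positive outscores a random
#' negative (ties count one half), computed via midranks; AUPRC by the
#' precision-weighted recall-increment rule (average precision), with tied
#' scores handled as a single threshold step.
#'
#' @inheritParams false_negative_rate
#' @return A list with elements `auroc` and `auprc`.
#' @export
rank_metrics <- function(scores, outcomes) {
  check_scores_outcomes(scores, outcomes)
  n_pos <- sum(outcomes == 1)
  n_neg <- sum(outcomes == 0)
  if (n_pos == 0L || n_neg == 0L) stopf("rank metrics need both classes")
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[outcomes == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # Average precision over descending unique score thresholds.
  ord <- order(scores, decreasing = TRUE)
  y <- outcomes[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_tie]
  fp <- fp[last_of_tie]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  d_recall <- diff(c(0, recall))
  auprc <- sum(precision * d_recall)
  list(auroc = auroc, auprc = auprc)
}

#' Per-subgroup metric table
#'
#' Computes ECE, FNR, FPR, record count and positive count for every group
#' in a collection, plus an `overall` row and `mean_over_groups` /
#' `max_over_groups` summary rows. Undefined rates (groups without the
#' denominator class) are excluded from the summaries.
#'
#' @inheritParams false_negative_rate
#' @param collection A `group_collection` whose membership rows align with
#'   `scores`.
#' @param binning A [binning_scheme()].
#' @return A tibble with columns `group`, `ece`, `fnr`, `fpr`, `count`,
#'   `positives`.
#' @export
subgroup_metric_table <- function(scores, outcomes, collection,
                                  binning = binning_scheme(),
                                  threshold = 0.5) {
  check_scores_outcomes(scores, outcomes)
  if (nrow(collection$membership) != length(scores)) {
    stopf("collection membership does not align with scores")
  }
  one_row <- function(label, s, y) {
    tibble::tibble(
      group = label,
      ece = if (length(s)) expected_calibration_error(s, y, binning) else NA_real_,
      fnr = if (length(s)) false_negative_rate(s, y, threshold) else NA_real_,
      fpr = if (length(s)) false_positive_rate(s, y, threshold) else NA_real_,
      count = length(s),
      positives = sum(y == 1)
    )
  }
  rows <- list(one_row("overall", scores, outcomes))
  for (j in seq_along(collection$labels)) {
    m <- collection$membership[, j]
    rows[[length(rows) + 1L]] <-
      one_row(collection$labels[j], scores[m], outcomes[m])
  }
  tbl <- do.call(rbind, rows)
  if (length(collection$labels)) {
    grp <- tbl[tbl$group != "overall", , drop = FALSE]
    summ <- function(f, vals) {
      vals <- vals[!is.na(vals)]
      if (!length(vals)) NA_real_ else f(vals)
    }
    tbl <- rbind(
      tbl,
      tibble::tibble(group = "mean_over_groups",
                     ece = summ(mean, grp$ece), fnr = summ(mean, grp$fnr),
                     fpr = summ(mean, grp$fpr), count = NA_integer_,
                     positives = NA_integer_),
      tibble::tibble(group = "max_over_groups",
                     ece = summ(max, grp$ece), fnr = summ(max, grp$fnr),
                     fpr = summ(max, grp$fpr), count = NA_integer_,
                     positives = NA_integer_)
    )
  }
  tbl
}

#' Audit scores against the multicalibration constraint
#'
#' Enumerates every (group, prediction-bin) cell of the collection and lists
#' the cells that are both sufficiently prevalent (cell size / total records
#' >= `gamma`) and miscalibrated (`|mean(y | cell) - mean(s | cell)| >
#' alpha`). An empty violation list certifies that the scores are
#' (alpha, gamma)-multicalibrated on this data under this binning.
#'
#' @inheritParams subgroup_metric_table
#' @param alpha Calibration bound in `(0, 1)`.
#' @param gamma Prevalence cutoff in `[0, 1]`, measured against the full
#'   evaluation set.
#' @return An object of class `multical_audit`: list with `violations`
#'   (tibble: `group`, `bin`, `size`, `prevalence`, `residual`), `alpha`,
#'   `gamma`, `n_bins`, `n`.
#' @export
audit_multicalibration <- function(scores, outcomes, collection,
                                   binning = binning_scheme(),
                                   alpha = 0.01, gamma = 0.001) {
  check_scores_outcomes(scores, outcomes)
  if (alpha <= 0 || alpha >= 1) stopf("`alpha` must be in (0, 1)")
  if (gamma < 0 || gamma > 1) stopf("`gamma` must be in [0, 1]")
  n <- length(scores)
  b <- bin_index(scores, binning)
  rows <- list()
  for (j in seq_along(collection$labels)) {
    m <- collection$membership[, j]
    for (k in seq_len(binning$n_bins)) {
      cell <- m & (b == k)
      size <- sum(cell)
      if (size == 0L || size / n < gamma) next
      resid <- mean(outcomes[cell]) - mean(scores[cell])
      if (abs(resid) > alpha) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = collection$labels[j], bin = k, size = size,
          prevalence = size / n, residual = resid)
      }
    }
  }
  violations <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(group = character(0), bin = integer(0), size = integer(0),
                   prevalence = numeric(0), residual = numeric(0))
  structure(list(violations = violations, alpha = alpha, gamma = gamma,
                 n_bins = binning$n_bins, n = n),
            class = "multical_audit")
}

#' @exportS3Method base::print
print.multical_audit <- function(x, ...) {
  cat(sprintf("<multical_audit> alpha=%g gamma=%g bins=%d n=%d: %d violation(s)\n",
              x$alpha, x$gamma, x$n_bins, x$n, nrow(x$violations)))
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}
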