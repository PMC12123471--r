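# Independent brute-force reference implementations. These deliberately use
# naive enumeration / groupwise loops so they share no code path with the
# package's vectorized metrics.

oracle_ece <- function(scores, outcomes, n_bins = 10) {
  bins <- pmin(floor(scores * n_bins), n_bins - 1)
  total <- 0
  for (b in unique(bins)) {
    in_bin <- bins == b
    total <- total +
      sum(in_bin) / length(scores) *
        abs(mean(outcomes[in_bin]) - mean(scores[in_bin]))
  }
  total
}

oracle_fnr <- function(scores, outcomes, threshold = 0.5) {
  pos <- which(outcomes == 1)
  if (length(pos) == 0) return(NA_real_)
  mean(scores[pos] < threshold)
}

oracle_balanced_accuracy <- function(scores, outcomes, threshold = 0.5) {
  sens <- mean(scores[outcomes == 1] >= threshold)
  spec <- mean(scores[outcomes == 0] < threshold)
  (sens + spec) / 2
}

# AUROC by explicit positive/negative pair enumeration.
oracle_auroc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Average precision by looping over descending unique thresholds.
oracle_auprc <- function(scores, outcomes) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(outcomes == 1)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    called <- scores >= t
    tp <- sum(outcomes == 1 & called)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# Exact two-sided signed-rank p by full 2^n sign-flip enumeration.
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * mean(w_all <= w_obs + 1e-9))
}

# Small deterministic cohort used by several group/metric tests: two
# protected attributes with hand-set cell counts.
tiny_cohort <- function() {
  cells <- list(
    c(eth = "A", gender = "M", n = 9, rate = 0.2),
    c(eth = "A", gender = "F", n = 11, rate = 0.4),
    c(eth = "B", gender = "M", n = 40, rate = 0.5),
    c(eth = "B", gender = "F", n = 40, rate = 0.7)
  )
  rows <- do.call(rbind, lapply(cells, function(cl) {
    n <- as.integer(cl[["n"]])
    data.frame(eth = rep(cl[["eth"]], n), gender = rep(cl[["gender"]], n),
               admitted = rep(c(1L, 0L),
                              c(round(as.numeric(cl[["rate"]]) * n),
                                n - round(as.numeric(cl[["rate"]]) * n))),
               stringsAsFactors = FALSE)
  }))
  tbl <- tibble::as_tibble(rows)
  attr(tbl, "protected") <- c("eth", "gender")
  tbl
}
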