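#' Configure a synthetic emergency-department visit cohort
#'
#' Describes a generative model for visit-level tabular data: categorical
#' protected attributes drawn from a joint distribution over their Cartesian
#' product, numeric/ordinal feature columns, and a binary admission outcome
#' drawn from a logistic model whose linear predictor combines feature
#' effects, per-level main-effect offsets, and per-intersection interaction
#' offsets (all on the log-odds scale). Interaction offsets are the handle
#' used to plant miscalibration specifically at intersections of protected
#' attributes, which is what makes marginal debiasing insufficient by
#' construction.
#'
#' @param n_visits Number of visit rows to generate (non-negative integer).
#' @param attribute_levels Named list: protected attribute name -> character
#'   vector of category labels.
#' @param attribute_joint_probs Numeric vector of cell probabilities over the
#'   Cartesian product of attribute levels, in the row order of
#'   `expand.grid(attribute_levels)`. Must be non-negative and sum to 1
#'   (tolerance 1e-9). If `NULL`, attributes are drawn independently requires
#'   `attribute_marginals`.
#' @param attribute_marginals Named list of per-attribute marginal probability
#'   vectors; used to build an independence joint when
#'   `attribute_joint_probs` is `NULL`.
#' @param features List of feature specifications, each a list with `name`,
#'   `family` (one of `"normal"`, `"lognormal"`, `"ordinal"`), and family
#'   parameters (`mean`/`sd`, `meanlog`/`sdlog`, or `values`/`probs`).
#' @param outcome List with `intercept` (log-odds), `coef` (named numeric,
#'   one entry per feature used), `main_effects` (named list: attribute ->
#'   named numeric of per-level log-odds offsets), and `interactions` (named
#'   numeric keyed by canonical cell label, see [cell_label()]).
#' @param seed Master integer seed. Attributes, each feature, and outcomes
#'   use independent derived substreams, so the first m rows are identical
#'   for any `n_visits >= m`.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [cohort_preset()]
#' @export
cohort_config <- function(n_visits,
                          attribute_levels,
                          attribute_joint_probs = NULL,
                          attribute_marginals = NULL,
                          features = list(),
                          outcome = list(intercept = 0, coef = numeric(0),
                                         main_effects = list(),
                                         interactions = numeric(0)),
                          seed = 1L) {
  if (length(n_visits) != 1L || is.na(n_visits) || n_visits < 0) {
    stopf("`n_visits` must be a single non-negative integer")
  }
  if (!is.list(attribute_levels) || is.null(names(attribute_levels)) ||
      any(!nzchar(names(attribute_levels)))) {
    stopf("`attribute_levels` must be a named list of level vectors")
  }
  if (is.null(attribute_joint_probs)) {
    if (is.null(attribute_marginals)) {
      stopf("supply `attribute_joint_probs` or `attribute_marginals`")
    }
    if (!setequal(names(attribute_marginals), names(attribute_levels))) {
      stopf("`attribute_marginals` must name the same attributes as `attribute_levels`")
    }
    marg <- attribute_marginals[names(attribute_levels)]
    grid <- expand.grid(lapply(attribute_levels, seq_along),
                        KEEP.OUT.ATTRS = FALSE)
    attribute_joint_probs <- Reduce(`*`, lapply(names(marg), function(a) {
      marg[[a]][grid[[a]]]
    }))
  }
  n_cells <- prod(vapply(attribute_levels, length, integer(1)))
  if (length(attribute_joint_probs) != n_cells) {
    stopf("`attribute_joint_probs` has length %d but the attribute grid has %d cells",
          length(attribute_joint_probs), n_cells)
  }
  if (any(attribute_joint_probs < 0)) {
    stopf("`attribute_joint_probs` must be non-negative")
  }
  if (abs(sum(attribute_joint_probs) - 1) > 1e-9) {
    stopf("`attribute_joint_probs` must sum to 1 (got %.12f)",
          sum(attribute_joint_probs))
  }
  for (f in features) {
    if (is.null(f$name) || is.null(f$family)) {
      stopf("each feature spec needs `name` and `family`")
    }
    if (!f$family %in% c("normal", "lognormal", "ordinal")) {
      stopf("unknown distribution family '%s' for feature '%s'",
            f$family, f$name)
    }
  }
  outcome$coef <- outcome$coef %||% numeric(0)
  outcome$main_effects <- outcome$main_effects %||% list()
  outcome$interactions <- outcome$interactions %||% numeric(0)
  feat_names <- vapply(features, `[[`, character(1), "name")
  if (length(outcome$coef) && !all(names(outcome$coef) %in% feat_names)) {
    stopf("outcome `coef` names a feature that is not in `features`")
  }
  for (a in names(outcome$main_effects)) {
    if (!a %in% names(attribute_levels)) {
      stopf("main effect for unknown attribute '%s'", a)
    }
    bad <- setdiff(names(outcome$main_effects[[a]]), attribute_levels[[a]])
    if (length(bad)) {
      stopf("main effect for unknown level '%s' of '%s'", bad[1], a)
    }
  }
  valid_cells <- all_cell_labels(attribute_levels)
  if (length(outcome$interactions)) {
    bad <- setdiff(names(outcome$interactions), valid_cells)
    if (length(bad)) {
      stopf("interaction offset indexes nonexistent cell '%s'", bad[1])
    }
  }
  structure(
    list(n_visits = as.integer(n_visits),
         attribute_levels = attribute_levels,
         attribute_joint_probs = attribute_joint_probs,
         features = features,
         outcome = outcome,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Canonical label for an intersectional cell
#'
#' Attribute names are sorted alphabetically and joined as
#' `"attr=level; attr=level"`. Canonical labels give deterministic group
#' ordering across trials and are the keys for interaction offsets and
#' per-cell score shifts.
#'
#' @param constraints Named character vector: attribute -> level.
#' @return A single string.
#' @export
cell_label <- function(constraints) {
  ord <- order(names(constraints))
  paste(sprintf("%s=%s", names(constraints)[ord], unname(constraints)[ord]),
        collapse = "; ")
}

# All canonical cell labels of the attribute grid, in expand.grid row order.
all_cell_labels <- function(attribute_levels) {
  grid <- expand.grid(attribute_levels, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  vapply(seq_len(nrow(grid)), function(i) {
    cell_label(vapply(grid[i, , drop = FALSE], as.character, character(1)))
  }, character(1))
}

#' Generate a synthetic visit cohort
#'
#' Draws `n_visits` independent visit rows from a [cohort_config()]:
#' protected-attribute cells from the joint distribution, features from their
#' stated families, and a binary `admitted` outcome from
#' `Bernoulli(plogis(linear predictor))`. The logistic probability itself is
#' stored as `true_risk`, giving downstream tests a perfectly calibrated
#' scoring oracle. Identical `(config, seed)` yields an identical table.
#'
#' @param config A `cohort_config`.
#' @return A tibble with one row per visit: feature columns, protected
#'   attribute columns (character), `admitted` (0/1), and `true_risk`.
#'   Protected attribute names are recorded in `attr(, "protected")`.
#' @examples
#' cfg <- cohort_preset("adult_ed", n_visits = 500, seed = 1)
#' cohort <- generate_cohort(cfg)
#' mean(cohort$admitted)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stopf("`config` must be a cohort_config")
  }
  n <- config$n_visits
  attrs <- config$attribute_levels
  grid <- expand.grid(attrs, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  cell_idx <- with_seed(substream_seed(config$seed, "attributes"),
                        draw_categorical(n, config$attribute_joint_probs))
  out <- list()
  for (f in config$features) {
    s <- substream_seed(config$seed, paste0("feature:", f$name))
    out[[f$name]] <- with_seed(s, switch(
      f$family,
      normal    = stats::rnorm(n, f$mean %||% 0, f$sd %||% 1),
      lognormal = stats::rlnorm(n, f$meanlog %||% 0, f$sdlog %||% 1),
      ordinal   = {
        vals <- f$values %||% seq_along(f$probs)
        vals[draw_categorical(n, f$probs)]
      }
    ))
  }
  for (a in names(attrs)) {
    out[[a]] <- as.character(grid[[a]][cell_idx])
  }

  lp <- rep(config$outcome$intercept %||% 0, n)
  for (nm in names(config$outcome$coef)) {
    lp <- lp + config$outcome$coef[[nm]] * out[[nm]]
  }
  for (a in names(config$outcome$main_effects)) {
    eff <- config$outcome$main_effects[[a]]
    hit <- match(out[[a]], names(eff))
    lp <- lp + ifelse(is.na(hit), 0, eff[hit])
  }
  if (length(config$outcome$interactions)) {
    labels <- all_cell_labels(attrs)[cell_idx]
    hit <- match(labels, names(config$outcome$interactions))
    lp <- lp + ifelse(is.na(hit), 0, config$outcome$interactions[hit])
  }
  risk <- logistic(lp)
  y <- with_seed(substream_seed(config$seed, "outcome"),
                 as.integer(stats::runif(n) < risk))
  if (n == 0L) {
    y <- integer(0)
    risk <- numeric(0)
  }
  out$admitted <- y
  out$true_risk <- risk
  tbl <- tibble::as_tibble(out)
  attr(tbl, "protected") <- names(attrs)
  tbl
}

#' Protected attribute names declared on a cohort
#' @param data A cohort tibble produced by [generate_cohort()] or
#'   [read_cohort()].
#' @return Character vector of protected attribute column names.
#' @export
protected_attributes <- function(data) {
  p <- attr(data, "protected")
  if (is.null(p)) stopf("no protected attributes declared on this table")
  p
}

#' Shift risk scores inside chosen subgroups
#'
#' Adds a known offset to every score whose record belongs to a given group
#' of `collection`, clipping the result to `[0, 1]`. Used to plant per-cell
#' miscalibration with a known magnitude so that repairs can be verified
#' against a planted truth. Records in no listed cell are untouched.
#'
#' @param scores Numeric vector of probabilities.
#' @param collection A [group_collection] covering the same records.
#' @param cell_shifts Named numeric vector: group label -> additive offset.
#' @param seed Unused; accepted so perturbations slot into seeded pipelines.
#' @return The shifted, clipped score vector.
#' @export
perturb_scores <- function(scores, collection, cell_shifts, seed = NULL) {
  stopifnot(is.numeric(scores))
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    stopf("`scores` must lie in [0, 1]")
  }
  bad <- setdiff(names(cell_shifts), collection$labels)
  if (length(bad)) {
    stopf("cell_shifts names unknown group '%s'", bad[1])
  }
  out <- scores
  for (lab in names(cell_shifts)) {
    m <- collection$membership[, lab]
    out[m] <- out[m] + cell_shifts[[lab]]
  }
  out <- clip01(out)
  if (length(out) > 1 && length(unique(out)) == 1L) {
    message("perturb_scores: shifts produced all-identical scores")
  }
  out
}

#' Write / read a cohort table
#'
#' Cohorts are exchanged as UTF-8 CSV with a header row; the protected
#' attribute list travels in a JSON sidecar (`<path>.meta.json`) and is
#' restored on read. `protected` may also be given explicitly on read, e.g.
#' for externally produced files.
#'
#' @param data Cohort tibble.
#' @param path File path ending in `.csv`.
#' @param protected Optional character vector of protected attribute columns.
#' @return `read_cohort()` returns a cohort tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, fileEncoding = "UTF-8")
  meta <- list(protected = attr(data, "protected"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, protected = NULL) {
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                           fileEncoding = "UTF-8"))
  if (is.null(protected)) {
    meta_path <- paste0(path, ".meta.json")
    if (file.exists(meta_path)) {
      protected <- unlist(jsonlite::read_json(meta_path)$protected)
    }
  }
  if (is.null(protected)) stopf("no protected attribute declaration found")
  missing <- setdiff(protected, names(tbl))
  if (length(missing)) stopf("protected attribute '%s' not in file", missing[1])
  attr(tbl, "protected") <- protected
  tbl
}
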