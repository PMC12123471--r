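#' Build the collection of protected subgroups for a debiasing scenario
#'
#' Constructs the collection C of patient subgroups used both as the
#' debiasing handle (which cells a calibrator repairs, which groups a
#' reweighting genome indexes) and as the evaluation axis (per-group
#' metrics). Scenarios:
#'
#' * `"base"` - empty collection (no fairness constraint);
#' * `"single:<attr>"` - one group per observed level of one protected
#'   attribute;
#' * `"marginal"` - the union of all `single:<attr>` collections;
#' * `"intersectional"` - one group per observed cell of the Cartesian
#'   product of all protected attributes (unobserved cells are omitted, so
#'   nonempty groups partition the records).
#'
#' Group labels are canonical `"attr=level"` / `"attr=level; attr=level"`
#' strings sorted lexicographically, so group ordering is deterministic
#' across trials and serializations.
#'
#' @param data Cohort tibble.
#' @param protected Character vector of protected attribute column names;
#'   defaults to the cohort's declared attributes.
#' @param scenario Scenario tag.
#' @return An object of class `group_collection`: list with `scenario`,
#'   `labels`, `groups` (list of named constraint vectors), `membership`
#'   (logical record-by-group matrix), `prevalence` (named fractions), `n`.
#' @examples
#' cohort <- generate_cohort(cohort_preset("adult_ed", 1000, seed = 3))
#' build_collection(cohort, scenario = "intersectional")
#' @export
build_collection <- function(data,
                             protected = protected_attributes(data),
                             scenario = c("base", "marginal", "intersectional",
                                          "single")) {
  scen <- scenario[1]
  single_attr <- NULL
  if (startsWith(scen, "single:")) {
    single_attr <- sub("^single:", "", scen)
    scen <- "single"
  } else {
    scen <- match.arg(scenario)
    if (scen == "single") stopf("scenario 'single' needs an attribute: 'single:<attr>'")
  }
  missing <- setdiff(protected, names(data))
  if (length(missing)) stopf("unknown protected attribute '%s'", missing[1])
  if (!is.null(single_attr) && !single_attr %in% protected) {
    stopf("'%s' is not a declared protected attribute", single_attr)
  }
  n <- nrow(data)

  groups <- list()
  if (scen == "single") {
    for (lvl in sort(unique(data[[single_attr]]))) {
      groups[[length(groups) + 1L]] <- stats::setNames(lvl, single_attr)
    }
  } else if (scen == "marginal") {
    for (a in sort(protected)) {
      for (lvl in sort(unique(data[[a]]))) {
        groups[[length(groups) + 1L]] <- stats::setNames(lvl, a)
      }
    }
  } else if (scen == "intersectional") {
    cells <- unique(data[, sort(protected), drop = FALSE])
    for (i in seq_len(nrow(cells))) {
      groups[[length(groups) + 1L]] <-
        vapply(cells[i, , drop = FALSE], as.character, character(1))
    }
  }

  labels <- vapply(groups, cell_label, character(1))
  ord <- order(labels)
  groups <- groups[ord]
  labels <- labels[ord]

  membership <- matrix(FALSE, nrow = n, ncol = length(groups),
                       dimnames = list(NULL, labels))
  for (j in seq_along(groups)) {
    g <- groups[[j]]
    m <- rep(TRUE, n)
    for (a in names(g)) m <- m & (data[[a]] == g[[a]])
    membership[, j] <- m
  }
  scenario_tag <- if (scen == "single") paste0("single:", single_attr) else scen
  new_group_collection(scenario_tag, groups, labels, membership, n)
}

new_group_collection <- function(scenario, groups, labels, membership, n) {
  prevalence <- if (length(labels)) colSums(membership) / max(n, 1L) else numeric(0)
  names(prevalence) <- labels
  structure(
    list(scenario = scenario, groups = groups, labels = labels,
         membership = membership, prevalence = prevalence, n = n),
    class = "group_collection"
  )
}

#' @exportS3Method base::print
print.group_collection <- function(x, ...) {
  cat(sprintf("<group_collection> scenario=%s, %d groups over %d records\n",
              x$scenario, length(x$labels), x$n))
  if (length(x$labels)) {
    show <- utils::head(order(-x$prevalence), 10)
    for (j in show) {
      cat(sprintf("  %-45s %6.2f%%\n", x$labels[j], 100 * x$prevalence[j]))
    }
    if (length(x$labels) > 10) cat(sprintf("  ... %d more\n", length(x$labels) - 10))
  }
  invisible(x)
}

#' Drop subgroups below a prevalence cutoff
#'
#' Retains exactly the groups whose sample prevalence (members / total
#' records) is at least `gamma`. The cutoff prevents calibrators and
#' worst-case objectives from overfitting to very small groups.
#'
#' @param collection A `group_collection`.
#' @param gamma Prevalence cutoff in `[0, 1]`.
#' @return A filtered `group_collection`.
#' @export
prevalence_filter <- function(collection, gamma) {
  stopifnot(inherits(collection, "group_collection"))
  if (length(gamma) != 1L || is.na(gamma) || gamma < 0 || gamma > 1) {
    stopf("`gamma` must be a single value in [0, 1]")
  }
  keep <- collection$prevalence >= gamma
  new_group_collection(
    collection$scenario,
    collection$groups[keep],
    collection$labels[keep],
    collection$membership[, keep, drop = FALSE],
    collection$n
  )
}

# Rebuild a collection's membership on a different set of records (e.g. a
# test split): same group definitions, membership recomputed from the data.
collection_on <- function(collection, data) {
  membership <- matrix(FALSE, nrow = nrow(data), ncol = length(collection$groups),
                       dimnames = list(NULL, collection$labels))
  for (j in seq_along(collection$groups)) {
    g <- collection$groups[[j]]
    m <- rep(TRUE, nrow(data))
    for (a in names(g)) m <- m & (data[[a]] == g[[a]])
    membership[, j] <- m
  }
  new_group_collection(collection$scenario, collection$groups,
                       collection$labels, membership, nrow(data))
}

# Subset a collection's membership rows (e.g. train/test indices).
collection_subset <- function(collection, idx) {
  new_group_collection(collection$scenario, collection$groups,
                       collection$labels,
                       collection$membership[idx, , drop = FALSE],
                       length(idx))
}

#' Serialize a group collection to JSON
#'
#' Writes scenario, group labels, constraints and prevalences (not the
#' membership matrix) for audit trails.
#'
#' @param collection A `group_collection`.
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @export
collection_to_json <- function(collection, path = NULL) {
  obj <- list(
    scenario = collection$scenario,
    n_records = collection$n,
    groups = lapply(seq_along(collection$groups), function(j) {
      list(label = collection$labels[j],
           constraints = as.list(collection$groups[[j]]),
           prevalence = unname(collection$prevalence[j]))
    })
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
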