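# Measurement aggregation and subpopulation construction: concept scores
# as the mean of their unipolar items with a cap on the missing-item
# fraction, subgroup subsetting that removes the moderating factor from
# the model, and exclusion of variables left unobserved in a subset.
# Nothing here imputes; missingness is preserved for the learner.

#' Aggregate item responses into a concept score
#'
#' The concept score is the mean of the observed items, provided at most
#' `max_missing_fraction` of the items are missing (the boundary is
#' inclusive: exactly 25% missing still yields a score under the default);
#' otherwise the score is missing.
#'
#' @param items numeric vector of item values, `NA` for missing.
#' @param max_missing_fraction maximum tolerated missing fraction in
#'   `[0, 1)`; default 0.25.
#' @return the concept score, or `NA`.
#' @export
aggregate_concept <- function(items, max_missing_fraction = 0.25) {
  if (length(items) == 0L) stop("empty item list")
  stopifnot(max_missing_fraction >= 0, max_missing_fraction < 1)
  frac <- mean(is.na(items))
  if (frac > max_missing_fraction) return(NA_real_)
  mean(items, na.rm = TRUE)
}

#' Aggregate an item table into a concept-level panel dataset
#'
#' Item columns follow the `concept@wave#k` naming convention; any column
#' without `#` is passed through unchanged (demographics, intervention,
#' outcomes that are not item-based).
#'
#' @param items data.frame of item responses plus pass-through columns.
#' @param specs [variable_spec()] table of the concept-level variables.
#' @param max_missing_fraction forwarded to [aggregate_concept()].
#' @return a [panel_dataset()] at concept level.
#' @export
aggregate_items <- function(items, specs, max_missing_fraction = 0.25) {
  item_cols <- grep("#", names(items), fixed = TRUE, value = TRUE)
  concept_of <- sub("#.*$", "", item_cols)
  rec <- items[setdiff(names(items), item_cols)]
  for (cn in unique(concept_of)) {
    block <- as.matrix(items[item_cols[concept_of == cn]])
    rec[[cn]] <- apply(block, 1, aggregate_concept, max_missing_fraction)
  }
  rec <- rec[intersect(specs$name, names(rec))]
  panel_dataset(rec, specs, provenance = sprintf(
    "aggregated %d item columns into %d concepts (max missing %.0f%%)",
    length(item_cols), length(unique(concept_of)), 100 * max_missing_fraction))
}

#' Subset the panel to one level of a moderating factor
#'
#' Rows are filtered by the predicate on the factor, rows with a missing
#' factor value are dropped, and the factor column itself is removed from
#' the model variables (it is constant within the subset); the remaining
#' demographics stay in as correction covariates.
#'
#' @param dataset a [panel_dataset()].
#' @param factor_var name of a demographic variable in the specs.
#' @param levels character vector of levels to keep (discrete factors);
#'   several levels act as a merged category.
#' @param rule numeric threshold rule such as `"<65"` or `">=65"` for
#'   continuous factors (used when `levels` is `NULL`).
#' @return a [panel_dataset()] for the subpopulation.
#' @export
subset_subpopulation <- function(dataset, factor_var, levels = NULL, rule = NULL) {
  specs <- dataset$specs
  if (!factor_var %in% specs$name) stop("unknown factor: ", factor_var)
  if (specs$role[match(factor_var, specs$name)] != "demographic")
    stop(factor_var, " is not a demographic variable")
  x <- dataset$records[[factor_var]]
  if (!is.null(levels)) {
    keep <- !is.na(x) & as.character(x) %in% levels
    desc <- paste(levels, collapse = "|")
  } else if (!is.null(rule)) {
    m <- regmatches(rule, regexec("^\\s*(<=|>=|<|>)\\s*([0-9.]+)\\s*$", rule))[[1]]
    if (length(m) != 3L) stop("cannot parse rule: ", rule)
    thr <- as.numeric(m[3])
    keep <- !is.na(x) & switch(m[2], "<" = x < thr, "<=" = x <= thr,
                               ">" = x > thr, ">=" = x >= thr)
    desc <- rule
  } else stop("give either levels or rule")
  if (!any(keep)) warning("predicate on ", factor_var, " matches no participant")
  rec <- dataset$records[keep, setdiff(names(dataset$records), factor_var),
                         drop = FALSE]
  out <- panel_dataset(rec, specs[specs$name != factor_var, , drop = FALSE],
                       dataset$provenance)
  log_step(out, sprintf("subset %s %s: %d of %d participants kept, factor removed",
                        factor_var, desc, sum(keep), length(keep)))
}

#' Drop variables with too few observations in a subset
#'
#' Taking a subpopulation subset can leave variables with no (or almost
#' no) observed values; those are removed before learning. With
#' `min_observed = 1` only completely unobserved variables are dropped.
#'
#' @param dataset a [panel_dataset()].
#' @param min_observed minimum observed cells a column needs to stay
#'   (default 30; learning needs non-degenerate locals).
#' @return list with `dataset` (pruned) and `dropped` (removed names).
#' @export
drop_unobserved_variables <- function(dataset, min_observed = 30L) {
  stopifnot(min_observed >= 1)
  nobs <- colSums(dataset$mask)
  drop <- names(nobs)[nobs < min_observed]
  keep <- setdiff(names(dataset$records), drop)
  out <- panel_dataset(dataset$records[keep],
                       dataset$specs[dataset$specs$name %in% keep, , drop = FALSE],
                       dataset$provenance)
  if (length(drop))
    out <- log_step(out, sprintf("dropped %d under-observed variable(s) (< %d obs): %s",
                                 length(drop), min_observed,
                                 paste(drop, collapse = ", ")))
  list(dataset = out, dropped = drop)
}
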