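# End-to-end subgroup analysis: for each level of a moderating factor,
# subset and prune the panel, pick the bootstrap count, learn the averaged
# network, grade it, distill the intervention-to-outcome fragment, then
# compare the two fragments.

#' Run configuration for a subgroup comparison
#'
#' @param moderator demographic variable defining the subpopulations.
#' @param level_a,level_b level sets (character vectors) or threshold
#'   rules (strings such as `"<65"`) selecting the two subgroups.
#' @param source intervention variable name.
#' @param targets outcome variables (short- and long-term PA outcomes).
#' @param settings a [search_settings()].
#' @param B fixed bootstrap count, used when `B_grid` is `NULL`.
#' @param B_grid optional increasing grid for [stability_select_B()].
#' @param threshold averaging confidence threshold (default 0.6).
#' @param min_observed observation floor for [drop_unobserved_variables()].
#' @param seed master seed.
#' @param out_dir optional directory for the report bundle.
#' @return list of class `run_config`.
#' @export
run_config <- function(moderator, level_a, level_b, source, targets,
                       settings = search_settings(), B = 100L, B_grid = NULL,
                       threshold = 0.6, min_observed = 30L, seed = 1L,
                       out_dir = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  structure(list(moderator = moderator, level_a = level_a, level_b = level_b,
                 source = source, targets = targets, settings = settings,
                 B = as.integer(B), B_grid = B_grid, threshold = threshold,
                 min_observed = as.integer(min_observed),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

subset_by_spec <- function(dataset, moderator, level_spec) {
  if (is.character(level_spec) &&
      length(level_spec) == 1L && grepl("^\\s*(<|>|<=|>=)", level_spec))
    subset_subpopulation(dataset, moderator, rule = level_spec)
  else
    subset_subpopulation(dataset, moderator, levels = level_spec)
}

analyze_level <- function(dataset, config, level_spec, level_tag, seed_offset) {
  stage <- "subset"
  out <- tryCatch({
    sub <- subset_by_spec(dataset, config$moderator, level_spec)
    stage <- "drop_unobserved"
    pruned <- drop_unobserved_variables(sub, config$min_observed)
    sub <- pruned$dataset
    stage <- "constraint"
    constraint <- tiers_from_specs(sub$specs)
    seed <- derive_seed(config$seed, seed_offset)
    stage <- "bootstrap"
    if (!is.null(config$B_grid)) {
      sel <- stability_select_B(sub, constraint, config$settings,
                                B_grid = config$B_grid,
                                threshold = config$threshold, seed = seed)
      chosen_B <- sel$chosen_B
      structures <- sel$structures[seq_len(chosen_B)]
      curve <- sel$curve
    } else {
      structures <- bootstrap_structures(sub, constraint, config$settings,
                                         B = config$B, seed = seed)
      chosen_B <- config$B
      curve <- NULL
    }
    stage <- "average"
    avg <- average_network(structures, config$threshold)
    stage <- "grade/extract"
    frag <- extract_fragment(avg, config$source,
                             intersect(config$targets, avg$nodes),
                             dataset = sub)
    list(tag = level_tag, dataset = sub, dropped = pruned$dropped,
         constraint = constraint, chosen_B = chosen_B,
         stability_curve = curve, network = avg, fragment = frag,
         seed = seed)
  }, error = function(e) {
    stop("subgroup analysis failed at stage '", stage, "' for level ",
         level_tag, ": ", conditionMessage(e), call. = FALSE)
  })
  out
}

write_level_outputs <- function(level, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  conf <- level$network$confidence
  utils::write.csv(conf, file.path(dir, "arc_confidence.csv"), row.names = FALSE)
  utils::write.csv(level$network$arcs, file.path(dir, "averaged_arcs.csv"),
                   row.names = FALSE)
  utils::write.csv(level$network$undirected,
                   file.path(dir, "averaged_undirected.csv"), row.names = FALSE)
  ann <- level$fragment$annotations
  if (!is.null(ann))
    utils::write.csv(as.data.frame(ann), file.path(dir, "fragment_edges.csv"),
                     row.names = FALSE)
  if (!is.null(level$stability_curve))
    utils::write.csv(level$stability_curve, file.path(dir, "stability_curve.csv"),
                     row.names = FALSE)
  to_dot(level$fragment, path = file.path(dir, "fragment.dot"))
  writeLines(level$dataset$provenance, file.path(dir, "provenance.log"))
}

#' Run the full subgroup comparison analysis
#'
#' For each of the two moderator levels: subset the panel (dropping the
#' moderator from the model), remove unobserved variables, select or fix
#' the bootstrap count, learn bootstrap networks by structural EM, average
#' them at the confidence threshold, grade the retained edges, and distill
#' the intervention-to-outcome fragment; finally compare the two
#' fragments. When `config$out_dir` is set, all intermediates are written
#' there (arc-list and confidence CSVs, DOT renderings, stability curves,
#' the diff, and a manifest of seeds and settings).
#'
#' @param dataset a [panel_dataset()] holding both subgroups.
#' @param config a [run_config()].
#' @return list of class `subgroup_analysis` with `level_a`, `level_b`,
#'   `diff`, and `manifest`.
#' @export
run_subgroup_analysis <- function(dataset, config) {
  a <- analyze_level(dataset, config, config$level_a, "A", 1L)
  b <- analyze_level(dataset, config, config$level_b, "B", 2L)
  diff <- compare_fragments(a$fragment, b$fragment)
  manifest <- list(
    package_version = as.character(utils::packageVersion("panelbn")),
    seed = config$seed, level_seeds = c(A = a$seed, B = b$seed),
    moderator = config$moderator,
    level_a = config$level_a, level_b = config$level_b,
    threshold = config$threshold,
    B = c(A = a$chosen_B, B = b$chosen_B),
    settings = unclass(config$settings))
  out <- structure(list(level_a = a, level_b = b, diff = diff,
                        manifest = manifest),
                   class = "subgroup_analysis")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_level_outputs(a, file.path(config$out_dir, "level_a"))
    write_level_outputs(b, file.path(config$out_dir, "level_b"))
    dd <- rbind(
      if (nrow(diff$only_a)) cbind(diff$only_a, side = "A"),
      if (nrow(diff$only_b)) cbind(diff$only_b, side = "B"))
    utils::write.csv(dd %||% data.frame(),
                     file.path(config$out_dir, "diff_edges.csv"),
                     row.names = FALSE)
    utils::write.csv(diff$role_transitions,
                     file.path(config$out_dir, "role_transitions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.subgroup_analysis <- function(x, ...) {
  cat("subgroup_analysis of", x$manifest$moderator, "\n")
  cat(" level A: B =", x$level_a$chosen_B, ";",
      nrow(x$level_a$fragment$edges), "fragment edges\n")
  cat(" level B: B =", x$level_b$chosen_B, ";",
      nrow(x$level_b$fragment$edges), "fragment edges\n")
  print(x$diff)
  invisible(x)
}
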