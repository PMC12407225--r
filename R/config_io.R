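# YAML round-trip for synthetic-study configurations, so a run is fully
# described by one plain-text document.

arcs_to_list <- function(m) lapply(seq_len(NROW(m)), function(i) as.list(m[i, ]))

arcs_from_list <- function(l) {
  if (!length(l)) return(NULL)
  do.call(rbind, lapply(l, function(p) c(p[[1]], p[[2]])))
}

#' Write a synthetic configuration as YAML
#'
#' @param config a [synthetic_config()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
config_to_yaml <- function(config, path) {
  specs <- config$specs
  net <- config$network
  doc <- list(
    n_participants = config$n_participants,
    seed = config$seed,
    waves = config$waves,
    variables = lapply(seq_len(nrow(specs)), function(i) {
      v <- list(name = specs$name[i], timeslot = specs$timeslot[i],
                kind = specs$kind[i], role = specs$role[i])
      if (!is.null(specs$levels[[i]])) v$levels <- specs$levels[[i]]
      v
    }),
    network = list(
      arcs = arcs_to_list(net$arcs),
      coef = lapply(seq_len(NROW(net$coef)), function(i)
        list(from = net$coef$from[i], to = net$coef$to[i],
             value = net$coef$value[i])),
      intercept = as.list(net$intercept),
      sigma = as.list(net$sigma),
      cpt = lapply(net$cpt, function(m) {
        if (is.null(dim(m))) list(as.numeric(m))
        else lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
      }),
      config_intercept = lapply(net$config_intercept, as.numeric),
      config_sigma = lapply(net$config_sigma, as.numeric),
      trunc = lapply(net$trunc, function(m) {
        if (is.null(dim(m))) list(as.numeric(m))
        else lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
      })),
    concepts = if (!is.null(config$concepts)) as.list(config$concepts),
    moderator_effects = lapply(config$moderator_effects, function(levels)
      lapply(levels, function(e) list(
        remove_arcs = arcs_to_list(e$remove_arcs),
        add_arcs = arcs_to_list(e$add_arcs),
        coef = if (!is.null(e$coef)) as.list(e$coef)))),
    missing_item_rate = config$missing_item_rate,
    item_noise_sd = config$item_noise_sd,
    missing_cell_rate = config$missing_cell_rate,
    missing_wave_pattern = lapply(config$missing_wave_pattern, as.integer),
    study_mix = config$study_mix,
    study_var = config$study_var)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a synthetic configuration from YAML
#'
#' @param path a file written by [config_to_yaml()] (or hand-authored in
#'   the same schema).
#' @return a [synthetic_config()].
#' @export
config_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  specs <- variable_spec(
    name = vapply(doc$variables, `[[`, character(1), "name"),
    timeslot = vapply(doc$variables, `[[`, character(1), "timeslot"),
    kind = vapply(doc$variables, `[[`, character(1), "kind"),
    role = vapply(doc$variables, `[[`, character(1), "role"),
    levels = lapply(doc$variables, function(v)
      if (!is.null(v$levels)) as.character(v$levels) else NULL))
  nt <- doc$network
  mat_or_vec <- function(rows) {
    if (is.null(rows)) return(NULL)
    if (length(rows) == 1L) unlist(rows[[1]])
    else do.call(rbind, lapply(rows, unlist))
  }
  network <- list(
    arcs = arcs_from_list(nt$arcs),
    coef = if (length(nt$coef)) do.call(rbind, lapply(nt$coef, function(x)
      coef_row(x$from, x$to, as.numeric(x$value)))),
    intercept = unlist(nt$intercept),
    sigma = unlist(nt$sigma),
    cpt = lapply(nt$cpt, mat_or_vec),
    config_intercept = lapply(nt$config_intercept, unlist),
    config_sigma = lapply(nt$config_sigma, unlist),
    trunc = lapply(nt$trunc, mat_or_vec))
  concepts <- if (!is.null(doc$concepts))
    data.frame(name = unlist(doc$concepts$name),
               items_per_concept = as.integer(unlist(doc$concepts$items_per_concept)),
               scale_max = as.integer(unlist(doc$concepts$scale_max)),
               stringsAsFactors = FALSE)
  mods <- lapply(doc$moderator_effects, function(levels)
    lapply(levels, function(e) list(
      remove_arcs = arcs_from_list(e$remove_arcs),
      add_arcs = arcs_from_list(e$add_arcs),
      coef = if (!is.null(e$coef))
        data.frame(from = unlist(e$coef$from), to = unlist(e$coef$to),
                   value = as.numeric(unlist(e$coef$value)),
                   stringsAsFactors = FALSE))))
  synthetic_config(
    n_participants = doc$n_participants, seed = doc$seed,
    waves = unlist(doc$waves), specs = specs, network = network,
    concepts = concepts, moderator_effects = mods,
    missing_item_rate = doc$missing_item_rate %||% 0,
    item_noise_sd = doc$item_noise_sd %||% 0.5,
    missing_cell_rate = doc$missing_cell_rate %||% 0,
    missing_wave_pattern = lapply(doc$missing_wave_pattern, as.integer),
    study_mix = if (!is.null(doc$study_mix)) as.numeric(unlist(doc$study_mix)),
    study_var = doc$study_var)
}
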