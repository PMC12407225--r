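# Synthetic panel generator: a known ground-truth hybrid network over
# wave-stamped determinant/outcome variables plus static demographics,
# forward (ancestral) sampling, item-level rendering of concept scores,
# and study-driven structural missingness, so the whole analysis pipeline
# is testable against a known truth without any external data.

#' Synthetic study configuration
#'
#' Bundles everything the generator needs: the variable specification, a
#' ground-truth network recipe (arcs, coefficients, local parameters),
#' concept/item layout, missingness settings, the synthetic study mix with
#' its per-variable availability pattern, and optional moderator edits
#' that give demographic subgroups different ground-truth networks.
#'
#' @param n_participants default number of participants.
#' @param seed default integer seed.
#' @param waves wave labels in temporal order.
#' @param specs a [variable_spec()] table.
#' @param network ground-truth recipe: list with `arcs` (two-column
#'   matrix), `intercept` and `sigma` (named numerics for continuous
#'   nodes), `coef` (data.frame `from`, `to`, `value`; for a discrete
#'   parent the value is the additive shift per level step), `cpt` (named
#'   list for discrete nodes), and optionally `config_intercept`,
#'   `config_sigma`, `trunc` for per-configuration overrides and range
#'   clipping of generator-only statics such as age.
#' @param concepts data.frame `name`, `items_per_concept`, `scale_max`
#'   describing which continuous variables are item-aggregated scores.
#' @param moderator_effects named list: moderator variable -> list of
#'   level -> list(`remove_arcs`, `add_arcs`, `coef` overrides).
#' @param missing_item_rate probability an individual item is missing.
#' @param item_noise_sd SD of the Gaussian item noise around the concept
#'   score before rounding.
#' @param missing_cell_rate optional plain MCAR rate applied to
#'   determinant/outcome cells (simple fixtures; 0 disables).
#' @param missing_wave_pattern named list mapping variable name to the
#'   integer vector of studies in which it is measured (variables absent
#'   from the list are measured everywhere).
#' @param study_mix proportions over the synthetic studies (sum to 1);
#'   `NULL` for single-study configs.
#' @param study_var name of the study-index variable, if any.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants, seed = 1L,
                             waves = c("T0", "T1", "T2", "T3"),
                             specs, network, concepts = NULL,
                             moderator_effects = list(),
                             missing_item_rate = 0, item_noise_sd = 0.5,
                             missing_cell_rate = 0,
                             missing_wave_pattern = list(),
                             study_mix = NULL, study_var = NULL) {
  stopifnot(n_participants >= 1,
            missing_item_rate >= 0, missing_item_rate <= 1,
            missing_cell_rate >= 0, missing_cell_rate <= 1)
  if (!is.null(study_mix) && abs(sum(study_mix) - 1) > 1e-8)
    stop("study_mix proportions must sum to 1")
  bad <- setdiff(names(missing_wave_pattern), specs$name)
  if (length(bad))
    stop("missing_wave_pattern references unknown variable(s): ",
         paste(bad, collapse = ", "))
  cfg <- structure(list(n_participants = as.integer(n_participants),
                        seed = as.integer(seed), waves = waves, specs = specs,
                        network = network, concepts = concepts,
                        moderator_effects = moderator_effects,
                        missing_item_rate = missing_item_rate,
                        item_noise_sd = item_noise_sd,
                        missing_cell_rate = missing_cell_rate,
                        missing_wave_pattern = missing_wave_pattern,
                        study_mix = study_mix, study_var = study_var),
                   class = "synthetic_config")
  # fail fast on tier/cycle violations, for every moderator variant
  build_ground_truth(cfg)
  for (m in names(moderator_effects))
    for (lv in names(moderator_effects[[m]]))
      build_ground_truth(cfg, moderator = m, level = lv)
  cfg
}

apply_moderator_edits <- function(network, edits) {
  arcs <- network$arcs
  rm_ <- edits$remove_arcs
  for (i in seq_len(NROW(rm_))) {
    hit <- arcs[, 1] == rm_[i, 1] & arcs[, 2] == rm_[i, 2]
    if (!any(hit)) stop("moderator edit removes absent arc ",
                        rm_[i, 1], " -> ", rm_[i, 2])
    arcs <- arcs[!hit, , drop = FALSE]
  }
  if (NROW(edits$add_arcs)) arcs <- rbind(arcs, edits$add_arcs)
  network$arcs <- arcs
  for (i in seq_len(NROW(edits$coef))) {
    hit <- network$coef$from == edits$coef$from[i] &
      network$coef$to == edits$coef$to[i]
    if (any(hit)) network$coef$value[hit] <- edits$coef$value[i]
    else network$coef <- rbind(network$coef, edits$coef[i, ])
  }
  network
}

#' Build the parameterized ground-truth network from a configuration
#'
#' Validates tier consistency (no arc from a later wave into an earlier
#' one), acyclicity, the model-class rule, and that the intervention
#' variable is a root (randomized assignment), then assembles conditional
#' probability tables and per-configuration linear Gaussian locals.
#'
#' @param config a [synthetic_config()].
#' @param moderator,level optional moderator variable and level whose
#'   arc-set edits and coefficient overrides are applied.
#' @return a [hybrid_bn()].
#' @export
build_ground_truth <- function(config, moderator = NULL, level = NULL) {
  specs <- config$specs
  net <- config$network
  if (!is.null(moderator)) {
    edits <- config$moderator_effects[[moderator]][[level]]
    if (is.null(edits)) stop("no moderator edits for ", moderator, " = ", level)
    net <- apply_moderator_edits(net, edits)
  }
  arcs <- net$arcs
  if (is.null(arcs)) arcs <- matrix(character(), ncol = 2)
  wave_of <- function(v) specs$timeslot[match(v, specs$name)]
  widx <- function(w) ifelse(w == "static", 0L, match(w, config$waves))
  for (i in seq_len(nrow(arcs))) {
    wf <- widx(wave_of(arcs[i, 1])); wt <- widx(wave_of(arcs[i, 2]))
    if (wf > wt)
      stop("tier violation: arc ", arcs[i, 1], " -> ", arcs[i, 2],
           " runs against the time dimension")
  }
  iv <- specs$name[specs$role == "intervention"]
  if (length(iv) && any(arcs[, 2] %in% iv))
    stop("intervention variable must be a root (randomized assignment)")
  structure_ <- dag_structure(specs$name, arcs)  # errors on cycles
  params <- list()
  for (v in specs$name) {
    pa <- parents_of(structure_, v)
    dpar <- sort(pa[spec_kind(specs, pa) == "discrete"])
    cpar <- sort(pa[spec_kind(specs, pa) == "continuous"])
    if (spec_kind(specs, v) == "discrete") {
      if (length(cpar))
        stop("model-class violation: continuous parent ", cpar[1],
             " of discrete node ", v)
      lv <- spec_levels(specs, v)
      cpt <- net$cpt[[v]]
      if (is.null(cpt)) stop("no CPT for discrete node ", v)
      if (is.null(dim(cpt))) cpt <- matrix(cpt, nrow = 1)
      q <- prod(vapply(dpar, function(p) length(spec_levels(specs, p)), numeric(1)))
      if (nrow(cpt) != q || ncol(cpt) != length(lv))
        stop("CPT of ", v, " has wrong dimensions")
      if (any(abs(rowSums(cpt) - 1) > 1e-8)) stop("CPT rows of ", v, " must sum to 1")
      params[[v]] <- list(type = "discrete", dparents = dpar,
                          cparents = character(), cpt = cpt, levels = lv)
    } else {
      q <- if (length(dpar))
        prod(vapply(dpar, function(p) length(spec_levels(specs, p)), numeric(1)))
      else 1L
      base_int <- net$intercept[[v]] %||% 0
      sig <- net$sigma[[v]] %||% 1
      intercepts <- net$config_intercept[[v]] %||% {
        ic <- rep(base_int, q)
        # additive per-level shifts of discrete parents (radix order:
        # first parent fastest, matching config_index)
        if (length(dpar)) {
          mult <- 1L
          for (p in dpar) {
            np <- length(spec_levels(specs, p))
            shift <- net$coef$value[net$coef$from == p & net$coef$to == v]
            if (length(shift)) {
              lvl_idx <- ((seq_len(q) - 1L) %/% mult) %% np
              ic <- ic + shift[1] * lvl_idx
            }
            mult <- mult * np
          }
        }
        ic
      }
      sigmas <- net$config_sigma[[v]] %||% rep(sig, q)
      coef <- matrix(0, nrow = q, ncol = 1 + length(cpar),
                     dimnames = list(NULL, c("(Intercept)", cpar)))
      coef[, 1] <- intercepts
      for (p in cpar) {
        slope <- net$coef$value[net$coef$from == p & net$coef$to == v]
        if (!length(slope)) stop("no coefficient for arc ", p, " -> ", v)
        coef[, p] <- slope[1]
      }
      params[[v]] <- list(type = "gaussian", dparents = dpar, cparents = cpar,
                          coef = coef, sigma2 = sigmas^2,
                          fallback = rep(FALSE, q),
                          trunc = net$trunc[[v]])
    }
  }
  hybrid_bn(structure_, params, specs)
}

#' Forward-sample a panel from a parameterized network
#'
#' Ancestral sampling in topological order: discrete nodes from their CPT
#' rows, continuous nodes from their conditional Gaussians (clipped to a
#' node's `trunc` range when the generator recipe declares one, e.g. age
#' in years).
#'
#' @param bn a [hybrid_bn()].
#' @param n number of participants (>= 1).
#' @param seed integer seed; fixed seed gives identical tables.
#' @param given optional data.frame of pre-assigned columns (n rows);
#'   those variables are not re-sampled.
#' @return a complete [panel_dataset()].
#' @export
simulate_panel <- function(bn, n, seed = 1L, given = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be a positive integer")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  ord <- topological_order(bn$structure)
  rec <- as.data.frame(matrix(nrow = n, ncol = 0))
  if (!is.null(given)) {
    stopifnot(nrow(given) == n)
    rec <- as.data.frame(given, stringsAsFactors = FALSE)
  }
  for (v in ord) {
    if (v %in% names(rec)) next
    par <- bn$parameters[[v]]
    idx <- config_index_df(rec, bn$specs, par$dparents)
    if (par$type == "discrete") {
      lv <- par$levels
      val <- integer(n)
      for (g in unique(idx)) {
        rows <- which(idx == g)
        val[rows] <- sample.int(length(lv), length(rows), replace = TRUE,
                                prob = par$cpt[g, ])
      }
      rec[[v]] <- factor(lv[val], levels = lv)
    } else {
      mu <- par$coef[idx, 1]
      for (p in par$cparents)
        mu <- mu + par$coef[idx, p] * as.numeric(rec[[p]])
      x <- stats::rnorm(n, mu, sqrt(par$sigma2[idx]))
      tr <- par$trunc
      if (!is.null(tr)) {
        if (is.matrix(tr)) x <- pmin(pmax(x, tr[idx, 1]), tr[idx, 2])
        else x <- pmin(pmax(x, tr[1]), tr[2])
      }
      rec[[v]] <- x
    }
  }
  rec <- rec[bn$specs$name]
  panel_dataset(rec, bn$specs, provenance = sprintf(
    "simulated n=%d from ground truth (seed %d)", n, as.integer(seed)))
}

#' Generate the study panel, honoring moderator-specific ground truths
#'
#' Statics (demographics, study index, intervention) are sampled from the
#' base network; when the configuration carries moderator effects, the
#' wave variables of each subgroup are sampled from that subgroup's edited
#' network, conditional on the statics.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (default from the config).
#' @param n number of participants (default from the config).
#' @return a complete [panel_dataset()].
#' @export
generate_panel <- function(config, seed = config$seed, n = config$n_participants) {
  mods <- names(config$moderator_effects)
  if (length(mods) == 0L) {
    bn <- build_ground_truth(config)
    return(simulate_panel(bn, n, seed))
  }
  if (length(mods) > 1L)
    stop("at most one moderating factor may carry ground-truth edits")
  mod <- mods[[1]]
  bn0 <- build_ground_truth(config)
  statics <- config$specs$name[config$specs$timeslot == "static"]
  static_bn <- subnetwork(bn0, statics)
  base <- simulate_panel(static_bn, n, seed)
  rec <- base$records
  full <- NULL
  lv_all <- spec_levels(config$specs, mod)
  for (lv in lv_all) {
    rows <- which(as.character(rec[[mod]]) == lv)
    if (!length(rows)) next
    bn_lv <- if (lv %in% names(config$moderator_effects[[mod]]))
      build_ground_truth(config, moderator = mod, level = lv) else bn0
    sub <- simulate_panel(bn_lv, length(rows),
                          seed = derive_seed(seed, match(lv, lv_all)),
                          given = rec[rows, statics, drop = FALSE])
    part <- sub$records
    part$.row <- rows
    full <- rbind(full, part)
  }
  full <- full[order(full$.row), , drop = FALSE]
  full$.row <- NULL
  rownames(full) <- NULL
  panel_dataset(full, config$specs, provenance = sprintf(
    "simulated n=%d with moderator-specific truths on %s (seed %d)",
    n, mod, as.integer(seed)))
}

# restriction of a network to a set of nodes with no outside parents
subnetwork <- function(bn, nodes) {
  arcs <- bn$structure$arcs
  keep <- arcs[, 1] %in% nodes & arcs[, 2] %in% nodes
  if (any(arcs[, 2] %in% nodes & !keep))
    stop("subnetwork nodes have parents outside the set")
  st <- dag_structure(nodes, arcs[keep, , drop = FALSE])
  hybrid_bn(st, bn$parameters[nodes],
            bn$specs[bn$specs$name %in% nodes, , drop = FALSE])
}

#' Render concept scores as noisy ordinal items
#'
#' Each item equals the concept score plus independent Gaussian noise,
#' rounded half-up and clipped to `1..scale_max`; items go missing
#' independently at `missing_item_rate`. A missing concept score renders
#' all of its items missing. Non-concept columns pass through.
#'
#' @param dataset a [panel_dataset()] at concept level.
#' @param config a [synthetic_config()] with a `concepts` table.
#' @param seed integer seed.
#' @return data.frame of items (columns `concept@wave#k`) plus
#'   pass-through columns.
#' @export
render_items <- function(dataset, config, seed = 1L) {
  if (is.null(config$concepts)) stop("config has no concepts table")
  set.seed(as.integer(seed))
  rec <- dataset$records
  n <- nrow(rec)
  out <- rec[setdiff(names(rec), config$concepts$name)]
  for (ci in seq_len(nrow(config$concepts))) {
    cn <- config$concepts$name[ci]
    if (!cn %in% names(rec)) next
    k <- config$concepts$items_per_concept[ci]
    smax <- config$concepts$scale_max[ci]
    base <- as.numeric(rec[[cn]])
    for (j in seq_len(k)) {
      item <- base + stats::rnorm(n, 0, config$item_noise_sd)
      item <- pmin(pmax(floor(item + 0.5), 1), smax)  # round half-up, clip
      if (config$missing_item_rate > 0)
        item[stats::runif(n) < config$missing_item_rate] <- NA
      out[[paste0(cn, "#", j)]] <- item
    }
  }
  out
}

#' Blank variables wholesale for studies that never measured them
#'
#' Emulates the availability gaps of integrating several studies: for each
#' variable in the configuration's availability pattern, all values of
#' participants from studies not listed for it are discarded.
#'
#' @param dataset a [panel_dataset()] including the study-index column.
#' @param config a [synthetic_config()] with `missing_wave_pattern` and
#'   `study_var`.
#' @param seed unused for the deterministic pattern itself; kept for
#'   interface symmetry with the other injection steps.
#' @return the [panel_dataset()] with the pattern applied.
#' @export
inject_structural_missingness <- function(dataset, config, seed = 1L) {
  pat <- config$missing_wave_pattern
  if (!length(pat)) return(dataset)
  bad <- setdiff(names(pat), names(dataset$records))
  if (length(bad)) stop("pattern references unknown variable(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(config$study_var)) stop("config has no study variable")
  study <- as.integer(dataset$records[[config$study_var]])
  rec <- dataset$records
  for (v in names(pat)) {
    keep <- study %in% pat[[v]]
    rec[[v]][!keep] <- NA
  }
  out <- panel_dataset(rec, dataset$specs, dataset$provenance)
  log_step(out, sprintf("structural missingness applied to %d variable(s) by study",
                        length(pat)))
}

#' Inject plain MCAR missingness into determinant/outcome cells
#'
#' @param dataset a [panel_dataset()].
#' @param rate per-cell missingness probability.
#' @param seed integer seed.
#' @return the [panel_dataset()] with cells blanked.
#' @export
inject_mcar <- function(dataset, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(dataset)
  set.seed(as.integer(seed))
  rec <- dataset$records
  targets <- dataset$specs$name[dataset$specs$role %in% c("determinant", "outcome")]
  for (v in targets) rec[[v]][stats::runif(nrow(rec)) < rate] <- NA
  out <- panel_dataset(rec, dataset$specs, dataset$provenance)
  log_step(out, sprintf("MCAR missingness at rate %.2f on %d variable(s)",
                        rate, length(targets)))
}

#' Run the full generator: simulate, blank by study, render and aggregate
#'
#' Convenience wrapper producing the analysis-ready panel the way the
#' integrated multi-study dataset arises: forward-sample the complete
#' panel, apply the study availability pattern, render concepts as noisy
#' items with item-level missingness, aggregate items back into concept
#' scores (25% missing-item rule), and optionally add plain MCAR cell
#' missingness.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `complete` (the pre-missingness panel), `panel` (the
#'   analysis-ready panel), and `items` (the item table, or `NULL` when
#'   the config has no concepts table).
#' @export
generate_study <- function(config, seed = config$seed) {
  complete <- generate_panel(config, seed)
  panel <- complete
  if (length(config$missing_wave_pattern))
    panel <- inject_structural_missingness(panel, config, derive_seed(seed, 1))
  items <- NULL
  if (!is.null(config$concepts)) {
    items <- render_items(panel, config, derive_seed(seed, 2))
    panel <- aggregate_items(items, config$specs)
  }
  if (config$missing_cell_rate > 0)
    panel <- inject_mcar(panel, config$missing_cell_rate, derive_seed(seed, 3))
  list(complete = complete, panel = panel, items = items)
}
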