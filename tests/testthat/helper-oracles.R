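# Independent oracles and fixture builders shared across the test files.
# These deliberately avoid the package's own code paths wherever they act
# as a cross-check (closed forms, brute-force enumeration, lm-based fits).

# closed-form BIC of a single Gaussian column under the package's
# convention: loglik - (k/2) log n with k = 2 (mean, variance)
gaussian_column_bic <- function(x) {
  n <- length(x)
  s2 <- mean((x - mean(x))^2)
  -(n / 2) * (1 + log(2 * pi * s2)) - (2 / 2) * log(n)
}

# quick all-continuous single-tier panel
cont_panel <- function(df, timeslot = "T1") {
  sp <- variable_spec(names(df), rep(timeslot, ncol(df)),
                      rep("continuous", ncol(df)),
                      rep("determinant", ncol(df)))
  panel_dataset(df, sp)
}

# random DAG over p nodes: random topological order, arcs kept with prob
rand_dag <- function(p, prob = 0.35) {
  nodes <- sprintf("v%02d", seq_len(p))
  ord <- sample(nodes)
  arcs <- NULL
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    if (runif(1) < prob) arcs <- rbind(arcs, c(ord[i], ord[j]))
  dag_structure(nodes, arcs)
}

# brute-force enumeration of all simple directed source->target paths;
# returns the set of edges (as "from>to") lying on at least one path
brute_force_path_edges <- function(arcs, source, targets) {
  adj <- list()
  for (i in seq_len(NROW(arcs)))
    adj[[arcs[i, 1]]] <- c(adj[[arcs[i, 1]]], arcs[i, 2])
  edges <- character()
  path <- character()
  visit <- function(v) {
    path <<- c(path, v)
    if (v %in% targets && length(path) > 1L)
      edges <<- union(edges, paste(path[-length(path)], path[-1], sep = ">"))
    for (w in adj[[v]]) if (!(w %in% path)) visit(w)
    path <<- path[-length(path)]
  }
  if (source %in% names(adj) || source %in% unlist(adj)) visit(source)
  edges
}

# random small conditional-linear-Gaussian dataset with a known structure,
# for search-oracle comparisons (3-4 variables, occasionally a binary root)
rand_clg_panel <- function(p, n = 300, with_binary = FALSE) {
  nodes <- sprintf("x%d", seq_len(p))
  arcs <- NULL
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    if (runif(1) < 0.4) arcs <- rbind(arcs, c(nodes[i], nodes[j]))
  rec <- list()
  for (j in seq_len(p)) {
    v <- nodes[j]
    if (with_binary && j == 1L) {
      rec[[v]] <- factor(sample(c("a", "b"), n, TRUE), levels = c("a", "b"))
      next
    }
    mu <- rep(0, n)
    pa <- if (is.null(arcs)) character() else arcs[arcs[, 2] == v, 1]
    for (u in pa) {
      xu <- rec[[u]]
      xu <- if (is.factor(xu)) as.numeric(xu) - 1 else xu
      mu <- mu + runif(1, 0.4, 0.8) * xu
    }
    rec[[v]] <- mu + rnorm(n, 0, 0.8)
  }
  kinds <- ifelse(vapply(rec, is.factor, logical(1)), "discrete", "continuous")
  sp <- variable_spec(nodes, rep("T1", p), kinds,
                      rep("determinant", p),
                      levels = lapply(rec, function(x)
                        if (is.factor(x)) levels(x) else NULL))
  panel_dataset(as.data.frame(rec, check.names = FALSE), sp)
}

# single-structure averaged network with presence confidence 1 everywhere
averaged_from_arcs <- function(nodes, arcs) {
  average_network(list(dag_structure(nodes, arcs)), threshold = 0.6)
}

# full study fixture, generated once per test run
study_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- config_study(2500)
      cache <<- list(config = cfg, study = generate_study(cfg, seed = 404))
    }
    cache
  }
})
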