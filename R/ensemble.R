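# Efron-bootstrap model averaging: arc confidence across bootstrap-sample
# networks, thresholded averaged model with the undirected-tie rule, the
# structural Hamming distance, and stability selection of the bootstrap
# count.

derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) + 104729 * as.double(counter)) %% 2147483647)
}

#' Learn bootstrap-sample network structures
#'
#' Draws `B` resamples of the data (n rows with replacement, classical
#' Efron bootstrap) and runs [structural_em()] on each. Per-sample seeds
#' are derived from the master seed by a counter scheme, so growing `B`
#' extends the structure list without changing earlier samples. A failed
#' sample is retried with a fresh derived seed, at most 3 attempts.
#'
#' @param dataset a [panel_dataset()].
#' @param constraint a [tier_constraint()].
#' @param settings a [search_settings()].
#' @param B number of bootstrap samples (>= 1).
#' @param seed master integer seed.
#' @param resample set `FALSE` (diagnostic) to run on the original data
#'   each time with the master seed used directly, so `B = 1` equals a
#'   single [structural_em()] run with that seed.
#' @return list of [dag_structure()]s with attributes `B` and `seed`.
#' @export
bootstrap_structures <- function(dataset, constraint, settings = search_settings(),
                                 B, seed = settings$seed, resample = TRUE) {
  stopifnot(B >= 1)
  n <- nrow(dataset$records)
  out <- vector("list", B)
  for (b in seq_len(B)) {
    res <- NULL
    for (attempt in 0:2) {
      sb <- derive_seed(seed, b + 1000000 * attempt)
      res <- tryCatch({
        if (resample) {
          set.seed(sb)
          rows <- sample.int(n, n, replace = TRUE)
          d <- panel_dataset(dataset$records[rows, , drop = FALSE],
                             dataset$specs, dataset$provenance)
        } else d <- dataset
        st <- settings
        st$seed <- if (resample) sb else as.integer(seed)
        structural_em(d, constraint, st)$structure
      }, error = function(e) e)
      if (!inherits(res, "error")) break
    }
    if (inherits(res, "error"))
      stop("bootstrap sample ", b, " failed after 3 attempts: ",
           conditionMessage(res))
    out[[b]] <- res
  }
  attr(out, "B") <- as.integer(B)
  attr(out, "seed") <- as.integer(seed)
  out
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "~")
}

#' Arc confidence table over bootstrap structures
#'
#' For every unordered variable pair that occurs in at least one structure:
#' the fraction of bootstrap models containing the arc in either direction
#' (presence confidence) and the fraction of those containing the
#' alphabetically-forward orientation (direction confidence).
#'
#' @param structures list of [dag_structure()]s on a common node set.
#' @return data.frame with columns `a`, `b` (a < b), `n_fwd`, `n_rev`,
#'   `presence_conf`, `direction_conf`, and attribute `B_used`.
#' @export
arc_confidence <- function(structures) {
  B <- length(structures)
  counts <- new.env(parent = emptyenv())
  for (s in structures) {
    a <- s$arcs
    for (i in seq_len(nrow(a))) {
      fr <- a[i, 1]; to <- a[i, 2]
      key <- pair_key(fr, to)
      cur <- counts[[key]] %||% c(fwd = 0L, rev = 0L)
      if (fr < to) cur[["fwd"]] <- cur[["fwd"]] + 1L
      else cur[["rev"]] <- cur[["rev"]] + 1L
      counts[[key]] <- cur
    }
  }
  keys <- sort(ls(counts))
  ab <- do.call(rbind, strsplit(keys, "~", fixed = TRUE))
  if (is.null(ab)) ab <- matrix(character(), ncol = 2)
  nf <- vapply(keys, function(k) counts[[k]][["fwd"]], integer(1))
  nr <- vapply(keys, function(k) counts[[k]][["rev"]], integer(1))
  out <- data.frame(a = ab[, 1], b = ab[, 2], n_fwd = nf, n_rev = nr,
                    presence_conf = (nf + nr) / B,
                    direction_conf = ifelse(nf + nr > 0, nf / (nf + nr), NA_real_),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "B_used") <- B
  out
}

find_cycle_arcs <- function(arcs, nodes) {
  # returns the arcs of one directed cycle, or NULL
  adj <- stats::setNames(replicate(length(nodes), character()), nodes)
  for (i in seq_len(nrow(arcs))) adj[[arcs[i, 1]]] <- c(adj[[arcs[i, 1]]], arcs[i, 2])
  color <- stats::setNames(rep(0L, length(nodes)), nodes)
  stack_path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    color[[v]] <<- 1L
    stack_path <<- c(stack_path, v)
    for (w in adj[[v]]) {
      if (!is.null(found)) return()
      if (color[[w]] == 1L) {
        cyc <- c(stack_path[which(stack_path == w):length(stack_path)], w)
        found <<- cbind(from = cyc[-length(cyc)], to = cyc[-1])
        return()
      }
      if (color[[w]] == 0L) visit(w)
    }
    color[[v]] <<- 2L
    stack_path <<- stack_path[-length(stack_path)]
  }
  for (v in nodes) if (color[[v]] == 0L) visit(v)
  found
}

#' Averaged network from bootstrap structures
#'
#' Keeps every edge whose presence confidence is at least `threshold`,
#' oriented by direction majority; an exact direction tie yields an
#' undirected edge. If the majority orientations close a directed cycle,
#' the lowest-confidence arc of each cycle is dropped and flagged.
#'
#' @param structures list of [dag_structure()]s (or an [arc_confidence()]
#'   table via `confidence`).
#' @param threshold confidence threshold in (0, 1]; the analysis default
#'   is 0.6.
#' @return object of class `averaged_network`: `nodes`, `arcs` (directed,
#'   with `presence_conf` and `direction_conf`), `undirected` (with
#'   `presence_conf`), `threshold`, `B_used`, `dropped` (cycle-repair
#'   casualties, possibly empty).
#' @export
average_network <- function(structures, threshold = 0.6) {
  stopifnot(threshold > 0, threshold <= 1, length(structures) >= 1)
  conf <- arc_confidence(structures)
  nodes <- structures[[1]]$nodes
  keep <- conf$presence_conf >= threshold - 1e-9
  kept <- conf[keep, , drop = FALSE]
  directed <- kept[kept$n_fwd != kept$n_rev, , drop = FALSE]
  undirected <- kept[kept$n_fwd == kept$n_rev, , drop = FALSE]
  if (nrow(directed)) {
    fwd <- directed$n_fwd > directed$n_rev
    arcs <- data.frame(from = ifelse(fwd, directed$a, directed$b),
                       to = ifelse(fwd, directed$b, directed$a),
                       presence_conf = directed$presence_conf,
                       direction_conf = pmax(directed$n_fwd, directed$n_rev) /
                         (directed$n_fwd + directed$n_rev),
                       stringsAsFactors = FALSE)
  } else {
    arcs <- data.frame(from = character(), to = character(),
                       presence_conf = numeric(), direction_conf = numeric())
  }
  und <- data.frame(a = undirected$a, b = undirected$b,
                    presence_conf = undirected$presence_conf,
                    stringsAsFactors = FALSE)
  dropped <- arcs[0, ]
  # acyclicity repair on the directed part
  repeat {
    cyc <- find_cycle_arcs(as.matrix(arcs[, c("from", "to")]), nodes)
    if (is.null(cyc)) break
    on_cyc <- which(paste(arcs$from, arcs$to) %in% paste(cyc[, 1], cyc[, 2]))
    victim <- on_cyc[order(arcs$presence_conf[on_cyc],
                           arcs$from[on_cyc], arcs$to[on_cyc])][1]
    dropped <- rbind(dropped, arcs[victim, ])
    arcs <- arcs[-victim, , drop = FALSE]
  }
  if (nrow(dropped))
    warning("cycle repair dropped ", nrow(dropped), " arc(s) from the averaged network")
  structure(list(nodes = nodes, arcs = arcs, undirected = und,
                 threshold = threshold, B_used = attr(conf, "B_used"),
                 confidence = conf, dropped = dropped),
            class = "averaged_network")
}

#' @export
print.averaged_network <- function(x, ...) {
  cat("averaged_network:", length(x$nodes), "nodes;",
      nrow(x$arcs), "directed arcs,", nrow(x$undirected),
      "undirected edges at threshold", x$threshold,
      sprintf("(B = %d)\n", x$B_used))
  if (nrow(x$dropped)) cat("  cycle repair dropped", nrow(x$dropped), "arc(s)\n")
  invisible(x)
}

# canonical per-pair edge status: "fwd" (a->b with a<b), "rev", "und"
edge_status <- function(x) {
  if (inherits(x, "dag_structure")) {
    a <- x$arcs
    if (!nrow(a)) return(stats::setNames(character(), character()))
    st <- ifelse(a[, 1] < a[, 2], "fwd", "rev")
    stats::setNames(st, pair_key(a[, 1], a[, 2]))
  } else if (inherits(x, "averaged_network")) {
    st <- character(); key <- character()
    if (nrow(x$arcs)) {
      st <- c(st, ifelse(x$arcs$from < x$arcs$to, "fwd", "rev"))
      key <- c(key, pair_key(x$arcs$from, x$arcs$to))
    }
    if (nrow(x$undirected)) {
      st <- c(st, rep("und", nrow(x$undirected)))
      key <- c(key, pair_key(x$undirected$a, x$undirected$b))
    }
    stats::setNames(st, key)
  } else stop("unsupported graph type for edge_status")
}

#' Structural Hamming distance
#'
#' Number of single-edge edits (addition, deletion, reorientation, where
#' directed-to-undirected also counts one) transforming one graph into the
#' other. Accepts [dag_structure()]s and [averaged_network()]s.
#'
#' @param a,b graphs over the same node set.
#' @return integer edit count.
#' @export
shd <- function(a, b) {
  nodes_of <- function(x) if (inherits(x, "dag_structure")) x$nodes else x$nodes
  if (!setequal(nodes_of(a), nodes_of(b))) stop("node sets differ")
  sa <- edge_status(a); sb <- edge_status(b)
  keys <- union(names(sa), names(sb))
  va <- ifelse(keys %in% names(sa), sa[keys], "none")
  vb <- ifelse(keys %in% names(sb), sb[keys], "none")
  sum(va != vb)
}

#' Stability selection of the bootstrap count
#'
#' Runs the bootstrap once at the largest grid value (per-sample seeds are
#' counter-derived, so smaller counts reuse the prefix), forms the averaged
#' network at each grid point, and computes the structural Hamming distance
#' between consecutive averaged networks. The chosen count is the smallest
#' grid value whose distance to the next grid point is at most
#' `stability_tol` (default 0, a plateau); if the curve never plateaus the
#' largest grid value is returned with `plateau = FALSE`.
#'
#' @inheritParams bootstrap_structures
#' @param B_grid increasing integer grid of bootstrap counts (the analysis
#'   default is `seq(100, 150, by = 10)`).
#' @param threshold averaging confidence threshold.
#' @param stability_tol maximum tolerated consecutive distance.
#' @return list of class `stability_selection`: `chosen_B`, `plateau`,
#'   `curve` (data.frame `B_from`, `B_to`, `shd`), `structures` (at
#'   `max(B_grid)`), `networks` (averaged network per grid point).
#' @export
stability_select_B <- function(dataset, constraint, settings = search_settings(),
                               B_grid = seq(100L, 150L, by = 10L),
                               threshold = 0.6, seed = settings$seed,
                               stability_tol = 0L) {
  if (length(B_grid) < 2L) stop("B_grid must contain at least two values")
  if (is.unsorted(B_grid, strictly = TRUE)) stop("B_grid must be strictly increasing")
  structures <- bootstrap_structures(dataset, constraint, settings,
                                     B = max(B_grid), seed = seed)
  networks <- lapply(B_grid, function(B)
    average_network(structures[seq_len(B)], threshold))
  names(networks) <- as.character(B_grid)
  m <- length(B_grid)
  curve <- data.frame(B_from = B_grid[-m], B_to = B_grid[-1],
                      shd = vapply(seq_len(m - 1), function(i)
                        shd(networks[[i]], networks[[i + 1]]), numeric(1)))
  ok <- which(curve$shd <= stability_tol)
  if (length(ok)) {
    chosen <- curve$B_from[ok[1]]; plateau <- TRUE
  } else {
    chosen <- B_grid[m]; plateau <- FALSE
  }
  structure(list(chosen_B = chosen, plateau = plateau, curve = curve,
                 structures = structures, networks = networks),
            class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat("stability_selection: chosen B =", x$chosen_B,
      if (x$plateau) "(SHD plateau reached)" else "(no plateau; grid maximum)", "\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}
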