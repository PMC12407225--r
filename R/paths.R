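# Distillation of intervention-to-outcome pathway fragments from an
# averaged network, arc-strength grading (mutual-information terciles and
# confidence thickness groups), node role classification, and fragment
# comparison across subpopulations.

averaged_edge_table <- function(network) {
  ed <- network$arcs[, c("from", "to", "presence_conf"), drop = FALSE]
  ed$directed <- rep(TRUE, nrow(ed))
  if (nrow(network$undirected)) {
    ud <- data.frame(from = network$undirected$a, to = network$undirected$b,
                     presence_conf = network$undirected$presence_conf,
                     directed = FALSE, stringsAsFactors = FALSE)
    ed <- rbind(ed, ud)
  }
  ed
}

#' Grade the edges of an averaged network or fragment
#'
#' Each retained edge gets a jackknife bias-corrected mutual-information
#' estimate computed on the complete cases of its endpoint pair, a tercile
#' group (cut at the 33% and 67% quantiles of the graded edge set, ties
#' assigned to the lower group), and a thickness group from its presence
#' confidence (groups 0.6-0.7, 0.7-0.8, 0.8-0.9, 0.9-1.0).
#'
#' @param network an [average_network()] result or a `path_fragment`.
#' @param dataset the [panel_dataset()] the network was learned from.
#' @return data.frame of class `strength_annotation` with columns `from`,
#'   `to`, `directed`, `presence_conf`, `thickness_group`, `mi`, `mi_se`,
#'   `tercile`; the tercile cutpoints are kept in attribute `cutpoints`.
#' @export
grade_edges <- function(network, dataset) {
  ed <- if (inherits(network, "path_fragment")) network$edges
        else averaged_edge_table(network)
  if (!nrow(ed)) {
    out <- cbind(ed, thickness_group = integer(), mi = numeric(),
                 mi_se = numeric(), tercile = integer())
    class(out) <- c("strength_annotation", "data.frame")
    return(out)
  }
  miss <- setdiff(unique(c(ed$from, ed$to)), names(dataset$records))
  if (length(miss))
    stop("edge endpoints absent from dataset: ", paste(miss, collapse = ", "))
  mi <- numeric(nrow(ed)); mi_se <- numeric(nrow(ed))
  for (i in seq_len(nrow(ed))) {
    est <- mi_jackknife(dataset$records[[ed$from[i]]],
                        dataset$records[[ed$to[i]]])
    mi[i] <- est$mi; mi_se[i] <- est$se
  }
  q <- stats::quantile(mi, c(0.33, 0.67), names = FALSE, type = 7)
  out <- ed
  out$thickness_group <- 1L + (ed$presence_conf >= 0.7) +
    (ed$presence_conf >= 0.8) + (ed$presence_conf >= 0.9)
  out$mi <- mi
  out$mi_se <- mi_se
  out$tercile <- 1L + (mi > q[1]) + (mi > q[2])
  attr(out, "cutpoints") <- q
  class(out) <- c("strength_annotation", "data.frame")
  out
}

#' Extract the intervention-to-outcome path fragment
#'
#' Returns the subgraph of edges lying on at least one directed path from
#' the source (intervention) variable to any target (outcome) variable.
#' Undirected edges are traversable in either direction by default, since
#' they stand for Markov-equivalent orientations; an edge is on a path
#' exactly when its tail is reachable from the source and a target is
#' reachable from its head.
#'
#' @param network an [average_network()] result.
#' @param source the intervention variable name.
#' @param targets character vector of outcome variable names (at least one
#'   must be present in the network).
#' @param traversal `"both"` (undirected edges usable in both directions)
#'   or `"exclude"` (directed arcs only).
#' @param min_confidence optional extra presence-confidence filter applied
#'   before extraction (highlighted fragments); `NULL` leaves the
#'   averaging threshold as the only filter.
#' @param dataset optional [panel_dataset()]; when given, the fragment is
#'   annotated via [grade_edges()] over the fragment's own edge set.
#' @return object of class `path_fragment`: `source`, `targets`, `nodes`,
#'   `edges` (with `directed` flag and `presence_conf`), `annotations`
#'   (or `NULL`).
#' @export
extract_fragment <- function(network, source, targets,
                             traversal = c("both", "exclude"),
                             min_confidence = NULL, dataset = NULL) {
  traversal <- match.arg(traversal)
  if (!source %in% network$nodes) stop("source ", source, " not in network")
  targets <- intersect(targets, network$nodes)
  ed <- averaged_edge_table(network)
  if (!is.null(min_confidence))
    ed <- ed[ed$presence_conf >= min_confidence - 1e-9, , drop = FALSE]
  if (length(targets) == 0L || !nrow(ed)) {
    warning("no path from ", source, " to any target; empty fragment")
    return(empty_fragment(source, targets))
  }
  dir_edges <- ed[ed$directed, , drop = FALSE]
  und_edges <- ed[!ed$directed, , drop = FALSE]
  el <- as.matrix(dir_edges[, c("from", "to")])
  if (traversal == "both" && nrow(und_edges))
    el <- rbind(el, as.matrix(und_edges[, c("from", "to")]),
                as.matrix(und_edges[, c("to", "from")]))
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2]), directed = TRUE,
    vertices = data.frame(name = network$nodes))
  desc <- names(igraph::subcomponent(g, source, mode = "out"))
  anc <- unique(unlist(lapply(targets, function(t)
    names(igraph::subcomponent(g, t, mode = "in")))))
  on_path_dir <- dir_edges$from %in% desc & dir_edges$to %in% anc
  keep_dir <- dir_edges[on_path_dir, , drop = FALSE]
  on_path_und <- if (traversal == "both") {
    (und_edges$from %in% desc & und_edges$to %in% anc) |
      (und_edges$to %in% desc & und_edges$from %in% anc)
  } else rep(FALSE, nrow(und_edges))
  keep_und <- und_edges[on_path_und, , drop = FALSE]
  edges <- rbind(keep_dir, keep_und)
  if (!nrow(edges)) {
    warning("no path from ", source, " to any target; empty fragment")
    return(empty_fragment(source, targets))
  }
  frag <- structure(list(source = source, targets = targets,
                         nodes = unique(c(edges$from, edges$to)),
                         edges = edges, annotations = NULL),
                    class = "path_fragment")
  if (!is.null(dataset)) frag$annotations <- grade_edges(frag, dataset)
  frag
}

empty_fragment <- function(source, targets) {
  structure(list(source = source, targets = targets, nodes = character(),
                 edges = data.frame(from = character(), to = character(),
                                    presence_conf = numeric(),
                                    directed = logical()),
                 annotations = NULL),
            class = "path_fragment")
}

#' @export
print.path_fragment <- function(x, ...) {
  cat("path_fragment:", x$source, "->",
      paste(x$targets, collapse = ", "), ":",
      nrow(x$edges), "edges over", length(x$nodes), "nodes\n")
  invisible(x)
}

fragment_has_edge <- function(fragment, from, to, directed_only = FALSE) {
  e <- fragment$edges
  hit <- (e$from == from & e$to == to & e$directed) |
    (!directed_only & !e$directed &
       ((e$from == from & e$to == to) | (e$from == to & e$to == from)))
  any(hit)
}

#' Classify a determinant's role for one outcome
#'
#' A node is `direct` when the fragment contains an edge from it straight
#' into the target (an undirected edge to the target also counts, as it
#' admits that orientation), `indirect` when it appears in the fragment
#' without such an edge, and `absent` otherwise.
#'
#' @param fragment a `path_fragment`.
#' @param node variable name to classify.
#' @param target one of the fragment's targets.
#' @return `"direct"`, `"indirect"`, or `"absent"`.
#' @export
classify_role <- function(fragment, node, target) {
  if (!target %in% fragment$targets) stop(target, " is not a fragment target")
  if (!(node %in% fragment$nodes) || node == target) {
    if (node == target) return("direct")
    return("absent")
  }
  if (fragment_has_edge(fragment, node, target)) "direct" else "indirect"
}

edge_key_frag <- function(e) {
  ifelse(e$directed, paste0(e$from, ">", e$to),
         paste0(pmin(e$from, e$to), "~", pmax(e$from, e$to)))
}

#' Compare two subpopulation path fragments
#'
#' @param a,b `path_fragment`s for the two levels of a moderating factor.
#' @return list of class `fragment_diff`: `shared` (edges in both, with
#'   orientation), `only_a`, `only_b`, and `role_transitions`, a data.frame
#'   (`node`, `target`, `role_a`, `role_b`) listing every node whose role
#'   differs between the fragments for some common target.
#' @export
compare_fragments <- function(a, b) {
  ka <- edge_key_frag(a$edges); kb <- edge_key_frag(b$edges)
  shared <- a$edges[ka %in% kb, , drop = FALSE]
  only_a <- a$edges[!(ka %in% kb), , drop = FALSE]
  only_b <- b$edges[!(kb %in% ka), , drop = FALSE]
  targets <- intersect(a$targets, b$targets)
  nodes <- setdiff(union(a$nodes, b$nodes), targets)
  rows <- list()
  for (t in targets) for (v in nodes) {
    ra <- classify_role(a, v, t); rb <- classify_role(b, v, t)
    if (ra != rb)
      rows[[length(rows) + 1L]] <- data.frame(node = v, target = t,
                                              role_a = ra, role_b = rb,
                                              stringsAsFactors = FALSE)
  }
  transitions <- if (length(rows)) do.call(rbind, rows)
    else data.frame(node = character(), target = character(),
                    role_a = character(), role_b = character())
  structure(list(shared = shared, only_a = only_a, only_b = only_b,
                 role_transitions = transitions),
            class = "fragment_diff")
}

#' @export
print.fragment_diff <- function(x, ...) {
  cat("fragment_diff:", nrow(x$shared), "shared,", nrow(x$only_a),
      "only in A,", nrow(x$only_b), "only in B;",
      nrow(x$role_transitions), "role transition(s)\n")
  if (nrow(x$role_transitions)) print(x$role_transitions, row.names = FALSE)
  invisible(x)
}

#' Emit a Graphviz DOT rendering
#'
#' Edge penwidth encodes the confidence thickness group and the edge label
#' carries one to three asterisks for the mutual-information tercile,
#' mirroring the usual presentation of averaged intervention-pathway
#' models. Node fill colors can encode determinant categories.
#'
#' @param x an `averaged_network` or `path_fragment`.
#' @param annotations optional [grade_edges()] table (taken from the
#'   fragment when present).
#' @param categories optional named character vector mapping node name to
#'   a fill color.
#' @param path optional file to write to.
#' @return the DOT source, invisibly when `path` is given.
#' @export
to_dot <- function(x, annotations = NULL, categories = NULL, path = NULL) {
  ed <- if (inherits(x, "path_fragment")) x$edges else averaged_edge_table(x)
  if (is.null(annotations) && inherits(x, "path_fragment"))
    annotations <- x$annotations
  nodes <- if (inherits(x, "path_fragment")) x$nodes else x$nodes
  lines <- c("digraph averaged_model {", "  rankdir=LR;",
             "  node [style=filled, fillcolor=white, shape=box];")
  for (v in nodes) {
    col <- if (!is.null(categories) && v %in% names(categories))
      categories[[v]] else "white"
    lines <- c(lines, sprintf("  \"%s\" [fillcolor=\"%s\"];", v, col))
  }
  for (i in seq_len(nrow(ed))) {
    pw <- 1; stars <- ""
    if (!is.null(annotations)) {
      j <- which(annotations$from == ed$from[i] & annotations$to == ed$to[i])
      if (length(j)) {
        pw <- annotations$thickness_group[j[1]]
        stars <- strrep("*", annotations$tercile[j[1]])
      }
    }
    style <- if (ed$directed[i]) "" else ", dir=none"
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [penwidth=%d, label=\"%s\"%s];",
      ed$from[i], ed$to[i], pw, stars, style))
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(dot, path); return(invisible(dot)) }
  dot
}
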