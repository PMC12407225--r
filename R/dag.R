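#' Directed acyclic graph structure
#'
#' @param nodes character vector of variable names.
#' @param arcs two-column character matrix (or data.frame) of arcs,
#'   `from` then `to`; may have zero rows.
#' @return object of class `dag_structure`.
#' @export
dag_structure <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (is.null(arcs) || NROW(arcs) == 0L) {
    arcs <- matrix(character(), ncol = 2, dimnames = list(NULL, c("from", "to")))
  } else {
    arcs <- as.matrix(arcs)
    colnames(arcs) <- c("from", "to")
    if (!all(arcs %in% nodes)) stop("arc endpoint not among nodes")
    if (any(arcs[, 1] == arcs[, 2])) stop("self-loop arc")
    if (anyDuplicated(paste(arcs[, 1], arcs[, 2]))) stop("duplicate arc")
  }
  g <- structure(list(nodes = nodes, arcs = arcs), class = "dag_structure")
  if (has_cycle(adjacency_list(g), nodes)) stop("arc set contains a cycle")
  g
}

#' @export
print.dag_structure <- function(x, ...) {
  cat("dag_structure:", length(x$nodes), "nodes,", nrow(x$arcs), "arcs\n")
  invisible(x)
}

adjacency_list <- function(structure) {
  adj <- stats::setNames(vector("list", length(structure$nodes)), structure$nodes)
  for (i in seq_len(nrow(structure$arcs)))
    adj[[structure$arcs[i, 1]]] <- c(adj[[structure$arcs[i, 1]]], structure$arcs[i, 2])
  adj
}

# iterative DFS reachability: can `to` be reached from `from`?
reaches <- function(adj, from, to) {
  if (from == to) return(TRUE)
  stack <- from
  seen <- character()
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (w == to) return(TRUE)
      if (!(w %in% seen)) { seen <- c(seen, w); stack <- c(stack, w) }
    }
  }
  FALSE
}

has_cycle <- function(adj, nodes) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in nodes) for (w in adj[[v]]) indeg[[w]] <- indeg[[w]] + 1L
  queue <- names(indeg)[indeg == 0L]
  removed <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; removed <- removed + 1L
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  removed < length(nodes)
}

#' Topological ordering of a DAG
#'
#' Kahn's algorithm with lexicographic tie-breaking, so the order is a
#' deterministic function of the structure.
#'
#' @param structure a [dag_structure()].
#' @return character vector of node names, parents before children.
#' @export
topological_order <- function(structure) {
  nodes <- structure$nodes
  adj <- adjacency_list(structure)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in nodes) for (w in adj[[v]]) indeg[[w]] <- indeg[[w]] + 1L
  out <- character()
  avail <- sort(names(indeg)[indeg == 0L])
  while (length(avail)) {
    v <- avail[[1]]; avail <- avail[-1]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(out) < length(nodes)) stop("graph is cyclic")
  out
}

parents_of <- function(structure, node) {
  structure$arcs[structure$arcs[, 2] == node, 1]
}

#' Temporal tier constraint
#'
#' Tiers are ordered variable sets (static exogenous variables first, then
#' each measurement wave); any arc from a later tier into a strictly earlier
#' tier is forbidden, which encodes that causes cannot postdate their
#' effects across measurement waves. Additional arcs can be forbidden or
#' required explicitly.
#'
#' @param tiers list of character vectors partitioning the variable set,
#'   earliest first.
#' @param forbidden optional two-column matrix of extra forbidden arcs.
#' @param required optional two-column matrix of arcs forced present.
#' @return object of class `tier_constraint`.
#' @export
tier_constraint <- function(tiers, forbidden = NULL, required = NULL) {
  all_vars <- unlist(tiers, use.names = FALSE)
  if (anyDuplicated(all_vars)) stop("tiers must partition the variable set")
  tidy <- function(m) {
    if (is.null(m) || NROW(m) == 0L)
      return(matrix(character(), ncol = 2, dimnames = list(NULL, c("from", "to"))))
    m <- as.matrix(m); colnames(m) <- c("from", "to"); m
  }
  structure(list(tiers = lapply(tiers, as.character),
                 forbidden = tidy(forbidden), required = tidy(required)),
            class = "tier_constraint")
}

tier_index <- function(constraint, vars) {
  idx <- rep(NA_integer_, length(vars))
  for (t in seq_along(constraint$tiers))
    idx[vars %in% constraint$tiers[[t]]] <- t
  idx
}

#' Build the tier constraint implied by a variable specification
#'
#' Static variables form the first tier, then waves in the given order. By
#' default the intervention indicator and the demographics are exogenous
#' roots: arcs into them are forbidden (randomized assignment; immutable
#' demographics).
#'
#' @param specs a [variable_spec()] table.
#' @param waves wave labels in temporal order.
#' @param exogenous_roots forbid arcs into intervention/demographic
#'   variables (default `TRUE`).
#' @return a [tier_constraint()].
#' @export
tiers_from_specs <- function(specs, waves = c("T0", "T1", "T2", "T3"),
                             exogenous_roots = TRUE) {
  waves <- intersect(waves, unique(specs$timeslot))
  tiers <- c(list(specs$name[specs$timeslot == "static"]),
             lapply(waves, function(w) specs$name[specs$timeslot == w]))
  tiers <- tiers[vapply(tiers, length, integer(1)) > 0L]
  forb <- NULL
  if (exogenous_roots) {
    roots <- specs$name[specs$role %in% c("intervention", "demographic")]
    if (length(roots)) {
      others <- specs$name
      forb <- cbind(from = rep(others, each = length(roots)),
                    to = rep(roots, times = length(others)))
      forb <- forb[forb[, 1] != forb[, 2], , drop = FALSE]
    }
  }
  tier_constraint(tiers, forbidden = forb)
}

#' Check whether a single arc is legal
#'
#' An arc is illegal when it runs from a later tier into an earlier one
#' (`"tier"`), when adding it would close a directed cycle (`"cycle"`),
#' when it points from a continuous variable into a discrete one, which the
#' conditional linear Gaussian model class forbids (`"class"`), or when it
#' is explicitly blacklisted (`"forbidden"`).
#'
#' @param structure a [dag_structure()] (the arc is checked as an addition).
#' @param constraint a [tier_constraint()].
#' @param arc length-2 character vector `c(from, to)`.
#' @param specs optional [variable_spec()] table; enables the model-class
#'   check for continuous-to-discrete arcs.
#' @return `TRUE`, or `FALSE` with attribute `reason`.
#' @export
check_arc_legal <- function(structure, constraint, arc, specs = NULL) {
  from <- arc[[1]]; to <- arc[[2]]
  if (!(from %in% structure$nodes) || !(to %in% structure$nodes))
    stop("unknown node in arc: ", from, " -> ", to)
  fail <- function(reason) { r <- FALSE; attr(r, "reason") <- reason; r }
  ok <- function() { r <- TRUE; attr(r, "reason") <- "ok"; r }
  if (from == to) return(fail("cycle"))
  ti <- tier_index(constraint, c(from, to))
  if (!anyNA(ti) && ti[1] > ti[2]) return(fail("tier"))
  if (nrow(constraint$forbidden) &&
      any(constraint$forbidden[, 1] == from & constraint$forbidden[, 2] == to))
    return(fail("forbidden"))
  if (!is.null(specs) &&
      spec_kind(specs, from) == "continuous" && spec_kind(specs, to) == "discrete")
    return(fail("class"))
  if (reaches(adjacency_list(structure), to, from)) return(fail("cycle"))
  ok()
}

arc_in <- function(arcs, from, to) {
  nrow(arcs) > 0L && any(arcs[, 1] == from & arcs[, 2] == to)
}

add_arc <- function(structure, from, to) {
  structure$arcs <- rbind(structure$arcs, c(from, to))
  structure
}

remove_arc <- function(structure, from, to) {
  keep <- !(structure$arcs[, 1] == from & structure$arcs[, 2] == to)
  structure$arcs <- structure$arcs[keep, , drop = FALSE]
  structure
}

#' Serialize a structure's arcs to CSV
#' @param structure a [dag_structure()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_arcs_csv <- function(structure, path) {
  utils::write.csv(as.data.frame(structure$arcs), path, row.names = FALSE)
  invisible(path)
}
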