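#' Search and EM settings
#'
#' @param max_iter_hc maximum hill-climbing moves per search.
#' @param tabu_length length of the tabu list / permitted worsening streak
#'   used to escape local optima (0 disables the escape phase).
#' @param random_restarts number of perturb-and-restart rounds.
#' @param em_max_iter maximum structural-EM iterations.
#' @param em_tol convergence tolerance on the per-row completed-data score.
#' @param seed integer seed (used for restarts and `single_draw` completion).
#' @param completion_mode E-step completion: `"single_draw"` (default)
#'   draws the missing values from their exact conditional distribution
#'   under the current network, which keeps the completed data properly
#'   dispersed; `"expected_value"` substitutes conditional means, which is
#'   deterministic but shrinks conditional variance and can let the score
#'   pick up spurious arcs between the neighbors of imputed variables.
#' @return object of class `search_settings`.
#' @export
search_settings <- function(max_iter_hc = 200L, tabu_length = 10L,
                            random_restarts = 0L, em_max_iter = 10L,
                            em_tol = 1e-4, seed = 1L,
                            completion_mode = c("single_draw", "expected_value")) {
  completion_mode <- match.arg(completion_mode)
  stopifnot(max_iter_hc >= 1, tabu_length >= 0, random_restarts >= 0,
            em_max_iter >= 1, em_tol > 0)
  structure(list(max_iter_hc = as.integer(max_iter_hc),
                 tabu_length = as.integer(tabu_length),
                 random_restarts = as.integer(random_restarts),
                 em_max_iter = as.integer(em_max_iter),
                 em_tol = em_tol, seed = as.integer(seed),
                 completion_mode = completion_mode),
            class = "search_settings")
}

# static (structure-independent) legality of every ordered pair
static_legal_matrix <- function(nodes, constraint, specs) {
  p <- length(nodes)
  legal <- matrix(TRUE, p, p, dimnames = list(nodes, nodes))
  diag(legal) <- FALSE
  ti <- tier_index(constraint, nodes)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (!legal[i, j]) next
    if (!is.na(ti[i]) && !is.na(ti[j]) && ti[i] > ti[j]) { legal[i, j] <- FALSE; next }
    if (spec_kind(specs, nodes[i]) == "continuous" &&
        spec_kind(specs, nodes[j]) == "discrete") { legal[i, j] <- FALSE; next }
  }
  fb <- constraint$forbidden
  for (k in seq_len(nrow(fb)))
    if (fb[k, 1] %in% nodes && fb[k, 2] %in% nodes)
      legal[fb[k, 1], fb[k, 2]] <- FALSE
  legal
}

arcs_from_pa <- function(pa) {
  fr <- unlist(pa, use.names = FALSE)
  to <- rep(names(pa), vapply(pa, length, integer(1)))
  if (!length(fr))
    return(matrix(character(), ncol = 2, dimnames = list(NULL, c("from", "to"))))
  cbind(from = fr, to = to)
}

pa_hash <- function(pa) {
  paste(vapply(sort(names(pa)), function(v)
    paste0(v, "<", paste(sort(pa[[v]]), collapse = "+")), character(1)),
    collapse = ";")
}

# reachability on a parent-list representation: TRUE if `to` reachable
# from `from` following child direction
pa_reaches <- function(children, from, to) {
  stack <- from; seen <- character()
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    for (w in children[[v]]) {
      if (w == to) return(TRUE)
      if (!(w %in% seen)) { seen <- c(seen, w); stack <- c(stack, w) }
    }
  }
  FALSE
}

#' BIC hill climbing under tier constraints
#'
#' Greedy search over single-arc additions, deletions and reversals, all
#' checked for tier, model-class, blacklist and acyclicity legality. When
#' no move improves the score and `tabu_length > 0`, a bounded tabu phase
#' accepts the best non-tabu move (even if worsening) for up to
#' `tabu_length` consecutive non-improving steps, keeping the best
#' structure seen. Ties between equal-score moves break lexicographically
#' by (child, parent), so the search is deterministic.
#'
#' @param dataset a complete-data [panel_dataset()].
#' @param constraint a [tier_constraint()].
#' @param settings a [search_settings()].
#' @param start optional [dag_structure()] to start from (default: the
#'   empty graph plus any required arcs).
#' @return a [dag_structure()] with attributes `score` (its BIC) and
#'   `moves` (number of accepted moves).
#' @export
hill_climb <- function(dataset, constraint, settings = search_settings(),
                       start = NULL) {
  nodes <- names(dataset$records)
  specs <- dataset$specs
  sdat <- scored_data(dataset$records, specs)
  legal <- static_legal_matrix(nodes, constraint, specs)
  req <- constraint$required
  fs <- function(child, parents) fit_family(sdat, child, parents)$bic

  pa <- stats::setNames(replicate(length(nodes), character()), nodes)
  if (!is.null(start)) for (v in nodes) pa[[v]] <- parents_of(start, v)
  for (k in seq_len(nrow(req))) {
    if (!arc_in(arcs_from_pa(pa), req[k, 1], req[k, 2]))
      pa[[req[k, 2]]] <- c(pa[[req[k, 2]]], req[k, 1])
  }
  required_arc <- function(from, to)
    nrow(req) > 0L && any(req[, 1] == from & req[, 2] == to)

  run_once <- function(pa) {
    ns <- vapply(nodes, function(v) fs(v, pa[[v]]), numeric(1))
    children <- stats::setNames(replicate(length(nodes), character()), nodes)
    for (v in nodes) for (u in pa[[v]]) children[[u]] <- c(children[[u]], v)
    score <- sum(ns)
    best_pa <- pa; best_score <- score
    tabu <- character(); stall <- 0L; moves <- 0L
    eps <- 1e-8
    snodes <- sort(nodes)
    repeat {
      if (moves >= settings$max_iter_hc) break
      cand <- NULL; cand_delta <- -Inf
      for (child in snodes) {
        cur <- ns[[child]]
        for (parent in snodes) {
          if (parent == child) next
          has <- parent %in% pa[[child]]
          if (!has && legal[parent, child]) {
            d <- fs(child, c(pa[[child]], parent)) - cur
            if (d > cand_delta + eps &&
                !pa_reaches(children, child, parent)) {
              new_pa <- pa; new_pa[[child]] <- c(new_pa[[child]], parent)
              if (!(pa_hash(new_pa) %in% tabu)) {
                cand <- list(type = "add", from = parent, to = child,
                             pa = new_pa)
                cand_delta <- d
              }
            }
          } else if (has && !required_arc(parent, child)) {
            d_del <- fs(child, setdiff(pa[[child]], parent)) - cur
            if (d_del > cand_delta + eps) {
              new_pa <- pa; new_pa[[child]] <- setdiff(new_pa[[child]], parent)
              if (!(pa_hash(new_pa) %in% tabu)) {
                cand <- list(type = "delete", from = parent, to = child,
                             pa = new_pa)
                cand_delta <- d_del
              }
            }
            if (legal[child, parent]) {
              d_rev <- d_del +
                fs(parent, c(pa[[parent]], child)) - ns[[parent]]
              if (d_rev > cand_delta + eps) {
                ch2 <- children
                ch2[[parent]] <- setdiff(ch2[[parent]], child)
                if (!pa_reaches(ch2, parent, child)) {
                  new_pa <- pa
                  new_pa[[child]] <- setdiff(new_pa[[child]], parent)
                  new_pa[[parent]] <- c(new_pa[[parent]], child)
                  if (!(pa_hash(new_pa) %in% tabu)) {
                    cand <- list(type = "reverse", from = parent, to = child,
                                 pa = new_pa)
                    cand_delta <- d_rev
                  }
                }
              }
            }
          }
        }
      }
      if (is.null(cand)) break
      improving <- cand_delta > eps
      if (!improving && (settings$tabu_length == 0L || stall >= settings$tabu_length))
        break
      # apply the move
      pa <- cand$pa
      ns[[cand$to]] <- fs(cand$to, pa[[cand$to]])
      if (cand$type == "reverse")
        ns[[cand$from]] <- fs(cand$from, pa[[cand$from]])
      children <- stats::setNames(replicate(length(nodes), character()), nodes)
      for (v in nodes) for (u in pa[[v]]) children[[u]] <- c(children[[u]], v)
      score <- sum(ns)
      moves <- moves + 1L
      tabu <- c(tabu, pa_hash(pa))
      if (length(tabu) > max(settings$tabu_length, 1L))
        tabu <- tabu[-1]
      if (score > best_score + eps) {
        best_score <- score; best_pa <- pa; stall <- 0L
      } else stall <- stall + 1L
    }
    list(pa = best_pa, score = best_score, moves = moves)
  }

  res <- run_once(pa)
  if (settings$random_restarts > 0L) {
    set.seed(settings$seed)
    for (r in seq_len(settings$random_restarts)) {
      pa2 <- res$pa
      # perturb: delete up to 2 random non-required arcs
      arcs <- arcs_from_pa(pa2)
      del <- which(!apply(arcs, 1, function(a) required_arc(a[1], a[2])))
      if (length(del)) {
        drop <- sample(del, min(2L, length(del)))
        for (i in drop) pa2[[arcs[i, 2]]] <- setdiff(pa2[[arcs[i, 2]]], arcs[i, 1])
      }
      res2 <- run_once(pa2)
      if (res2$score > res$score) res <- res2
    }
  }
  out <- dag_structure(nodes, arcs_from_pa(res$pa))
  attr(out, "score") <- res$score
  attr(out, "moves") <- res$moves
  out
}

#' Enumerate all legal DAGs over a small variable set
#'
#' Test/oracle utility: lists every arc set that is acyclic and respects
#' the tier constraint, the model-class rule and the blacklist/whitelist.
#'
#' @param nodes character vector (at most 5 variables).
#' @param constraint a [tier_constraint()].
#' @param specs a [variable_spec()] table.
#' @return list of two-column arc matrices.
#' @export
enumerate_legal_dags <- function(nodes, constraint, specs) {
  if (length(nodes) > 5L) stop("enumeration limited to 5 variables")
  legal <- static_legal_matrix(nodes, constraint, specs)
  pairs <- which(legal, arr.ind = TRUE)
  arcs <- cbind(from = nodes[pairs[, 1]], to = nodes[pairs[, 2]])
  ord <- order(arcs[, 1], arcs[, 2])
  arcs <- arcs[ord, , drop = FALSE]
  m <- nrow(arcs)
  req <- constraint$required
  out <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)))
    a <- arcs[sel, , drop = FALSE]
    ok <- TRUE
    for (k in seq_len(nrow(req)))
      if (!arc_in(a, req[k, 1], req[k, 2])) { ok <- FALSE; break }
    if (!ok) next
    g <- list(nodes = nodes, arcs = a)
    class(g) <- "dag_structure"
    if (!has_cycle(adjacency_list(g), nodes)) out[[length(out) + 1L]] <- a
  }
  out
}

#' Globally optimal structure by exhaustive enumeration
#'
#' Finds the BIC-optimal legal DAG on at most 5 variables by maximizing
#' over topological orders with per-node optimal parent subsets (exact, and
#' equivalent to enumerating all legal DAGs because the score decomposes).
#' Intended as the oracle against which [hill_climb()] is validated.
#'
#' @inheritParams hill_climb
#' @return a [dag_structure()] with attribute `score`.
#' @export
exhaustive_search <- function(dataset, constraint) {
  nodes <- names(dataset$records)
  if (length(nodes) > 5L) stop("exhaustive search limited to 5 variables")
  specs <- dataset$specs
  sdat <- scored_data(dataset$records, specs)
  legal <- static_legal_matrix(nodes, constraint, specs)
  req <- constraint$required
  perms <- all_permutations(nodes)
  best <- NULL; best_score <- -Inf
  for (ord in perms) {
    total <- 0; pa <- list(); feasible <- TRUE
    for (i in seq_along(ord)) {
      v <- ord[[i]]
      preds <- if (i > 1) ord[seq_len(i - 1)] else character()
      allowed <- preds[legal[preds, v]]
      forced <- req[req[, 2] == v, 1]
      if (!all(forced %in% allowed)) { feasible <- FALSE; break }
      free <- setdiff(allowed, forced)
      best_fam <- -Inf; best_pa <- NULL
      subs <- subsets_of(free)
      for (s in subs) {
        cand <- c(forced, s)
        sc <- fit_family(sdat, v, cand)$bic
        if (sc > best_fam + 1e-12) { best_fam <- sc; best_pa <- cand }
      }
      total <- total + best_fam
      pa[[v]] <- best_pa
    }
    if (feasible && total > best_score + 1e-9) {
      best_score <- total
      best <- pa
    }
  }
  pa_full <- stats::setNames(replicate(length(nodes), character()), nodes)
  for (v in names(best)) pa_full[[v]] <- best[[v]]
  out <- dag_structure(nodes, arcs_from_pa(pa_full))
  attr(out, "score") <- best_score
  out
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[[i]], rest)
  out
}

subsets_of <- function(x) {
  m <- length(x)
  if (m == 0L) return(list(character()))
  out <- vector("list", 2^m)
  for (mask in 0:(2^m - 1))
    out[[mask + 1L]] <- x[as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)))]
  out
}
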