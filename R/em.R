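# Structural expectation-maximization: alternate completion of the missing
# cells under the current fitted network (E) with hill-climb structure
# search plus maximum-likelihood refit on the completed data (M).

# initial completion: column means (continuous) / column modes (discrete)
complete_initial <- function(dataset) {
  rec <- dataset$records
  for (v in names(rec)) {
    miss <- !dataset$mask[, v]
    if (!any(miss)) next
    if (dataset$specs$kind[match(v, dataset$specs$name)] == "discrete") {
      tab <- table(rec[[v]])
      if (sum(tab) == 0) stop("variable ", v, " has no observed cells")
      mode_lv <- names(tab)[which.max(tab)]
      rec[[v]][miss] <- mode_lv
    } else {
      mu <- mean(rec[[v]], na.rm = TRUE)
      if (is.nan(mu)) stop("variable ", v, " has no observed cells")
      rec[[v]][miss] <- mu
    }
  }
  rec
}

# E-step completion under a fitted network. Missing discrete values are
# completed first by a topological sweep over their (discrete) parents;
# missing continuous values are then completed exactly, as the
# conditional expectation (or a draw) of the joint Gaussian implied by
# the linear-Gaussian locals for the row's discrete profile, conditioned
# on every observed continuous value of that row. Conditioning on the
# full observed vector (children included) avoids the spurious residual
# dependence a parents-only sweep would leave between the children of an
# imputed variable.
complete_with_bn <- function(dataset, bn, mode = "expected_value") {
  rec <- dataset$records
  ord <- topological_order(bn$structure)
  kind <- stats::setNames(bn$specs$kind, bn$specs$name)

  for (v in ord[kind[ord] == "discrete"]) {
    miss <- which(!dataset$mask[, v])
    if (!length(miss)) next
    par <- bn$parameters[[v]]
    sub <- rec[miss, , drop = FALSE]
    idx <- config_index_df(sub, bn$specs, par$dparents)
    lv <- par$levels %||% spec_levels(bn$specs, v)
    if (mode == "expected_value") {
      pick <- apply(par$cpt[idx, , drop = FALSE], 1, which.max)
    } else {
      pick <- vapply(idx, function(g)
        sample.int(length(lv), 1L, prob = par$cpt[g, ]), integer(1))
    }
    rec[[v]][miss] <- lv[pick]
  }

  cont <- ord[kind[ord] == "continuous"]
  if (!length(cont)) return(rec)
  miss_any <- rowSums(!dataset$mask[, cont, drop = FALSE]) > 0
  if (!any(miss_any)) return(rec)
  disc <- bn$specs$name[bn$specs$kind == "discrete"]
  profile <- if (length(disc))
    do.call(paste, c(lapply(rec[disc], as.character), sep = "\r"))
  else rep("", nrow(rec))
  p <- length(cont)
  for (rows_p in split(which(miss_any), profile[miss_any])) {
    one <- rec[rows_p[1], , drop = FALSE]
    W <- matrix(0, p, p, dimnames = list(cont, cont))
    b <- numeric(p); s2 <- numeric(p)
    for (j in seq_len(p)) {
      par <- bn$parameters[[cont[j]]]
      g <- config_index_df(one, bn$specs, par$dparents)
      b[j] <- par$coef[g, 1]
      for (u in par$cparents) W[u, cont[j]] <- par$coef[g, u]
      s2[j] <- par$sigma2[g]
    }
    M <- solve(diag(p) - t(W))
    mu <- drop(M %*% b)
    Sigma <- M %*% (t(M) * s2)
    X <- as.matrix(rec[rows_p, cont, drop = FALSE])
    pat <- apply(!dataset$mask[rows_p, cont, drop = FALSE], 1, paste,
                 collapse = "")
    for (rows_q in split(seq_along(rows_p), pat)) {
      m <- !dataset$mask[rows_p[rows_q[1]], cont]
      if (!any(m)) next
      if (all(m)) {
        cmean <- matrix(mu, nrow = length(rows_q), ncol = p, byrow = TRUE)
        cvar <- Sigma
      } else {
        Soo <- Sigma[!m, !m, drop = FALSE]
        Smo <- Sigma[m, !m, drop = FALSE]
        dev <- sweep(X[rows_q, !m, drop = FALSE], 2, mu[!m])
        cmean <- sweep(dev %*% solve(Soo, t(Smo)), 2, mu[m], `+`)
        cvar <- Sigma[m, m, drop = FALSE] - Smo %*% solve(Soo, t(Smo))
      }
      filled <- if (mode == "expected_value") cmean
      else cmean + matrix(stats::rnorm(length(rows_q) * sum(m)),
                          nrow = length(rows_q)) %*%
        chol(cvar + diag(1e-10, sum(m)))
      if (all(m)) filled <- filled[, m, drop = FALSE]
      X[rows_q, m] <- filled
    }
    for (j in which(colSums(!dataset$mask[rows_p, cont, drop = FALSE]) > 0))
      rec[rows_p, cont[j]] <- X[, j]
  }
  rec
}

as_complete_panel <- function(records, dataset) {
  panel_dataset(records, dataset$specs,
                provenance = c(dataset$provenance, "EM-completed"))
}

#' Structural EM for incomplete panel data
#'
#' Learns a hybrid network from data with missing cells by iterating an
#' E-step that completes the dataset under the currently fitted network
#' (missing discrete values from their parent configuration's CPT row;
#' missing continuous values from the exact Gaussian conditional of the
#' row's discrete profile given all its observed values — drawn under the
#' default `completion_mode = "single_draw"`, or substituted by their
#' conditional mean under `"expected_value"`) and an M-step that hill
#' climbs and refits on the completed data. The
#' first completion uses column means/modes. An iteration is accepted only
#' if it improves the completed-data BIC, so the recorded score log is
#' non-decreasing; the algorithm stops when the per-row improvement falls
#' below `em_tol` or `em_max_iter` is reached, returning the best network
#' seen with a convergence flag (it never raises on non-convergence).
#'
#' @param dataset a [panel_dataset()], possibly with missing cells; every
#'   variable must have at least one observed cell.
#' @param constraint a [tier_constraint()].
#' @param settings a [search_settings()].
#' @return list of class `structural_em` with elements `bn` (a
#'   [hybrid_bn()]), `structure`, `scores` (completed-data BIC per accepted
#'   iteration), `converged`, and `iterations`.
#' @export
structural_em <- function(dataset, constraint, settings = search_settings()) {
  n <- nrow(dataset$records)
  complete_input <- all(dataset$mask)
  if (settings$completion_mode == "single_draw") set.seed(settings$seed)

  completed <- if (complete_input) dataset$records else complete_initial(dataset)
  cd <- as_complete_panel(completed, dataset)
  s <- hill_climb(cd, constraint, settings)
  bn <- fit_parameters(s, cd)
  scores <- attr(s, "score")
  converged <- TRUE

  if (!complete_input) {
    converged <- FALSE
    for (it in seq_len(settings$em_max_iter - 1L)) {
      completed2 <- complete_with_bn(dataset, bn, settings$completion_mode)
      cd2 <- as_complete_panel(completed2, dataset)
      s2 <- hill_climb(cd2, constraint, settings, start = s)
      sc2 <- attr(s2, "score")
      if (sc2 <= scores[length(scores)]) { converged <- TRUE; break }  # plateau: keep best-so-far
      improvement <- (sc2 - scores[length(scores)]) / n
      s <- s2
      bn <- fit_parameters(s2, cd2)
      scores <- c(scores, sc2)
      if (improvement < settings$em_tol) { converged <- TRUE; break }
    }
  }

  structure(list(bn = bn, structure = s, scores = scores,
                 converged = converged, iterations = length(scores)),
            class = "structural_em")
}

#' @export
print.structural_em <- function(x, ...) {
  cat("structural_em:", length(x$structure$nodes), "nodes,",
      nrow(x$structure$arcs), "arcs;",
      x$iterations, "iterations;",
      if (x$converged) "converged" else "stopped at best-so-far", "\n")
  invisible(x)
}
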