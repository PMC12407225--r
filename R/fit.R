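# Conditional linear Gaussian local distributions: maximum-likelihood
# fitting, decomposable BIC scoring, and per-row log density. Discrete
# nodes are multinomial given discrete parents; continuous nodes are
# Gaussian with a linear mean in their continuous parents, one coefficient
# set per configuration of their discrete parents. Discrete nodes may not
# have continuous parents (model-class restriction).

VAR_FLOOR <- 1e-9

# columnar view of a complete data table for fast repeated family fits,
# with a per-(child, parent-set) memo cache
scored_data <- function(records, specs) {
  n <- nrow(records)
  kind <- stats::setNames(specs$kind, specs$name)
  cols <- list(); nlev <- integer()
  for (v in names(records)) {
    if (kind[[v]] == "discrete") {
      f <- records[[v]]
      if (anyNA(f)) stop("bic_score/fit require complete data; NA in ", v)
      cols[[v]] <- as.integer(f)
      nlev[[v]] <- length(levels(f))
    } else {
      x <- as.numeric(records[[v]])
      if (anyNA(x)) stop("bic_score/fit require complete data; NA in ", v)
      cols[[v]] <- x
    }
  }
  env <- new.env(parent = emptyenv())
  env$n <- n; env$cols <- cols; env$nlev <- nlev; env$kind <- kind
  env$cache <- new.env(parent = emptyenv())
  env
}

# mixed-radix configuration index over discrete parents (order as given)
config_index <- function(sdat, dparents) {
  n <- sdat$n
  if (!length(dparents)) return(list(idx = rep.int(1L, n), q = 1L))
  idx <- rep.int(1L, n); mult <- 1L
  for (p in dparents) {
    idx <- idx + (sdat$cols[[p]] - 1L) * mult
    mult <- mult * sdat$nlev[[p]]
  }
  list(idx = idx, q = mult)
}

fit_family <- function(sdat, child, parents) {
  parents <- sort(parents)
  key <- paste0(child, "|", paste(parents, collapse = ","))
  hit <- sdat$cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- sdat$n
  dpar <- parents[sdat$kind[parents] == "discrete"]
  cpar <- parents[sdat$kind[parents] == "continuous"]
  if (sdat$kind[[child]] == "discrete") {
    if (length(cpar)) stop("discrete node ", child, " with continuous parent")
    r <- sdat$nlev[[child]]
    cfg <- config_index(sdat, dpar)
    counts <- matrix(tabulate((cfg$idx - 1L) * r + sdat$cols[[child]],
                              nbins = cfg$q * r),
                     nrow = cfg$q, byrow = TRUE)
    rowtot <- rowSums(counts)
    nz <- counts > 0
    ll <- sum(counts[nz] * log(counts[nz] / rowtot[row(counts)[nz]]))
    k <- (r - 1) * cfg$q
    cpt <- counts / ifelse(rowtot > 0, rowtot, 1)
    cpt[rowtot == 0, ] <- 1 / r
    out <- list(type = "discrete", ll = ll, k = k,
                bic = ll - k / 2 * log(n),
                levels = r, dparents = dpar, cpt = cpt)
  } else {
    y <- sdat$cols[[child]]
    X <- cbind(`(Intercept)` = rep.int(1, n))
    for (p in cpar) X <- cbind(X, sdat$cols[[p]])
    colnames(X) <- c("(Intercept)", cpar)
    p_col <- ncol(X)
    cfg <- config_index(sdat, dpar)
    pooled <- .lm.fit(X, y)
    pcoef <- pooled$coefficients
    pcoef[is.na(pcoef)] <- 0
    pres <- y - drop(X %*% pcoef)
    psig <- max(mean(pres^2), VAR_FLOOR)
    coef <- matrix(rep(pcoef, each = cfg$q), nrow = cfg$q,
                   dimnames = list(NULL, colnames(X)))
    sigma2 <- rep(psig, cfg$q)
    fallback <- rep(FALSE, cfg$q)
    ll <- 0
    if (cfg$q == 1L) {
      sigma2[1] <- psig
      ll <- -n / 2 * (1 + log(2 * pi * psig))
    } else {
      groups <- split(seq_len(n), cfg$idx)
      for (gname in names(groups)) {
        g <- as.integer(gname); rows <- groups[[gname]]; m <- length(rows)
        if (m >= p_col + 1L) {
          f <- .lm.fit(X[rows, , drop = FALSE], y[rows])
          b <- f$coefficients; b[is.na(b)] <- 0
          res <- y[rows] - drop(X[rows, , drop = FALSE] %*% b)
          s2 <- max(mean(res^2), VAR_FLOOR)
          coef[g, ] <- b; sigma2[g] <- s2
        } else {
          # too few rows for this configuration: pooled fallback
          res <- pres[rows]
          s2 <- max(mean(res^2), VAR_FLOOR)
          sigma2[g] <- s2; fallback[g] <- TRUE
          if (m == 0L) next
        }
        ll <- ll - m / 2 * (1 + log(2 * pi * sigma2[g]))
      }
      empty <- setdiff(seq_len(cfg$q), as.integer(names(groups)))
      fallback[empty] <- TRUE
    }
    k <- cfg$q * (length(cpar) + 2)
    out <- list(type = "gaussian", ll = ll, k = k,
                bic = ll - k / 2 * log(n),
                cparents = cpar, dparents = dpar,
                coef = coef, sigma2 = sigma2, fallback = fallback)
  }
  sdat$cache[[key]] <- out
  out
}

#' Decomposable BIC score of a structure on complete data
#'
#' Sum over nodes of the maximized log-likelihood of the node's local
#' conditional linear Gaussian (or multinomial) distribution minus
#' `(k/2) log(n)` with `k` the node's free-parameter count: larger is
#' better. The score decomposes over node families, so structure search
#' only rescores the families a move changes.
#'
#' @param structure a [dag_structure()].
#' @param dataset a complete-data [panel_dataset()] (no missing cells).
#' @param by_node return the per-node score vector instead of the total.
#' @return numeric score (or named vector if `by_node`).
#' @export
bic_score <- function(structure, dataset, by_node = FALSE) {
  if (!all(structure$nodes %in% names(dataset$records)))
    stop("structure refers to variables absent from the dataset")
  sdat <- scored_data(dataset$records[structure$nodes], dataset$specs)
  terms <- vapply(structure$nodes, function(v)
    fit_family(sdat, v, parents_of(structure, v))$bic, numeric(1))
  if (by_node) terms else sum(terms)
}

#' Hybrid Bayesian network
#'
#' Couples a DAG with conditional linear Gaussian parameters and the
#' variable specification.
#'
#' @param structure a [dag_structure()].
#' @param parameters named list of local distributions (one per node), as
#'   produced by [fit_parameters()].
#' @param specs a [variable_spec()] table.
#' @return object of class `hybrid_bn`.
#' @export
hybrid_bn <- function(structure, parameters, specs) {
  missing_par <- setdiff(structure$nodes, names(parameters))
  if (length(missing_par))
    stop("no parameters for node(s): ", paste(missing_par, collapse = ", "))
  for (v in structure$nodes) {
    pa <- sort(parents_of(structure, v))
    got <- sort(c(parameters[[v]]$dparents, parameters[[v]]$cparents))
    if (!identical(pa, got))
      stop("parameters of ", v, " do not match its parent set")
  }
  structure2 <- structure
  obj <- list(structure = structure2, parameters = parameters, specs = specs)
  class(obj) <- "hybrid_bn"
  obj
}

#' @export
print.hybrid_bn <- function(x, ...) {
  nd <- sum(vapply(x$parameters, function(p) p$type == "discrete", logical(1)))
  cat("hybrid_bn:", length(x$structure$nodes), "nodes (", nd, "discrete ),",
      nrow(x$structure$arcs), "arcs\n")
  invisible(x)
}

#' Maximum-likelihood parameters for a structure on complete data
#'
#' Conditional probability tables are empirical frequencies; linear
#' Gaussian locals are per-configuration least-squares fits with the
#' maximum-likelihood residual variance (floored at 1e-9). Discrete-parent
#' configurations with fewer rows than continuous parents plus two fall
#' back to the pooled (configuration-marginal) fit and are flagged.
#'
#' @param structure a [dag_structure()].
#' @param dataset a complete-data [panel_dataset()].
#' @return a [hybrid_bn()].
#' @export
fit_parameters <- function(structure, dataset) {
  if (!all(structure$nodes %in% names(dataset$records)))
    stop("structure refers to variables absent from the dataset")
  sdat <- scored_data(dataset$records[structure$nodes], dataset$specs)
  params <- lapply(stats::setNames(structure$nodes, structure$nodes), function(v) {
    fam <- fit_family(sdat, v, parents_of(structure, v))
    if (fam$type == "discrete") {
      list(type = "discrete", dparents = fam$dparents, cparents = character(),
           cpt = fam$cpt, levels = spec_levels(dataset$specs, v))
    } else {
      list(type = "gaussian", dparents = fam$dparents, cparents = fam$cparents,
           coef = fam$coef, sigma2 = fam$sigma2, fallback = fam$fallback)
    }
  })
  hybrid_bn(structure, params, dataset$specs[match(structure$nodes,
                                                   dataset$specs$name), ])
}

# configuration index of discrete parent values held in a data.frame
config_index_df <- function(records, specs, dparents) {
  n <- nrow(records)
  if (!length(dparents)) return(rep.int(1L, n))
  idx <- rep.int(1L, n); mult <- 1L
  for (p in dparents) {
    lv <- spec_levels(specs, p)
    idx <- idx + (as.integer(factor(records[[p]], levels = lv)) - 1L) * mult
    mult <- mult * length(lv)
  }
  idx
}

# vectorized per-row log density contributions of one node
node_logdens <- function(bn, records, v) {
  par <- bn$parameters[[v]]
  idx <- config_index_df(records, bn$specs, par$dparents)
  if (par$type == "discrete") {
    lv <- par$levels %||% spec_levels(bn$specs, v)
    ci <- as.integer(factor(records[[v]], levels = lv))
    if (anyNA(ci) && !anyNA(records[[v]]))
      stop("value outside declared levels of ", v)
    p <- par$cpt[cbind(idx, ci)]
    log(pmax(p, 1e-300))
  } else {
    mu <- par$coef[idx, 1]
    for (p in par$cparents)
      mu <- mu + par$coef[idx, p] * as.numeric(records[[p]])
    s2 <- par$sigma2[idx]
    -0.5 * (log(2 * pi * s2) + (as.numeric(records[[v]]) - mu)^2 / s2)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-likelihood of complete observations under a hybrid network
#'
#' @param bn a [hybrid_bn()].
#' @param row a one-row data.frame (or list) covering the network's
#'   variables, with no missing values.
#' @return the log joint density/probability of the row.
#' @export
loglik <- function(bn, row) {
  row <- as.data.frame(row)
  vars <- bn$structure$nodes
  if (anyNA(row[vars])) stop("loglik requires a complete row")
  sum(vapply(vars, function(v) node_logdens(bn, row, v), numeric(1)))
}

#' Total log-likelihood of a complete dataset under a hybrid network
#'
#' @param bn a [hybrid_bn()].
#' @param dataset a complete-data [panel_dataset()].
#' @return total log-likelihood over the rows.
#' @export
loglik_dataset <- function(bn, dataset) {
  vars <- bn$structure$nodes
  rec <- dataset$records
  if (anyNA(rec[vars])) stop("loglik_dataset requires complete data")
  tot <- 0
  for (v in vars) tot <- tot + sum(node_logdens(bn, rec, v))
  tot
}
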