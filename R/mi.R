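# Jackknife bias-corrected mutual information between two variables,
# computed on complete cases. Plug-in estimators by kind pair:
#  - discrete-discrete: empirical cell frequencies;
#  - continuous-continuous: Gaussian-model MI, -0.5 * log(1 - r^2);
#  - mixed: difference of pooled and per-level Gaussian entropies.
# Bias correction: n * theta_hat - (n - 1) * mean(leave-one-out estimates);
# the jackknife standard error is returned alongside.

mi_disc_disc <- function(xi, yi, rx, ry) {
  n <- length(xi)
  cell <- (xi - 1L) * ry + yi
  counts <- tabulate(cell, nbins = rx * ry)
  cm <- matrix(counts, nrow = rx, byrow = TRUE)
  plugin <- function(cm, n) {
    rs <- rowSums(cm); cs <- colSums(cm)
    nz <- cm > 0
    sum(cm[nz] / n * log(cm[nz] * n / (rs[row(cm)[nz]] * cs[col(cm)[nz]])))
  }
  theta <- plugin(cm, n)
  # leave-one-out: identical within a cell, so loop over occupied cells
  occ <- which(cm > 0, arr.ind = TRUE)
  loo_vals <- numeric(nrow(occ)); loo_wts <- numeric(nrow(occ))
  for (k in seq_len(nrow(occ))) {
    cm2 <- cm
    cm2[occ[k, 1], occ[k, 2]] <- cm2[occ[k, 1], occ[k, 2]] - 1L
    loo_vals[k] <- plugin(cm2, n - 1L)
    loo_wts[k] <- cm[occ[k, 1], occ[k, 2]]
  }
  list(theta = theta, loo_mean = sum(loo_vals * loo_wts) / n,
       loo_var = sum(loo_wts * (loo_vals - sum(loo_vals * loo_wts) / n)^2))
}

mi_cont_cont <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  r_from <- function(n, sx, sy, sxx, syy, sxy) {
    vx <- sxx - sx^2 / n; vy <- syy - sy^2 / n
    cv <- sxy - sx * sy / n
    r2 <- cv^2 / pmax(vx * vy, 1e-300)
    pmin(r2, 1 - 1e-12)
  }
  theta <- -0.5 * log(1 - r_from(n, sx, sy, sxx, syy, sxy))
  r2i <- r_from(n - 1L, sx - x, sy - y, sxx - x^2, syy - y^2, sxy - x * y)
  loo <- -0.5 * log(1 - r2i)
  list(theta = theta, loo_mean = mean(loo),
       loo_var = sum((loo - mean(loo))^2))
}

mi_mixed <- function(di, x, r) {
  n <- length(x)
  S <- sum(x); SS <- sum(x^2)
  nl <- tabulate(di, nbins = r)
  Sl <- vapply(seq_len(r), function(l) sum(x[di == l]), numeric(1))
  SSl <- vapply(seq_len(r), function(l) sum(x[di == l]^2), numeric(1))
  varml <- function(s, ss, m) pmax(ss / m - (s / m)^2, 1e-12)
  plugin <- function(S, SS, n, Sl, SSl, nl) {
    keep <- nl > 0
    0.5 * log(varml(S, SS, n)) -
      sum(nl[keep] / n * 0.5 * log(varml(Sl[keep], SSl[keep], nl[keep])))
  }
  theta <- plugin(S, SS, n, Sl, SSl, nl)
  loo <- numeric(n)
  # per-level log-variance sum, adjusted for the removed observation
  base_terms <- ifelse(nl > 0, nl * 0.5 * log(varml(Sl, SSl, pmax(nl, 1L))), 0)
  for (i in seq_len(n)) {
    l <- di[i]
    nl2 <- nl; nl2[l] <- nl2[l] - 1L
    Sl2 <- Sl[l] - x[i]; SSl2 <- SSl[l] - x[i]^2
    term_l <- if (nl2[l] > 0) nl2[l] * 0.5 * log(varml(Sl2, SSl2, nl2[l])) else 0
    cond <- (sum(base_terms) - base_terms[l] + term_l) / (n - 1L)
    loo[i] <- 0.5 * log(varml(S - x[i], SS - x[i]^2, n - 1L)) - cond
  }
  list(theta = theta, loo_mean = mean(loo),
       loo_var = sum((loo - mean(loo))^2))
}

#' Jackknife bias-corrected mutual information
#'
#' @param x,y paired observations; rows with a missing value in either are
#'   excluded first. Factors are treated as discrete, numerics as
#'   continuous.
#' @param min_pairs minimum number of complete pairs required (default 10).
#' @return list of class `mi_jackknife` with `mi` (bias-corrected
#'   estimate, nats), `plugin`, `se` (jackknife standard error), `n`
#'   (complete pairs used), `flag` (`"constant"` when either variable is
#'   degenerate, in which case `mi` is 0).
#' @export
mi_jackknife <- function(x, y, min_pairs = 10L) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < min_pairs) stop("need at least ", min_pairs, " complete pairs, got ", n)
  out <- function(res, flag = NA_character_) {
    se <- sqrt((n - 1) / n * res$loo_var)
    structure(list(mi = n * res$theta - (n - 1) * res$loo_mean,
                   plugin = res$theta, se = se, n = n, flag = flag),
              class = "mi_jackknife")
  }
  degenerate <- function(v)
    if (is.factor(v)) length(unique(v)) < 2L else stats::var(v) < 1e-12
  if (degenerate(x) || degenerate(y))
    return(structure(list(mi = 0, plugin = 0, se = 0, n = n, flag = "constant"),
                     class = "mi_jackknife"))
  if (is.factor(x) && is.factor(y)) {
    xi <- as.integer(droplevels(x)); yi <- as.integer(droplevels(y))
    out(mi_disc_disc(xi, yi, max(xi), max(yi)))
  } else if (!is.factor(x) && !is.factor(y)) {
    out(mi_cont_cont(as.numeric(x), as.numeric(y)))
  } else {
    if (is.factor(y)) { tmp <- x; x <- y; y <- tmp }
    di <- as.integer(droplevels(x))
    out(mi_mixed(di, as.numeric(y), max(di)))
  }
}

#' @export
print.mi_jackknife <- function(x, ...) {
  cat(sprintf("MI = %.4f nats (plug-in %.4f, jackknife SE %.4f, n = %d)%s\n",
              x$mi, x$plugin, x$se, x$n,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' @export
as.numeric.mi_jackknife <- function(x, ...) x$mi
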