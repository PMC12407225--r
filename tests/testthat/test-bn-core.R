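# Model class: arc legality, maximum-likelihood fitting, BIC scoring,
# and log density evaluation.

arc_in_test <- function(arcs, from, to) {
  NROW(arcs) > 0 && any(arcs[, 1] == from & arcs[, 2] == to)
}

test_that("arc legality distinguishes tier, class, and cycle violations", {
  sp <- variable_spec(
    c("age", "gender", "habit@T1", "pa@T1", "pa@T2"),
    c("static", "static", "T1", "T1", "T2"),
    c("continuous", "discrete", "continuous", "continuous", "continuous"),
    c("demographic", "demographic", "determinant", "outcome", "outcome"),
    levels = list(NULL, c("f", "m"), NULL, NULL, NULL))
  con <- tiers_from_specs(sp, exogenous_roots = FALSE)
  g <- dag_structure(sp$name)

  backward <- check_arc_legal(g, con, c("pa@T2", "pa@T1"), sp)
  expect_false(as.logical(backward))
  expect_equal(attr(backward, "reason"), "tier")

  cls <- check_arc_legal(g, con, c("age", "gender"), sp)
  expect_false(as.logical(cls))
  expect_equal(attr(cls, "reason"), "class")

  ok <- check_arc_legal(g, con, c("gender", "pa@T1"), sp)
  expect_true(as.logical(ok))

  g2 <- dag_structure(sp$name, rbind(c("habit@T1", "pa@T1")))
  cyc <- check_arc_legal(g2, con, c("pa@T1", "habit@T1"), sp)
  expect_false(as.logical(cyc))
  expect_equal(attr(cyc, "reason"), "cycle")

  expect_error(check_arc_legal(g, con, c("nope", "pa@T1"), sp), "unknown")
})

test_that("maximum-likelihood fits recover CPTs and regression locals", {
  sp <- variable_spec(c("d", "x", "y"), c("T1", "T1", "T1"),
                      c("discrete", "continuous", "continuous"),
                      rep("determinant", 3),
                      levels = list(c("1", "2"), NULL, NULL))
  x <- c(0.5, 1.5, 2.5, 3.5)
  rec <- data.frame(d = c("1", "2", "2", "2"), x = x, y = 3 + 2 * x)
  d <- panel_dataset(rec, sp)
  bn <- fit_parameters(dag_structure(sp$name, rbind(c("x", "y"))), d)
  expect_equal(as.numeric(bn$parameters$d$cpt), c(0.25, 0.75))
  expect_equal(unname(bn$parameters$y$coef[1, ]), c(3, 2), tolerance = 1e-9)
  expect_gte(bn$parameters$y$sigma2[1], 1e-9)  # floored, not zero
})

test_that("sparse discrete-parent configurations fall back to the pooled fit", {
  set.seed(31)
  n <- 60
  g <- factor(c(rep("a", n - 2), rep("b", 2)), levels = c("a", "b"))
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n, 0, 0.3)
  sp <- variable_spec(c("g", "x", "y"), rep("T1", 3),
                      c("discrete", "continuous", "continuous"),
                      rep("determinant", 3),
                      levels = list(c("a", "b"), NULL, NULL))
  d <- panel_dataset(data.frame(g = g, x = x, y = y), sp)
  bn <- fit_parameters(dag_structure(sp$name, rbind(c("g", "y"), c("x", "y"))), d)
  expect_true(bn$parameters$y$fallback[2])
  expect_false(bn$parameters$y$fallback[1])
  # pooled oracle: plain least squares ignoring the configuration
  pooled <- stats::lm(y ~ x)
  expect_equal(unname(bn$parameters$y$coef[2, ]),
               unname(stats::coef(pooled)), tolerance = 1e-9)
})

test_that("empty-graph BIC equals the closed-form per-column sum", {
  set.seed(7)
  df <- as.data.frame(matrix(rnorm(200 * 5), ncol = 5))
  names(df) <- paste0("z", 1:5)
  d <- cont_panel(df)
  got <- bic_score(dag_structure(names(df)), d)
  want <- sum(vapply(df, gaussian_column_bic, numeric(1)))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("an arc between independent columns lowers the score at large n", {
  set.seed(8)
  df <- data.frame(a = rnorm(5000), b = rnorm(5000))
  d <- cont_panel(df)
  empty <- bic_score(dag_structure(names(df)), d)
  with_arc <- bic_score(dag_structure(names(df), rbind(c("a", "b"))), d)
  expect_lt(with_arc, empty)
})

test_that("the score decomposes over node families", {
  set.seed(9)
  for (rep_i in 1:5) {
    g <- rand_dag(5)
    df <- as.data.frame(matrix(rnorm(120 * 5), ncol = 5))
    names(df) <- g$nodes
    d <- cont_panel(df)
    total <- bic_score(g, d)
    per_node <- bic_score(g, d, by_node = TRUE)
    expect_equal(total, sum(per_node))
    # adding one arc changes only the child's family term
    child <- g$nodes[5]; parent <- g$nodes[1]
    if (!arc_in_test(g$arcs, parent, child)) {
      g2 <- tryCatch(dag_structure(g$nodes, rbind(g$arcs, c(parent, child))),
                     error = function(e) NULL)  # skip if the arc closes a cycle
      if (!is.null(g2)) {
        pn2 <- bic_score(g2, d, by_node = TRUE)
        expect_equal(per_node[setdiff(g$nodes, child)],
                     pn2[setdiff(g$nodes, child)])
      }
    }
  }
})

test_that("log density matches closed forms and the independence product", {
  sp <- variable_spec("z", "T1", "continuous", "determinant")
  st <- dag_structure("z")
  bn <- hybrid_bn(st, list(z = list(type = "gaussian", dparents = character(),
                                    cparents = character(),
                                    coef = matrix(0, 1, 1,
                                                  dimnames = list(NULL, "(Intercept)")),
                                    sigma2 = 1)), sp)
  expect_equal(loglik(bn, data.frame(z = 0)), -0.5 * log(2 * pi))

  set.seed(10)
  df <- data.frame(a = rnorm(50), b = rnorm(50))
  d <- cont_panel(df)
  fit <- fit_parameters(dag_structure(names(df)), d)
  want <- sum(dnorm(df$a, mean(df$a), sqrt(mean((df$a - mean(df$a))^2)), log = TRUE)) +
    sum(dnorm(df$b, mean(df$b), sqrt(mean((df$b - mean(df$b))^2)), log = TRUE))
  expect_equal(loglik_dataset(fit, d), want, tolerance = 1e-8)
})

test_that("fitted likelihood agrees with the score's likelihood term and is
           monotone in the arc set", {
  set.seed(11)
  n <- 400
  x <- rnorm(n); y <- 0.6 * x + rnorm(n); z <- 0.5 * y + rnorm(n)
  d <- cont_panel(data.frame(x = x, y = y, z = z))
  nested <- list(
    dag_structure(c("x", "y", "z")),
    dag_structure(c("x", "y", "z"), rbind(c("x", "y"))),
    dag_structure(c("x", "y", "z"), rbind(c("x", "y"), c("y", "z"))))
  ll <- vapply(nested, function(g) loglik_dataset(fit_parameters(g, d), d),
               numeric(1))
  expect_true(all(diff(ll) >= -1e-9))
  # shared code path: BIC = fitted loglik - penalty
  g <- nested[[3]]
  k <- 2 + 3 + 3  # root: mean+var; each regression child: int+slope+var
  expect_equal(bic_score(g, d), ll[3] - k / 2 * log(n), tolerance = 1e-8)
})
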