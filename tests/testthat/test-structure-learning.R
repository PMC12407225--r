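# Hill climbing, the exhaustive oracle, and structural EM.

test_that("independent noise yields the empty graph", {
  set.seed(21)
  df <- as.data.frame(matrix(rnorm(2000 * 4), ncol = 4))
  names(df) <- paste0("n", 1:4)
  d <- cont_panel(df)
  g <- hill_climb(d, tier_constraint(list(names(df))))
  expect_equal(nrow(g$arcs), 0)
})

test_that("a three-variable chain is recovered score-equivalent to truth", {
  set.seed(22)
  n <- 5000
  x <- rnorm(n); y <- 0.8 * x + rnorm(n, 0, 0.6); z <- 0.8 * y + rnorm(n, 0, 0.6)
  d <- cont_panel(data.frame(x = x, y = y, z = z))
  con <- tier_constraint(list(c("x", "y", "z")))
  h <- hill_climb(d, con)
  e <- exhaustive_search(d, con)
  expect_equal(attr(h, "score"), attr(e, "score"), tolerance = 1e-9)
  # truth itself scores no better than the found optimum
  truth_score <- bic_score(dag_structure(c("x", "y", "z"),
                                         rbind(c("x", "y"), c("y", "z"))), d)
  expect_lte(truth_score, attr(h, "score") + 1e-9)
})

test_that("whitelisted arcs are forced into the result", {
  set.seed(23)
  df <- data.frame(a = rnorm(300), b = rnorm(300))
  d <- cont_panel(df)
  con <- tier_constraint(list(c("a", "b")), required = rbind(c("a", "b")))
  g <- hill_climb(d, con)
  expect_true(any(g$arcs[, 1] == "a" & g$arcs[, 2] == "b"))
})

test_that("tier-constrained enumeration has the expected size", {
  sp <- variable_spec(c("a", "b", "c"), c("T1", "T2", "T3"),
                      rep("continuous", 3), rep("determinant", 3))
  con <- tier_constraint(list("a", "b", "c"))
  dags <- enumerate_legal_dags(c("a", "b", "c"), con, sp)
  expect_equal(length(dags), 8)  # each of the 3 forward arcs in or out
})

test_that("hill climbing attains the exhaustive optimum on random instances", {
  set.seed(24)
  for (i in 1:10) {
    d <- rand_clg_panel(sample(3:4, 1), n = 250, with_binary = i %% 3 == 0)
    con <- tier_constraint(list(names(d$records)))
    h <- hill_climb(d, con)
    e <- exhaustive_search(d, con)
    expect_gte(attr(e, "score") + 1e-9, attr(h, "score"))
    expect_equal(attr(h, "score"), attr(e, "score"), tolerance = 1e-6)
  }
})

test_that("structural EM on complete data is exactly hill climb plus fit", {
  cfg <- config_stability(300)
  cfg$missing_cell_rate <- 0
  p <- generate_panel(cfg, seed = 31)
  con <- tiers_from_specs(p$specs)
  em <- structural_em(p, con)
  hc <- hill_climb(p, con)
  expect_identical(em$structure$arcs[order(em$structure$arcs[, 1]), ],
                   hc$arcs[order(hc$arcs[, 1]), ])
  expect_equal(em$scores, attr(hc, "score"))
  expect_equal(em$iterations, 1L)
  expect_true(em$converged)
})

test_that("structural EM recovers the chain skeleton under 20% MCAR", {
  set.seed(32)
  n <- 2000
  x <- rnorm(n); y <- 0.9 * x + rnorm(n, 0, 0.6); z <- 0.9 * y + rnorm(n, 0, 0.6)
  rec <- data.frame(x = x, y = y, z = z)
  sp <- variable_spec(names(rec), c("T1", "T2", "T3"),
                      rep("continuous", 3), rep("determinant", 3))
  d <- panel_dataset(rec, sp)
  d <- inject_mcar(d, 0.2, seed = 33)
  expect_gt(mean(is.na(d$records$x)), 0.15)
  em <- structural_em(d, tier_constraint(list("x", "y", "z")))
  skel <- apply(em$structure$arcs, 1, function(a) paste(sort(a), collapse = "~"))
  expect_setequal(skel, c("x~y", "y~z"))
  # accepted-iteration score log is non-decreasing
  expect_true(all(diff(em$scores) >= 0))
})

test_that("every structure returned by search respects the constraint", {
  cfg <- config_recovery(400)
  p <- generate_panel(cfg, seed = 35)
  p <- inject_mcar(p, 0.15, seed = 36)
  con <- tiers_from_specs(p$specs)
  em <- structural_em(p, con)
  sp <- p$specs
  for (i in seq_len(nrow(em$structure$arcs))) {
    arc <- em$structure$arcs[i, ]
    g_minus <- dag_structure(em$structure$nodes,
                             em$structure$arcs[-i, , drop = FALSE])
    expect_true(as.logical(check_arc_legal(g_minus, con, arc, sp)))
  }
})

test_that("fitted coefficients recover the generating values", {
  cfg <- config_recovery(2000)
  bn0 <- build_ground_truth(cfg)
  p <- generate_panel(cfg, seed = 37)
  fit <- fit_parameters(bn0$structure, p)
  checks <- 0L; within <- 0L
  for (v in bn0$structure$nodes) {
    par0 <- bn0$parameters[[v]]
    if (par0$type != "gaussian" || !length(par0$cparents)) next
    # lm on the first discrete-parent configuration as the independent
    # oracle for both the estimate and its standard error
    rows <- rep(TRUE, nrow(p$records))
    for (dp in par0$dparents)
      rows <- rows & p$records[[dp]] == levels(p$records[[dp]])[1]
    dd <- p$records[rows, c(v, par0$cparents), drop = FALSE]
    names(dd) <- make.names(names(dd))
    f <- stats::lm(stats::reformulate(names(dd)[-1], names(dd)[1]), dd)
    sm <- summary(f)$coefficients
    for (cp in par0$cparents) {
      se <- sm[make.names(cp), "Std. Error"]
      est <- fit$parameters[[v]]$coef[1, cp]
      truth <- par0$coef[1, cp]
      checks <- checks + 1L
      if (abs(est - truth) <= 3 * se) within <- within + 1L
      # the package's per-configuration fit equals the lm oracle
      expect_equal(unname(est), unname(sm[make.names(cp), "Estimate"]),
                   tolerance = 1e-8)
    }
  }
  expect_gte(within / checks, 0.95)
})
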