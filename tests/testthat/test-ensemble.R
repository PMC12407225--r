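# Bootstrap averaging, the confidence threshold and tie rules, SHD, and
# stability selection of the bootstrap count.

mk3 <- function(arcs = NULL) dag_structure(c("A", "B", "C"), arcs)

rep_structs <- function(...) {
  spec <- list(...)
  out <- list()
  for (s in spec) out <- c(out, replicate(s$k, mk3(s$arcs), simplify = FALSE))
  out
}

test_that("the 60% presence threshold is an inclusive boundary", {
  retained <- average_network(rep_structs(list(k = 90, arcs = rbind(c("A", "B"))),
                                          list(k = 60, arcs = NULL)), 0.6)
  expect_equal(nrow(retained$arcs), 1)
  expect_equal(retained$arcs$presence_conf, 0.6)

  dropped <- average_network(rep_structs(list(k = 89, arcs = rbind(c("A", "B"))),
                                         list(k = 61, arcs = NULL)), 0.6)
  expect_equal(nrow(dropped$arcs) + nrow(dropped$undirected), 0)
})

test_that("an exact direction tie yields an undirected edge", {
  av <- average_network(rep_structs(list(k = 45, arcs = rbind(c("A", "B"))),
                                    list(k = 45, arcs = rbind(c("B", "A"))),
                                    list(k = 60, arcs = NULL)), 0.6)
  expect_equal(nrow(av$arcs), 0)
  expect_equal(nrow(av$undirected), 1)
  expect_equal(av$undirected$presence_conf, 0.6)
  # a near-tie stays directed by majority
  av2 <- average_network(rep_structs(list(k = 46, arcs = rbind(c("A", "B"))),
                                     list(k = 45, arcs = rbind(c("B", "A"))),
                                     list(k = 59, arcs = NULL)), 0.6)
  expect_equal(nrow(av2$arcs), 1)
  expect_equal(av2$arcs$from, "A")
})

test_that("raising the threshold never adds edges, and confidence is
           invariant to sample relabeling", {
  set.seed(41)
  pool <- rep_structs(
    list(k = 70, arcs = rbind(c("A", "B"), c("B", "C"))),
    list(k = 20, arcs = rbind(c("A", "B"))),
    list(k = 10, arcs = NULL))
  lo <- average_network(pool, 0.6)
  hi <- average_network(pool, 0.9)
  edges_of <- function(x) c(paste(x$arcs$from, x$arcs$to),
                            paste(x$undirected$a, x$undirected$b))
  expect_true(all(edges_of(hi) %in% edges_of(lo)))
  shuffled <- pool[sample(length(pool))]
  expect_equal(average_network(shuffled, 0.6)$confidence,
               lo$confidence)
})

test_that("structural Hamming distance matches hand-computed edit counts", {
  gAB_BC <- mk3(rbind(c("A", "B"), c("B", "C")))
  cases <- list(
    list(a = gAB_BC, b = gAB_BC, want = 0),                          # identical
    list(a = gAB_BC, b = mk3(rbind(c("A", "B"))), want = 1),         # deletion
    list(a = gAB_BC, b = mk3(rbind(c("B", "A"), c("B", "C"))), want = 1),  # reversal
    list(a = mk3(), b = mk3(), want = 0),
    list(a = mk3(), b = gAB_BC, want = 2),                           # two additions
    list(a = mk3(rbind(c("A", "C"))), b = mk3(rbind(c("C", "A"))), want = 1),
    list(a = mk3(rbind(c("A", "B"), c("A", "C"))),
         b = mk3(rbind(c("B", "A"), c("C", "A"))), want = 2),        # two reversals
    list(a = mk3(rbind(c("A", "B"))), b = mk3(rbind(c("B", "C"))), want = 2),
    list(a = gAB_BC, b = mk3(rbind(c("A", "B"), c("B", "C"), c("A", "C"))), want = 1),
    list(a = mk3(rbind(c("A", "C"), c("B", "C"))), b = gAB_BC, want = 2))
  for (cs in cases) expect_equal(shd(cs$a, cs$b), cs$want)
  # undirected-vs-directed counts one edit
  und <- average_network(rep_structs(list(k = 5, arcs = rbind(c("A", "B"))),
                                     list(k = 5, arcs = rbind(c("B", "A")))), 0.6)
  dir_ <- average_network(rep_structs(list(k = 10, arcs = rbind(c("A", "B")))), 0.6)
  expect_equal(shd(und, dir_), 1)
  expect_error(shd(gAB_BC, dag_structure(c("A", "B"))), "node sets")
})

test_that("bootstrap structure lists are deterministic and reducible to a
           single run", {
  cfg <- config_stability(150)
  p <- generate_study(cfg, seed = 51)$panel
  con <- tiers_from_specs(p$specs)
  st <- search_settings()
  b1 <- bootstrap_structures(p, con, st, B = 3, seed = 99)
  b2 <- bootstrap_structures(p, con, st, B = 3, seed = 99)
  for (i in 1:3) expect_identical(b1[[i]]$arcs, b2[[i]]$arcs)
  # diagnostic mode: B = 1 without resampling equals one structural EM run
  b0 <- bootstrap_structures(p, con, st, B = 1, seed = 99, resample = FALSE)
  em <- structural_em(p, con, search_settings(seed = 99))
  expect_identical(b0[[1]]$arcs, em$structure$arcs)
  # counter-derived seeds: a longer run extends the shorter one
  b5 <- bootstrap_structures(p, con, st, B = 5, seed = 99)
  for (i in 1:3) expect_identical(b5[[i]]$arcs, b1[[i]]$arcs)
})

test_that("a strong dependence reaches full presence confidence", {
  set.seed(52)
  n <- 1000
  x <- rnorm(n); y <- 2 * x + rnorm(n, 0, 0.1)
  sp <- variable_spec(c("x", "y"), c("T1", "T2"),
                      c("continuous", "continuous"), rep("determinant", 2))
  d <- panel_dataset(data.frame(x = x, y = y), sp)
  st <- bootstrap_structures(d, tier_constraint(list("x", "y")),
                             search_settings(), B = 50, seed = 1)
  n_with_arc <- sum(vapply(st, function(s) nrow(s$arcs) == 1, logical(1)))
  expect_equal(n_with_arc, 50)
  conf <- arc_confidence(st)
  expect_equal(conf$presence_conf, 1.0)
})

test_that("stability selection validates its grid", {
  cfg <- config_stability(100)
  p <- generate_study(cfg, seed = 53)$panel
  con <- tiers_from_specs(p$specs)
  expect_error(stability_select_B(p, con, B_grid = c(10)), "two values")
  expect_error(stability_select_B(p, con, B_grid = c(20, 10)), "increasing")
})
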