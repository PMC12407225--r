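# Generator: ground-truth validation, forward sampling, item rendering,
# and study-driven structural missingness.

tiny_config <- function(arcs, slope = 2, sigma_y = 0.1) {
  sp <- variable_spec(c("x@T1", "y@T2"), c("T1", "T2"),
                      c("continuous", "continuous"),
                      c("determinant", "outcome"))
  network <- list(arcs = arcs,
                  coef = data.frame(from = arcs[, 1], to = arcs[, 2],
                                    value = slope, stringsAsFactors = FALSE),
                  intercept = c("x@T1" = 0, "y@T2" = 0),
                  sigma = c("x@T1" = 1, "y@T2" = sigma_y),
                  cpt = list())
  synthetic_config(n_participants = 100, specs = sp, network = network)
}

test_that("ground truths violating the time dimension are rejected by name", {
  expect_error(tiny_config(rbind(c("y@T2", "x@T1"))),
               "tier violation.*y@T2 -> x@T1")
  expect_silent(cfg <- tiny_config(rbind(c("x@T1", "y@T2"))))
})

test_that("the intervention variable is forced to be a root", {
  cfg <- config_recovery(100)
  bn <- build_ground_truth(cfg)
  expect_false("intervention" %in% bn$structure$arcs[, 2])
  # and a config that tries anyway is refused
  bad <- cfg$network
  bad$arcs <- rbind(bad$arcs, c("selfeff@T0", "intervention"))
  expect_error(
    synthetic_config(n_participants = 100, specs = cfg$specs, network = bad),
    "root|tier|class")
})

test_that("forward sampling is deterministic and honors the local models", {
  cfg <- tiny_config(rbind(c("x@T1", "y@T2")))
  bn <- build_ground_truth(cfg)
  expect_error(simulate_panel(bn, 0), "positive")
  a <- simulate_panel(bn, 500, seed = 5)
  b <- simulate_panel(bn, 500, seed = 5)
  expect_identical(a$records, b$records)
  # OLS oracle: regression of y on x recovers the generating slope
  fit <- stats::lm(a$records[["y@T2"]] ~ a$records[["x@T1"]])
  expect_lt(abs(unname(stats::coef(fit)[2]) - 2), 0.05)
})

test_that("with no moderator effects every subgroup shares one network", {
  cfg <- config_moderated(800)
  cfg$moderator_effects <- list()
  bn <- build_ground_truth(cfg)
  p1 <- generate_panel(cfg, seed = 3, n = 800)
  p2 <- simulate_panel(bn, 800, seed = 3)
  expect_identical(p1$records, p2$records)
})

test_that("moderator edits change the oracle partial correlations exactly
           at the edited arc", {
  cfg <- config_moderated(12000)
  p <- generate_panel(cfg, seed = 17)
  rec <- p$records
  pcor <- function(rows, y, x, given) {
    d <- rec[rows, c(y, x, given)]
    G <- as.matrix(d[given])
    ry <- stats::resid(stats::lsfit(G, d[[y]]))
    rx <- stats::resid(stats::lsfit(G, d[[x]]))
    stats::cor(ry, rx)
  }
  young <- rec$agegroup == "under65"
  old <- rec$agegroup == "65plus"
  given <- c("intention@T2", "pa@T2")
  edited_y <- pcor(young, "pa@T3", "habit@T1", given)
  edited_o <- pcor(old, "pa@T3", "habit@T1", given)
  expect_gt(edited_y, 0.3)            # arc present for the younger group
  expect_lt(abs(edited_o), 0.06)      # absent for the older group
  # an unedited arc keeps the same strength in both subgroups
  keep_y <- pcor(young, "intention@T2", "selfeff@T1", "habit@T1")
  keep_o <- pcor(old, "intention@T2", "selfeff@T1", "habit@T1")
  expect_lt(abs(keep_y - keep_o), 0.06)
})

test_that("item rendering round-trips noiselessly and respects scale bounds", {
  sp <- variable_spec(c("c@T1", "pa@T1"), c("T1", "T1"),
                      c("continuous", "continuous"),
                      c("determinant", "outcome"))
  network <- list(arcs = NULL, coef = NULL,
                  intercept = c("c@T1" = 3, "pa@T1" = 100),
                  sigma = c("c@T1" = 0.8, "pa@T1" = 10), cpt = list())
  concepts <- data.frame(name = "c@T1", items_per_concept = 1L, scale_max = 5L)
  cfg <- synthetic_config(n_participants = 200, specs = sp, network = network,
                          concepts = concepts, missing_item_rate = 0,
                          item_noise_sd = 0)
  bn <- build_ground_truth(cfg)
  d <- simulate_panel(bn, 200, seed = 2)
  items <- render_items(d, cfg, seed = 3)
  back <- aggregate_items(items, sp)
  # single noiseless item: concept recovered up to rounding and clipping
  expect_equal(back$records[["c@T1"]],
               pmin(pmax(floor(d$records[["c@T1"]] + 0.5), 1), 5))
  expect_true(all(items[["c@T1#1"]] >= 1 & items[["c@T1#1"]] <= 5))
  # pass-through column untouched
  expect_identical(back$records[["pa@T1"]], d$records[["pa@T1"]])

  cfg$missing_item_rate <- 1
  items_gone <- render_items(d, cfg, seed = 4)
  back_gone <- aggregate_items(items_gone, sp)
  expect_true(all(is.na(back_gone$records[["c@T1"]])))

  cfg$missing_item_rate <- 0
  cfg$item_noise_sd <- 2
  noisy <- render_items(d, cfg, seed = 5)
  expect_true(all(noisy[["c@T1#1"]] >= 1 & noisy[["c@T1#1"]] <= 5))
})

test_that("structural missingness blanks whole variables by study", {
  fx <- study_fixture()
  panel <- fx$study$panel
  # a variable measured at that wave by no synthetic study: zero
  # observations, flagged for downstream exclusion
  expect_equal(sum(!is.na(panel$records[["habit@T1"]])), 0)
  expect_true("habit@T1" %in% drop_unobserved_variables(panel)$dropped)

  # empty pattern leaves the dataset unchanged
  cfg0 <- fx$config
  cfg0$missing_wave_pattern <- list()
  complete <- fx$study$complete
  expect_identical(inject_structural_missingness(complete, cfg0)$records,
                   complete$records)

  # observed rate per variable matches the study-mix expectation
  blanked <- inject_structural_missingness(complete, fx$config)
  for (v in c("intention@T1", "self_efficacy@T2", "habit@T3")) {
    expected <- sum(fx$config$study_mix[fx$config$missing_wave_pattern[[v]]])
    expect_lt(abs(mean(!is.na(blanked$records[[v]])) - expected), 0.02)
  }

  # unknown variable in the pattern is refused
  cfg_bad <- fx$config
  cfg_bad$missing_wave_pattern <- list(nonexistent = 1:2)
  expect_error(inject_structural_missingness(complete, cfg_bad), "unknown")
})
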