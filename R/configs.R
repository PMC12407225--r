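# Shipped synthetic-study configurations. `config_study()` emulates the
# statistical structure of the integrated multi-study intervention panel
# (12 determinant concepts plus the MVPA outcome over four waves, five
# synthetic studies with the per-variable availability pattern, item-based
# concept scores). The smaller fixtures back the validation studies:
# `config_recovery()` for structure recovery, `config_stability()` for
# bootstrap-count stability, `config_moderated()` for the planted
# moderation end-to-end check. Coefficients are arbitrary but fixed and
# chosen so the respective ground truth is identifiable at the shipped
# sample size.

coef_row <- function(from, to, value) {
  data.frame(from = from, to = to, value = value, stringsAsFactors = FALSE)
}

concept_names <- function() {
  c("self_efficacy", "attitude_pros", "attitude_cons", "intrinsic_motivation",
    "intention", "commitment", "strategic_planning", "action_planning",
    "coping_planning", "habit", "social_modeling", "social_support")
}

# Table of wave availability per variable: which synthetic studies (1..5)
# measured it at which wave. Mirrors the integration pattern of the five
# source studies; variables measured by no study at a wave are still part
# of the ground truth but end up fully unobserved.
study_availability <- function() {
  list(
    self_efficacy        = list(T0 = 1:5, T1 = c(1, 2, 3, 5), T2 = 5, T3 = 4),
    attitude_pros        = list(T0 = 1:5, T1 = c(1, 2, 3, 5), T2 = 5, T3 = 4),
    attitude_cons        = list(T0 = 1:5, T1 = c(1, 2, 3, 5), T2 = 5, T3 = 4),
    intrinsic_motivation = list(T0 = c(1, 2, 5), T1 = c(1, 2), T2 = 5, T3 = integer()),
    intention            = list(T0 = 1:5, T1 = c(1, 2, 3), T2 = c(1, 2, 4, 5), T3 = c(1, 2, 4, 5)),
    commitment           = list(T0 = c(1, 2), T1 = c(1, 2), T2 = c(1, 2), T3 = integer()),
    strategic_planning   = list(T0 = 1:5, T1 = c(1, 2), T2 = c(1, 2, 5), T3 = c(1, 4)),
    action_planning      = list(T0 = c(1, 2, 5), T1 = c(1, 2), T2 = c(1, 2, 5), T3 = integer()),
    coping_planning      = list(T0 = c(1, 2, 5), T1 = c(1, 2), T2 = c(1, 2, 5), T3 = integer()),
    habit                = list(T0 = c(1, 2, 4, 5), T1 = integer(), T2 = c(1, 2, 4, 5), T3 = c(1, 2, 4, 5)),
    social_modeling      = list(T0 = 1:5, T1 = c(1, 2, 3), T2 = c(1, 3), T3 = 4),
    social_support       = list(T0 = 1:5, T1 = c(1, 2, 3), T2 = c(3, 5), T3 = 4),
    pa                   = list(T0 = 1:5, T1 = c(1, 2, 3, 5), T2 = 1:5, T3 = c(1, 2, 4, 5))
  )
}

#' Full synthetic study configuration
#'
#' Emulates the integrated five-study intervention panel: ~3000
#' participants, randomized binary intervention (about 1 control : 3
#' intervention), demographics (gender, 3-level education, physical
#' activity impairment, age in years truncated to 50-90, with the two
#' 65-plus-targeted studies contributing only older participants), 12
#' determinant concepts plus the weekly-MVPA-minutes outcome at waves
#' T0-T3, per-study variable availability, and item-based concept scores
#' (5-point items, 10-point for intention).
#'
#' @param n_participants number of participants (default 3000).
#' @param seed default seed.
#' @return a [synthetic_config()].
#' @export
config_study <- function(n_participants = 3000L, seed = 2024L) {
  waves <- c("T0", "T1", "T2", "T3")
  cn <- concept_names()
  wave_vars <- as.vector(outer(c(cn, "pa"), waves, paste, sep = "@"))
  statics <- c("study", "intervention", "gender", "education", "impairment", "age")
  specs <- variable_spec(
    name = c(statics, wave_vars),
    timeslot = c(rep("static", length(statics)),
                 rep(waves, each = length(cn) + 1L)),
    kind = c("discrete", "discrete", "discrete", "discrete", "discrete",
             "continuous", rep("continuous", length(wave_vars))),
    role = c(rep("demographic", 1), "intervention", rep("demographic", 4),
             rep(c(rep("determinant", length(cn)), "outcome"),
                 times = length(waves))),
    levels = c(list(paste0("s", 1:5), c("control", "intervention"),
                    c("female", "male"), c("low", "medium", "high"),
                    c("no", "yes"), NULL),
               vector("list", length(wave_vars))))

  arcs <- NULL; coef <- NULL
  add <- function(from, to, value) {
    arcs <<- rbind(arcs, c(from, to))
    coef <<- rbind(coef, coef_row(from, to, value))
  }
  # statics
  add("study", "impairment", NA)  # via CPT, coefficient unused
  add("study", "age", NA)         # via per-configuration intercepts
  # demographic effects on the baseline
  add("age", "pa@T0", -4)
  add("impairment", "pa@T0", -120)
  add("gender", "pa@T0", 30)
  add("education", "intention@T0", 0.3)
  # autoregressive continuity
  for (c0 in c(cn, "pa")) for (k in 1:3)
    add(paste0(c0, "@", waves[k]), paste0(c0, "@", waves[k + 1]),
        if (c0 == "pa") 0.5 else 0.5)
  # within-wave determinant staging (premotivational -> motivational ->
  # postmotivational -> behavior, social concepts feeding in)
  for (w in waves) {
    v <- function(c0) paste0(c0, "@", w)
    add(v("social_support"), v("self_efficacy"), 0.15)
    add(v("self_efficacy"), v("intention"), 0.35)
    add(v("attitude_pros"), v("intention"), 0.30)
    add(v("attitude_cons"), v("intention"), -0.25)
    add(v("intrinsic_motivation"), v("intention"), 0.25)
    add(v("social_modeling"), v("intention"), 0.20)
    add(v("intention"), v("commitment"), 0.12)
    add(v("intention"), v("strategic_planning"), 0.12)
    add(v("intention"), v("action_planning"), 0.10)
    add(v("strategic_planning"), v("coping_planning"), 0.30)
    add(v("action_planning"), v("habit"), 0.25)
    add(v("commitment"), v("habit"), 0.20)
    add(v("intention"), v("pa"), 20)
    add(v("habit"), v("pa"), 50)
  }
  # intervention exposure effects emerge after the baseline
  add("intervention", "self_efficacy@T1", 0.25)
  add("intervention", "attitude_pros@T1", 0.25)
  add("intervention", "attitude_cons@T1", -0.20)
  add("intervention", "intention@T1", 0.50)
  add("intervention", "strategic_planning@T1", 0.25)
  add("intervention", "action_planning@T1", 0.25)
  add("intervention", "self_efficacy@T2", 0.15)
  add("intervention", "intention@T2", 0.30)
  add("intervention", "habit@T2", 0.20)

  intercept <- numeric(); sigma <- numeric()
  for (v in wave_vars) {
    c0 <- sub("@.*$", "", v)
    if (c0 == "pa") { intercept[v] <- 150; sigma[v] <- 250 }
    else if (c0 == "intention") { intercept[v] <- 2.0; sigma[v] <- 1.5 }
    else { intercept[v] <- 1.8; sigma[v] <- 0.7 }
  }
  # roots keep their full marginal location
  for (v in paste0(c("self_efficacy", "attitude_pros", "attitude_cons",
                     "intrinsic_motivation", "social_modeling",
                     "social_support"), "@T0"))
    intercept[v] <- 3.4
  intercept["pa@T0"] <- 900
  intercept["age"] <- 0; sigma["age"] <- 0  # overridden per study below

  cpt <- list(
    study = c(0.30, 0.25, 0.10, 0.15, 0.20),
    intervention = c(0.25, 0.75),
    gender = c(0.55, 0.45),
    education = c(0.30, 0.45, 0.25),
    # impairment given study: the impairment-targeted study recruits
    # almost only impaired participants
    impairment = rbind(c(0.70, 0.30), c(0.70, 0.30), c(0.65, 0.35),
                       c(0.05, 0.95), c(0.60, 0.40)))

  network <- list(
    arcs = arcs, coef = coef, intercept = intercept, sigma = sigma,
    cpt = cpt,
    config_intercept = list(age = c(64, 65, 73, 74, 63)),
    config_sigma = list(age = c(7, 7, 5, 5, 8)),
    trunc = c(list(age = rbind(c(50, 90), c(50, 90), c(65, 90),
                               c(65, 90), c(50, 90))),
              stats::setNames(rep(list(c(0, Inf)), length(waves)),
                              paste0("pa@", waves))))

  pattern <- list()
  avail <- study_availability()
  for (c0 in names(avail)) for (w in waves)
    pattern[[paste0(c0, "@", w)]] <- avail[[c0]][[w]]

  concepts <- data.frame(
    name = as.vector(outer(cn, waves, paste, sep = "@")),
    items_per_concept = rep(ifelse(cn == "intention", 3L, 4L), times = length(waves)),
    scale_max = rep(ifelse(cn == "intention", 10L, 5L), times = length(waves)),
    stringsAsFactors = FALSE)

  synthetic_config(
    n_participants = n_participants, seed = seed, waves = waves,
    specs = specs, network = network, concepts = concepts,
    missing_item_rate = 0.03, item_noise_sd = 0.5,
    missing_wave_pattern = pattern,
    study_mix = cpt$study, study_var = "study")
}

#' Structure-recovery benchmark configuration
#'
#' Twenty variables over four temporal tiers (two static roots plus a
#' baseline wave in the first tier, then T1-T3), 24 cross-tier true arcs
#' with standardized effects large enough to be identifiable at n = 2000.
#'
#' @param n_participants default 2000.
#' @param seed default seed.
#' @return a [synthetic_config()].
#' @export
config_recovery <- function(n_participants = 2000L, seed = 7L) {
  base <- c("selfeff", "intention", "planning", "habit", "pa")
  vars <- c("intervention", "gender",
            paste0(c("selfeff", "intention", "pa"), "@T0"),
            paste0(base, "@T1"), paste0(base, "@T2"), paste0(base, "@T3"))
  specs <- variable_spec(
    name = vars,
    timeslot = c("static", "static", rep("T0", 3), rep("T1", 5),
                 rep("T2", 5), rep("T3", 5)),
    kind = c("discrete", "discrete", rep("continuous", 18)),
    role = c("intervention", "demographic",
             rep(c(rep("determinant", 2), "outcome"), times = 1),
             rep(c(rep("determinant", 4), "outcome"), times = 3)),
    levels = c(list(c("control", "intervention"), c("female", "male")),
               vector("list", 18)))
  arcs <- NULL; coef <- NULL
  add <- function(from, to, value) {
    arcs <<- rbind(arcs, c(from, to))
    coef <<- rbind(coef, coef_row(from, to, value))
  }
  add("intervention", "selfeff@T1", 0.8)
  add("intervention", "planning@T1", 0.8)
  add("intervention", "intention@T1", 0.8)
  add("gender", "pa@T1", 0.5)
  add("selfeff@T0", "selfeff@T1", 0.6)
  add("intention@T0", "intention@T1", 0.6)
  add("pa@T0", "pa@T1", 0.6)
  add("selfeff@T0", "planning@T1", 0.5)
  add("pa@T0", "habit@T1", 0.5)
  add("selfeff@T1", "selfeff@T2", 0.6)
  add("intention@T1", "intention@T2", 0.6)
  add("planning@T1", "intention@T2", 0.4)
  add("planning@T1", "planning@T2", 0.6)
  add("habit@T1", "habit@T2", 0.6)
  add("pa@T1", "pa@T2", 0.5)
  add("habit@T1", "pa@T2", 0.4)
  add("intention@T1", "pa@T2", 0.4)
  add("selfeff@T2", "selfeff@T3", 0.6)
  add("intention@T2", "intention@T3", 0.6)
  add("planning@T2", "planning@T3", 0.6)
  add("habit@T2", "habit@T3", 0.6)
  add("pa@T2", "pa@T3", 0.5)
  add("intention@T2", "pa@T3", 0.4)
  add("habit@T2", "pa@T3", 0.4)
  cont <- vars[-(1:2)]
  network <- list(
    arcs = arcs, coef = coef,
    intercept = stats::setNames(rep(0, length(cont)), cont),
    sigma = stats::setNames(ifelse(grepl("@T0$", cont), 1, 0.8), cont),
    cpt = list(intervention = c(0.5, 0.5), gender = c(0.5, 0.5)))
  synthetic_config(n_participants = n_participants, seed = seed,
                   specs = specs, network = network)
}

#' Bootstrap-stability fixture configuration
#'
#' A five-variable chain with strong effects and mild missingness, on
#' which bootstrap-sample models agree essentially always, so the
#' stability curve of the averaged model plateaus immediately.
#'
#' @param n_participants default 400.
#' @param seed default seed.
#' @return a [synthetic_config()].
#' @export
config_stability <- function(n_participants = 400L, seed = 11L) {
  vars <- c("intervention", "selfeff@T1", "intention@T2", "pa@T2", "pa@T3")
  specs <- variable_spec(
    name = vars,
    timeslot = c("static", "T1", "T2", "T2", "T3"),
    kind = c("discrete", rep("continuous", 4)),
    role = c("intervention", "determinant", "determinant", "outcome", "outcome"),
    levels = c(list(c("control", "intervention")), vector("list", 4)))
  arcs <- rbind(c("intervention", "selfeff@T1"),
                c("selfeff@T1", "intention@T2"),
                c("intention@T2", "pa@T2"),
                c("pa@T2", "pa@T3"))
  coef <- rbind(coef_row("intervention", "selfeff@T1", 0.9),
                coef_row("selfeff@T1", "intention@T2", 0.8),
                coef_row("intention@T2", "pa@T2", 0.8),
                coef_row("pa@T2", "pa@T3", 0.8))
  network <- list(arcs = arcs, coef = coef,
                  intercept = stats::setNames(rep(0, 4), vars[-1]),
                  sigma = stats::setNames(c(1, 0.6, 0.6, 0.6), vars[-1]),
                  cpt = list(intervention = c(0.5, 0.5)))
  synthetic_config(n_participants = n_participants, seed = seed,
                   specs = specs, network = network,
                   missing_cell_rate = 0.1)
}

#' Planted-moderation configuration
#'
#' Two subgroups defined by a binary age-group moderator share a strong
#' seven-arc intervention pathway; the ground truth of the older subgroup
#' lacks exactly one arc (habit at T1 straight into the long-term PA
#' outcome), so its habit effect on long-term PA runs only through
#' intention and previous PA. Every true arc crosses waves, so the
#' temporal tiers compel all orientations and the only difference the
#' subgroup comparison should report is the planted arc with the implied
#' direct-to-indirect role change of habit.
#'
#' @param n_participants total participants over both subgroups
#'   (default 5000, about 2500 per level).
#' @param seed default seed.
#' @return a [synthetic_config()].
#' @export
config_moderated <- function(n_participants = 5000L, seed = 23L) {
  vars <- c("intervention", "agegroup", "selfeff@T1", "habit@T1",
            "intention@T2", "pa@T2", "pa@T3")
  specs <- variable_spec(
    name = vars,
    timeslot = c("static", "static", "T1", "T1", "T2", "T2", "T3"),
    kind = c("discrete", "discrete", rep("continuous", 5)),
    role = c("intervention", "demographic", "determinant", "determinant",
             "determinant", "outcome", "outcome"),
    levels = c(list(c("control", "intervention"), c("under65", "65plus")),
               vector("list", 5)))
  arcs <- rbind(c("intervention", "selfeff@T1"),
                c("intervention", "habit@T1"),
                c("selfeff@T1", "intention@T2"),
                c("habit@T1", "intention@T2"),
                c("habit@T1", "pa@T2"),
                c("intention@T2", "pa@T3"),
                c("pa@T2", "pa@T3"),
                c("habit@T1", "pa@T3"))
  coef <- rbind(coef_row("intervention", "selfeff@T1", 0.8),
                coef_row("intervention", "habit@T1", 0.8),
                coef_row("selfeff@T1", "intention@T2", 0.6),
                coef_row("habit@T1", "intention@T2", 0.5),
                coef_row("habit@T1", "pa@T2", 0.6),
                coef_row("intention@T2", "pa@T3", 0.6),
                coef_row("pa@T2", "pa@T3", 0.6),
                coef_row("habit@T1", "pa@T3", 0.6))
  network <- list(arcs = arcs, coef = coef,
                  intercept = stats::setNames(rep(0, 5), vars[-(1:2)]),
                  sigma = stats::setNames(c(1, 1, 0.7, 0.7, 0.7), vars[-(1:2)]),
                  cpt = list(intervention = c(0.5, 0.5),
                             agegroup = c(0.5, 0.5)))
  synthetic_config(
    n_participants = n_participants, seed = seed, specs = specs,
    network = network, missing_cell_rate = 0.1,
    moderator_effects = list(
      agegroup = list(
        "65plus" = list(remove_arcs = rbind(c("habit@T1", "pa@T3"))))))
}
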