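---
title: "Learning subpopulation intervention networks from longitudinal panel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning subpopulation intervention networks from longitudinal panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Physical-activity (PA) interventions are believed to work by shifting
psycho-social *determinants* — self-efficacy, attitudes, intention,
planning, habit, social support — which in turn shift PA behavior. When
several intervention studies are pooled into one longitudinal panel
(baseline T0 and follow-ups T1–T3), a natural question is whether the
*mechanism* of change differs between demographic subpopulations: younger
versus older participants, lower versus higher educated, with or without
PA impairment. `panelbn` implements a complete, testable pipeline for that
question: learn a Bayesian network per subgroup, stabilize it by bootstrap
model averaging, grade its arcs, distill the intervention→outcome
pathways, and compare the two subgroup fragments.

Because participant-level data of such pooled studies are typically not
redistributable, the package ships a synthetic-data generator with a known
ground-truth network that emulates the statistical structure of this kind
of panel; every claim the test suite makes is made against that known
truth.

## The model class

Each subgroup model is a *temporal hybrid Bayesian network*: a DAG over
static variables (intervention arm, demographics) and wave-stamped
variables (determinant concept scores and the weekly-MVPA-minutes outcome
at T0–T3), with

* multinomial local distributions for discrete nodes (conditional
  probability tables over discrete-parent configurations),
* linear-Gaussian locals for continuous nodes: one intercept, one slope
  per continuous parent and one residual variance per configuration of
  the node's discrete parents,
* no continuous parent of any discrete node (the conditional linear
  Gaussian restriction).

Arcs must be consistent with measurement time: variables are partitioned
into ordered tiers (statics first, then each wave) and any arc from a
later tier into an earlier one is forbidden. By default the intervention
indicator and the demographics are exogenous roots — randomization and
immutability argue against giving them parents — but this is switchable
(`tiers_from_specs(..., exogenous_roots = FALSE)`), since with observed
data only the intervention's rootness is compelled.

Structures are scored by BIC in the "larger is better" convention,
`loglik − (k/2)·log n`, with `k` counted as `(levels − 1) × parent
configurations` for discrete nodes and `continuous parents + 2` per
configuration for continuous nodes. The score decomposes over node
families and family terms are memoized, which is what makes greedy search
and the bootstrap affordable. Fitting is pure maximum likelihood (no
pseudo-counts); residual variances are floored at `1e-9` purely to guard
degenerate synthetic inputs; discrete-parent configurations with fewer
rows than continuous parents + 2 fall back to the pooled
configuration-marginal fit and are flagged.

## Search and missing data

`hill_climb()` walks single-arc additions, deletions and reversals, all
checked for tier, class, blacklist and acyclicity legality, accepting the
best strictly-improving move with lexicographic (child, parent)
tie-breaking so runs are reproducible. When it stalls, a bounded tabu
phase (default `tabu_length = 10` recently visited structures, aspiration
on the best score) is allowed to take non-improving steps before giving
up; random restarts are off by default. `exhaustive_search()` — exact
maximization over topological orders with per-node optimal parent subsets
— serves as the oracle on up to five variables.

Missing values are handled by structural EM (`structural_em()`):
alternate completing the dataset under the current fitted network with
re-running the hill climb and refit on the completed data. Two choices
here deserve explanation because both depart from the most obvious
implementation, and both were forced by observed failures of the obvious
one:

* **The E-step conditions on everything observed.** A cheaper and
  commonly used approximation completes values in one topological sweep,
  each missing cell from its parents only. That leaves the *children* of
  an imputed variable correlated beyond what the network explains (they
  share the unobserved true value), and in our tests this surfaced as
  spurious, unstable within-wave arcs sitting right at the averaging
  threshold. The package therefore computes, per discrete profile, the
  exact joint Gaussian implied by the linear-Gaussian locals and
  conditions it on all observed continuous values of the row (missing
  discrete values, which in practice are the rarer case, are completed
  from their parent configuration first).
* **Completion draws rather than substitutes means by default.**
  Conditional-mean completion (`completion_mode = "expected_value"`) is
  deterministic but systematically understates conditional variance, and
  the completed-data BIC then "discovers" arcs between variables that are
  conditionally independent given an imputed mediator: on a 2000-row
  x→y→z chain with 20% missing cells it reliably added x→z at every seed
  we tried. Drawing the missing values from their exact conditional
  (`"single_draw"`, the default) keeps the completed data properly
  dispersed and recovers exactly the chain. Determinism is preserved
  because every draw is governed by the settings seed, and the bootstrap
  derives per-sample seeds from its master seed.

EM iterations are accepted only if they improve the completed-data BIC;
otherwise the algorithm stops and keeps the best network so far. The
reported score log is therefore non-decreasing *by construction* — the
textbook sequence of scores on changing completions carries no such
guarantee — and non-convergence within `em_max_iter` (default 10) returns
the best-so-far with a flag rather than an error. Convergence is declared
when the per-row score improvement drops below `em_tol` (default `1e-4`).
The initial completion uses column means/modes.

## Bootstrap averaging and stability

`bootstrap_structures()` draws classical Efron resamples (n rows with
replacement), runs structural EM on each, and derives per-sample seeds by
a counter scheme so that growing the bootstrap count extends — never
re-randomizes — the earlier samples. `average_network()` keeps every edge
present (in either orientation) in at least a fraction `threshold` of the
bootstrap models; 0.6 is the analysis default and the boundary is
inclusive (90 of 150 models is retained, 89 is not). Orientation follows
the direction majority; an *exact* tie is reported as an undirected edge,
which is the expected signature of Markov-equivalent orientations. Should
the majority orientations ever close a directed cycle, the
lowest-confidence arc of each cycle is dropped and the repair is flagged
loudly; the repair can be disabled by inspecting the confidence table
directly.

The bootstrap count is chosen by a stability argument
(`stability_select_B()`): over a grid (default 100 to 150 in steps of
10), compute the structural Hamming distance — edge edits, with
directed↔undirected counting one — between averaged networks at
consecutive grid points and take the smallest count whose distance to the
next point is 0 (the tolerance is configurable). If the curve never
plateaus the grid maximum is returned, flagged.

## Arc strength and pathway fragments

Retained edges are graded two ways (`grade_edges()`):

* **Stability** — presence confidence, binned at 0.7 / 0.8 / 0.9 into
  four thickness groups for display.
* **Strength** — jackknife bias-corrected mutual information on the
  complete cases of the endpoint pair, allocated to terciles at the 33%
  and 67% quantiles *of the graded edge set* (ties go to the lower
  group). For continuous pairs the plug-in estimator is the Gaussian
  closed form −½·log(1 − r²); for discrete pairs, empirical cell
  frequencies; for mixed pairs, the difference of pooled and per-level
  Gaussian entropies. The Gaussian form was chosen over a kernel
  estimator deliberately: the learner's model class is Gaussian, so this
  is the internally consistent strength measure — anyone seeking numeric
  parity with kernel-based estimates should expect small differences.
  The jackknife correction `n·θ̂ − (n−1)·mean(θ̂₋ᵢ)` and its standard
  error are computed with vectorized leave-one-out updates.

`extract_fragment()` distills the subgraph of edges lying on at least one
directed path from the intervention variable to the PA outcomes: an edge
qualifies exactly when its tail is reachable from the source and a target
is reachable from its head. Undirected edges are traversable in either
direction by default (they stand for equivalent orientations;
`traversal = "exclude"` disables this). Terciles for a fragment are
computed over the fragment's own edges — grading is relative to the
visualized set — though grading the full network instead is a one-line
change. `classify_role()` calls a node *direct* for a target when the
fragment has an edge from it straight into the target, *indirect* when
the node appears in the fragment without one, *absent* otherwise;
`compare_fragments()` tabulates shared and unique edges and all role
transitions between two subgroup fragments. `to_dot()` renders fragments
with penwidth = thickness group and asterisk labels for the MI tercile.

## The synthetic generator

`synthetic_config()` couples a variable specification with a ground-truth
network recipe, item layout, missingness settings and a synthetic study
mix. The flagship `config_study()` emulates the statistical structure of
a pooled five-study intervention panel:

* ~3000 participants (subgroup cells then land in the 1300–3000 range),
  randomized binary intervention at roughly 1 control : 3 intervention;
* gender, 3-level education, PA impairment, and age in years drawn from
  per-study truncated normals on 50–90, with the two synthetic studies
  that target 65-plus participants contributing only ages ≥65 (one of
  them recruiting almost exclusively impaired participants) — this is
  what makes the availability pattern age-dependent, as in real pooled
  panels;
* 12 determinant concepts plus the MVPA outcome at each of T0–T3, with
  within-wave arcs following the premotivational → motivational →
  postmotivational → behavior staging, autoregressive continuity across
  waves, and intervention effects emerging at T1/T2 (all coefficients
  arbitrary but fixed in code);
* per-variable study availability: a variable is blanked wholesale for
  participants of studies that never measured it at that wave
  (deterministic given the study label, i.e. missing completely at
  random given study), so e.g. habit at T1 has no observations at all,
  and several T3 variables are observed only in the 65-plus studies;
* concept scores rendered as 4 items on 1–5 scales (3 items on 1–10 for
  intention): item = score + Gaussian noise (SD 0.5), rounded half-up and
  clipped, with 3% of items missing at random; aggregation back to
  concept scores is the mean of observed items allowing at most 25%
  missing items, a boundary treated as inclusive.

What the generator does *not* emulate: tailored intervention content,
realistic skewed SQUASH minute distributions (the outcome is plain
Gaussian, clipped at zero; a log-normal variant can be obtained by
transforming the outcome, but the learner treats outcomes as Gaussian, as
the model class prescribes), informative (non-MCAR) item missingness, and
instrument heterogeneity across studies. Passing tests on this generator
therefore demonstrates correctness of the machinery under the model's own
assumptions, not robustness to their violation on real data.

Three smaller shipped configurations back the validation studies, with
sizes chosen so each ground truth is identifiable at its shipped sample
size: `config_recovery()` (20 variables over 4 tiers, 24 cross-tier arcs,
n = 2000 — all true arcs cross tiers so orientations are compelled and
recovery is measured on directed arcs), `config_stability()` (a strong
five-variable chain, n = 400, on which bootstrap models agree and the
stability curve plateaus immediately), and `config_moderated()` (n = 5000
split over a binary age-group moderator whose older level lacks exactly
one arc, habit@T1 → pa@T3). The moderated fixture is deliberately built
without within-wave arcs: an earlier variant with an intention→PA arc
inside one wave produced Markov-equivalence direction flips across
bootstrap samples that smeared confidence onto neighboring pairs — an
instructive failure, but noise for a planted-edit recovery test.

## Numerical choices and degenerate inputs

* Score comparisons use an absolute epsilon of `1e-8`; equal-score moves
  break ties lexicographically.
* Residual-variance floor `1e-9`; MI correlation magnitudes are clamped
  away from 1; constant columns get MI 0 with a `"constant"` flag.
* Empty subsets, empty fragments and predicates matching nobody warn and
  return well-formed empty objects rather than erroring.
* A failed bootstrap sample is retried with a fresh derived seed (at most
  3 attempts) and only then aborts.
* All randomness flows from user-supplied integer seeds; derived seeds
  use a counter scheme modulo 2³¹ − 1.

## Problem sizes used in the validation suite

The shipped tests run the full machinery at deliberately moderate sizes —
the recovery study at n = 2000 with 100 bootstrap samples, the moderation
study at n = 5000 with 30, stability selection up to B = 150 on a
five-variable chain — chosen as the smallest sizes at which the
respective ground truths are comfortably identifiable, so the suite
exercises every stage end-to-end on one CPU.

## Known limitations

* The E-step treats missing discrete values by hard assignment from the
  parent configuration, not by posterior weighting over levels; in the
  shipped study designs discrete variables (demographics, intervention,
  study) are fully observed, so this path is exercised only lightly.
* Mean-completion mode remains available and remains biased (see above);
  it exists for diagnostic comparisons, not production runs.
* The averaged model's acyclicity repair is a heuristic; it is flagged
  whenever it fires, and it never fired in the shipped studies.
* Exhaustive search is limited to five variables by design; it is an
  oracle, not a user-facing learner.
* Exact probabilistic inference (arbitrary conditional queries) over the
  joint distribution is out of scope; no pipeline stage needs it.
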