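---
title: "Methods: marker derivation, survey statistics, and network learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker derivation, survey statistics, and network learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `irnet`, the defaults
it ships with and why, the scope of the synthetic cohort generator, and the
numerical choices made in the hand-implemented components.

## 1. Scientific setting

The package compares three surrogate markers of insulin resistance —
HOMA-IR, the triglyceride-glucose (TyG) index, and the triglyceride to HDL
cholesterol ratio (TG/HDL) — against two cardiometabolic outcomes, diabetes
and dyslipidemia, in middle-aged adults (40–69 years) drawn from a complex
survey design with strata, primary sampling units (PSUs), and unequal
sampling weights, as in national health examination surveys such as
KNHANES. Two complementary analyses are supported:

1. **Discrimination**: how well does each continuous marker separate
   cases from non-cases (weighted AUC), and how much outcome uncertainty
   does its quartile grouping remove (weighted mutual information)?
2. **Dependence structure**: in a discrete Bayesian network over the
   categorical analysis variables, which variables form each marker's
   Markov blanket — i.e. which associations survive conditioning on
   everything else?

## 2. Clinical derivation layer

All formulas use conventional clinical units (mg/dL for lipids and
glucose, µU/mL for insulin):

* `HOMA-IR = insulin × FBG / 405`
* `TyG = ln(TG × FBG / 2)`
* `TG/HDL = TG / HDL`
* Friedewald LDL `= TCHOL − HDL − TG/5`

`friedewald_ldl()` is a pure closed form: it returns the raw estimate,
warning when it is negative. The cohort-level wrapper `impute_ldl()`
applies the standard validity rule instead: estimates for records with
TG > 400 mg/dL, or estimates that come out negative, are left missing and
the record is subsequently dropped by the exclusion cascade as incomplete
data. Measured LDL values are never overwritten; the logical column
`ldl_friedewald` marks which entries were imputed.

Clinical categories are **lower-bound inclusive** (`cut(..., right =
FALSE)`): a fasting glucose of exactly 126 mg/dL is Danger, exactly 100 is
Caution. The bins are: FBG <100 / 100–125 / ≥126; TG <150 / 150–199 /
≥200; HDL ≥40 Normal, <40 Danger; TCHOL <200 / 200–239 / ≥240; LDL <130 /
130–189 / ≥190 (the derivation layer has no 129–130 gap: 129.9 is Normal
and 130.0 is Caution by the same lower-bound rule); HbA1c <5.7 / 5.7–6.3 /
≥6.4; blood pressure and age groups analogously.

Composite outcomes are logical ORs of their criteria, with the convention
that an observed "yes" dominates a missing component: diabetes is FBG ≥126
or HbA1c ≥6.5 or physician diagnosis or medication; dyslipidemia is TCHOL
≥240 or LDL ≥160 or HDL ≤40 or TG ≥200 or diagnosis or medication; the
three obesity definitions use BMI ≥25, waist circumference ≥90 cm (men) /
≥85 cm (women), and waist-to-height ratio ≥0.5.

The exclusion cascade removes, in order and with a per-criterion log:
records with incomplete core data, ages outside 40–69, and any history of
cardiovascular disease, cancer, or kidney disease. Overlapping records are
attributed to the first matching criterion, matching how study flow
diagrams are usually reported.

Quartile groups use type-7 sample quantiles (R's default), with boundary
values assigned to the **lower** group so that the observed cut points
themselves fall in Q1–Q3.

## 3. Survey-weighted statistics

The `survey` machinery is implemented directly in the package:

* **Rao-Scott chi-square** (second-order, Thomas-Rao F reference): the
  weighted Pearson statistic is corrected by the eigenvalues of the
  generalized design-effects matrix, estimated by stratified-cluster
  linearization of the cell-proportion estimators. A Moore-Penrose
  pseudoinverse (`MASS::ginv`) handles the singular multinomial covariance,
  and the F reference uses Satterthwaite-adjusted degrees of freedom.
  Under a trivial design (all weights equal, every row its own PSU) the
  statistic collapses to the ordinary Pearson chi-square; this identity is
  tested to 1e-10, and the test's size under a real cluster design is
  verified by simulation. Single-PSU strata either error or are centered
  at the overall mean (`singleton = "center"`), mirroring common survey
  practice.
* **Weighted mutual information** is computed in nats from the weighted
  joint table; the normalized form reported as a percentage is the
  uncertainty coefficient, MI divided by the outcome's weighted entropy.
* **Weighted AUC** is the weighted Mann-Whitney statistic with ties
  counted one half, computed by grouped cumulative sums rather than
  explicit pairwise comparison; the ROC curve is anchored at threshold
  +Inf, (FPR, TPR) = (0, 0). Agreement with `pROC` on unweighted data is
  tested to 1e-10.

## 4. Bayesian-network layer

Networks are over the categorical analysis variables only (markers enter
as quartile groups). The score is **AIC for discrete networks**,
`loglik − (r − 1)q` per node (`r` node levels, `q` parent configurations),
maximized. Levels declared in the data's factor definition but never
observed still count in the penalty, so the score depends on the declared
state space, not on which levels happen to occur.

* **Hill-climbing** starts from the empty graph and applies single-arc
  additions, deletions, and reversals, accepting only strict improvements
  (tolerance 1e-9). Tie-breaking is deterministic: additions before
  deletions before reversals, then lexicographic by arc. Gains are cached
  per target node and only recomputed for nodes whose parent set changed,
  which makes the search exactly reproducible and fast. The local
  likelihood is computed in C++ by streaming the encoded data matrix once
  per (node, parent set) evaluation, with optional row-index indirection
  so bootstrap resamples never materialize a copied data matrix.
* **Exhaustive search** enumerates all DAGs (3 / 25 / 543 / 29,281 for
  2–5 nodes) via arc-bitmask enumeration in C++ and serves as the oracle
  for the hill climber on small problems.
* **Bootstrap arc strength**: `B` nonparametric resamples of rows, one
  network learned per resample; the adjacency strength of a pair is the
  fraction of resamples in which the pair is connected in either
  direction, and the direction strength is the fraction oriented a given
  way. **Model averaging** keeps pairs with adjacency strength at or above
  the threshold (default 0.75, a conventional high-confidence cut),
  orients each by majority direction (lexicographic on exact ties), and
  repairs any directed cycle by dropping the weakest arc in the cycle.
* **Markov blankets and d-separation** are computed graphically (parents,
  children, co-parents; path blocking via the standard reachability
  algorithm), and the blanket is property-tested to be the minimal
  d-separating set.
* **Inference**: CPTs are fitted with additive (Laplace) smoothing
  `alpha` (default 1; `alpha = 0` gives raw frequencies, with
  never-observed parent configurations flagged and set uniform). Queries
  run either by exact joint enumeration (guarded to ≤ 2^20 joint states)
  or by likelihood weighting with a fixed seed; the Monte Carlo standard
  error reported with each estimate uses the weighted-sample variance.

## 5. Synthetic cohort generator

`ir_ground_truth()` defines a fixed 17-node ground-truth network whose
nodes are the analysis variables and whose arcs encode the qualitative
structure the package is designed to detect — in particular the marker
chain TG/HDL → TyG → HOMA-IR with glycemia (FBG category) feeding
HOMA-IR, and outcome nodes connected to their defining categories. Its
CPTs are fixed constants; they are the study conditions, not tunable
parameters. `sample_cohort()` performs ancestral sampling and attaches a
stratified-cluster design (strata, nested PSUs, positive weights;
optionally informative weights that tilt weighted prevalences away from
unweighted ones).

`emit_continuous()` back-solves continuous labs from the sampled
categorical state so the derivation layer can be exercised end to end:

* **Exact round trips**: all threshold-defined bins (FBG, TG, HDL, TCHOL,
  LDL categories), the composite outcomes, the obesity flags, the age
  window/groups, and the HOMA-IR quartile group (insulin is a free
  parameter given FBG, so `insulin = 405 × HOMA/FBG` is always feasible)
  re-derive exactly from the emitted labs.
* **Best-effort**: the TyG quartile is sampled in the network given the
  FBG category and the TG/HDL quartile, not given the TG bin, so the
  emitted TG must satisfy both its own bin and (if possible) the TyG
  band; when the two constraints conflict the bin wins and the TyG band
  is missed. Agreement is therefore high (~0.7 at default settings)
  but deliberately not exact, and the generator reports the number of
  infeasible cases in the `index_band_misses` attribute. The same
  applies to anthropometry, where BMI, waist circumference, and
  waist-to-height ratio interact.

This design keeps the generator honest: it cannot be nudged to make a
downstream check pass without changing the declared ground truth itself.

## 6. Pipeline defaults and rationale

`pipeline_config()` defaults: cohort size 8,195 (a typical 40–69 analysis
population in a national survey cycle); bootstrap `B = 1000` for stable
strengths (tests use 100–200); threshold 0.75; AIC score; likelihood
weighting with 1e5 particles per scenario query; smoothing `alpha = 1`.
All randomness descends from one master seed through
`child_seed(seed, stream)`, a fixed integer hash, so every stage is
independently reproducible and a re-run is byte-identical.

## 7. Limitations

* Markers enter the network as quartile groups; discretization loses
  within-quartile information, which is why AUC on the continuous scale
  is reported alongside.
* Structure learning treats rows as exchangeable: bootstrap resampling
  and the network score ignore weights and clustering (the survey design
  is honored in the descriptive statistics and marker comparison). Arcs
  should therefore be read as sample-level, not population-level,
  dependence statements.
* The Rao-Scott implementation covers stratified cluster sampling with
  replacement-style linearization; finite-population corrections and
  multi-stage designs beyond the first stage are out of scope.
* Likelihood weighting degrades when the evidence is improbable; the
  reported effective sample size and Monte Carlo standard error should be
  checked, or `method = "exact"` used where the state space allows.
* The synthetic generator emits marginally plausible but simplified lab
  distributions (uniform within bands); it validates mechanics and
  recovery, and is not a substitute for real survey data.
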