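---
title: "Methods: discrete Bayesian networks for prediabetes-to-T2D risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete Bayesian networks for prediabetes-to-T2D risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dbn)
```

## The model and its assumptions

`t2dbn` models a cohort of working adults with prediabetes as a discrete
Bayesian network over 12 categorical variables: the joint distribution
factorizes into one conditional probability table (CPT) per node given its
parents in a DAG. Three assumptions do the heavy lifting:

* **Discreteness.** Every variable is categorical with a small fixed state
  set (33 states in total across the 12 variables). Clinical markers enter
  pre-discretized (HbA1c at 6.0%, FLI at 30 and 60, WHO BMI classes, blood
  pressure grades, triglyceride bands).
* **Complete cases.** Cohort tables admit an explicit `NA` marker, but all
  learning and validation functions refuse it. There is no EM or
  imputation machinery; users must filter first.
* **Causal block ordering.** Structure search is restricted by expert
  knowledge encoded as four ordered blocks — background (GENDER, AGE,
  SOCIALs), lifestyle (DIET, SMOKING, PA, BMI), clinical intermediates
  (HbA1c, FLI, BP, TG), diagnosis (T2D). Arcs from a later block into an
  earlier one are blacklisted (51 ordered pairs). Within-block arcs are
  unrestricted, so the data still decide most of the topology.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `penalty` | 1 | per-free-parameter penalty of the network score; 1 gives AIC in the `logL − k` convention (higher is better), `log(n)/2` gives BIC. The `−2`-scaled AIC variant would not change any argmax. |
| `replicates` | 500 | bootstrap resamples for model averaging. |
| `threshold` | 0.85 | inclusive arc-strength cutoff for the consensus graph. |
| `iss` | 1 | equivalent sample size of the uniform Dirichlet prior: one imaginary observation spread over each node's whole table. `iss = r·q` reproduces Laplace add-one smoothing; `iss → 0` approaches maximum likelihood. |
| `k` | 10 | cross-validation folds (unstratified, seeded). |

The bootstrap resample size equals `n` (the standard nonparametric
bootstrap). Model averaging is assumed to operate under the same blacklist
as the final model; both choices are fixed and documented here because the
procedure they elaborate is usually described only at the level of "model
averaging over N networks at threshold t".

## Determinism and numerical choices

Every stochastic entry point takes a `seed` and restores the caller's RNG
state. Beyond that, several deliberately pinned conventions make results
bit-reproducible:

* **CPT row order.** Parent configurations are enumerated lexicographically
  over the parent order with each parent's states in declared order (first
  parent varying slowest) — the layout of a printed conditional table.
  Serialization writes this order with 17 significant digits, so JSON
  round-trips are bit-exact.
* **Hill-climbing tie-breaks.** Candidate moves are enumerated in a fixed
  order (ordered node pairs by variable declaration order; additions, then
  deletions, then reversals) and applied only on strict improvement
  (absolute tolerance 1e-9), which prevents cycling and makes the search a
  deterministic function of the data.
* **Topological ties** are broken by variable declaration order; direction
  ties in the averaged network (direction probability exactly 0.5) orient
  from the earlier declared variable; if thresholded arcs would form a
  cycle, the weakest strengths are dropped first.
* **Inference.** Variable elimination runs in linear space — the largest
  intermediate factor in this domain is far too small for underflow to
  matter (log-space products would be the switch if state spaces grew by
  orders of magnitude). The elimination order is a min-degree heuristic and
  affects cost only; a normalization constant below 1e-300 raises an
  explicit inconsistent-evidence error.
* **Zero-probability records** yield `-Inf` log-likelihood rather than an
  error, so cross-validation can report them; Bayesian fitting makes this
  unreachable for fitted networks.
* **Argmax ties** (`most_probable_state`, maximizing states in the
  ranking) resolve to the earlier declared state; ranking ties resolve
  alphabetically.

## The synthetic generator and its calibration

The study cohort is not publicly deposited, so the package ships a
ground-truth network whose structure follows the published parent sets
(`ground_truth_dag()`) and whose parameters are calibrated so that exact
inference reproduces every printed probability of the study:

* the gender split (12,080 men / 4,568 women of n = 16,648);
* the AGE | GENDER, SOCIALs table verbatim (two of its six printed rows sum
  to 0.9999 and 1.0001; they are renormalized, which leaves every entry
  unchanged to the printed four decimals);
* the headline marginals: T2D Yes 22.3%, TG Normal 71.1%, FLI Less 30
  40.4%, BMI Overweight 36.5%, BP High 48.2%, PA No 58.6% (the printed PA
  pair 40.4%/58.6% sums to 99.0%; the no-practice value is taken as the
  anchor);
* the five single-evidence conditionals that generate the risk ranking:
  P(T2D=Yes) given BMI=Obesity 0.673, HbA1c=More 6.0 0.635, FLI=More 60
  0.564, PA=No 0.372, AGE=48-62 0.307.

Unprinted quantities are free parameters, chosen once: SOCIALs
(0.20/0.35/0.45, manual classes modal in a working cohort), SMOKING
(0.45/0.25/0.30), DIET Yes 0.62, BMI Underweight 0.015 / Normal 0.40 /
Obesity 0.22, FLI middle and upper masses (0.236/0.360, the unique pair
consistent with the printed Less-30 mass and the printed per-group
step-one conditionals), and TG Limit/Hyper (0.15/0.139).

Intermediate CPTs take a monotone association form: the row for a parent
configuration is proportional to `base_s · exp(t_s · Σ_p λ_p u_p)`, where
`t_s` and `u_p` are severity scores of child and parent states and `λ_p`
per-edge strengths (strongest for BMI→FLI, AGE→HbA1c and the PA→adiposity
edges, where the clinical associations are strongest). `base` is solved by
iterative proportional fitting against the node's target marginal using the
exact parent joint of the partially built network, in topological order.
The T2D table is logistic in the severity scores plus one free offset per
calibration constraint, solved by tolerance-weighted least squares on
exact-inference residuals (multi-start Nelder–Mead with a damped
Gauss–Newton polish).

Two published figures cannot be satisfied simultaneously with the rest:
the HbA1c marginal 63.3%/36.7% is inconsistent with the printed T2D
marginal and both HbA1c conditionals (0.633·0.0269 + 0.367·0.635 ≈ 0.250 ≠
0.223), and the full six-target T2D system is only approximately
representable given any fixed upstream joint. The calibration therefore
anchors on the quantities the analyses actually consume — the marginal and
the five conditionals — letting the HbA1c marginal float (it lands near
0.71/0.29) and distributing sub-tolerance residuals across the
conditionals. `calibration_report()` recomputes every target by exact
inference; all must sit within ±0.005 (marginals) or ±0.01 (conditionals)
for the packaged network to be accepted, and `calibrate_network()` errors
otherwise. The calibrated network is frozen as a JSON data file;
regeneration from source is deterministic up to optimizer arithmetic.

**What the generator emulates and what it does not.** It matches the
printed first-order calibration targets, the published dependency
structure, and qualitative behaviours (risk-state monotonicity, protective
diet, the published ranking order). It does not attempt to match
higher-order statistics of the real cohort, measurement error, missingness,
or selection effects — so tests passing on synthetic cohorts demonstrate
that the *algorithms* behave correctly under the study's published
conditions, not that the real cohort's unpublished numbers would be
reproduced. At the extreme end of accumulated risk evidence the calibrated
logistic saturates (posteriors indistinguishable from 1), which is
epidemiologically overconfident; the published trajectories cap near 0.994.

## Structure recovery is scored up to Markov equivalence

Score-based learning from observational data identifies a DAG only up to
its Markov equivalence class: reversing a *covered* edge yields a network
with an identical decomposable score. The ground-truth DAG contains five
such reversible arcs (among SMOKING/PA/BMI, PA/DIET and TG/FLI), labelled
by Chickering's compelled-edge algorithm (`compelled_arcs()`). Recovery
experiments therefore count a true arc as recovered when its skeleton edge
is present and its orientation is either correct or not compelled
(`compare_structures()`), the same convention as structural-Hamming
distances computed on CPDAGs. Extra skeleton edges count as spurious.

## Validation conventions

The cross-validated loss is the *per-record* mean negative natural-log
joint likelihood of held-out records, with the structure re-learned on
every training split (a faster fixed-structure mode exists but is off by
default). For a well-specified learner this loss approaches the joint
entropy of the generating distribution from above, which
`network_entropy()` computes exactly by enumeration — the anchor used in
the test suite. Per-feature prediction conditions each variable on all
other 11 (equivalently, by the global Markov property, on its Markov
blanket); AUCs are one-vs-rest with midrank ties, and accuracy is the
per-variable argmax hit rate, reported identically for each state row of a
variable. Held-out posteriors can be exported for external classifier
comparisons.

## Problem sizes used by the test suite

Oracle-equivalence checks run on hundreds of random networks of up to 6–7
nodes, where brute-force enumeration is exact and cheap. Parameter-recovery
checks fit 200,000 simulated records; at that size the rare parent cells of
the AGE table (the smallest is about 5.5% of records) still carry binomial
standard errors near 0.005, so whole-table recovery is asserted at 0.01
while the two headline cells are asserted at 0.005. Structure recovery uses
cohorts of 50,000 records with 100-replicate averaging over three seeds;
cross-validation checks use the study-scale 16,648 records. These sizes
were chosen so each check is decisive for the property it tests while the
whole suite stays comfortably runnable on a laptop.

## Known limitations

* Fully discrete networks only: no conditional-Gaussian or hybrid nodes,
  and no dynamic/temporal structure.
* Exact inference only; adequate here, but the variable-elimination
  implementation is not engineered for domains with hundreds of variables.
* Search-and-score structure learning only (no PC-style constraint-based
  algorithms); scores other than AIC/BIC/log-likelihood would need a new
  penalty hook.
* No missing-data machinery (complete-case by design).
* The BIF reader covers the common dialect (discrete variables, `table`
  and per-configuration rows) and is read-only.
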