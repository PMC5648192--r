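---
title: "Wrapper feature selection with a grey-wolf-optimized extreme learning machine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper feature selection with a grey-wolf-optimized extreme learning machine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwoelm)
```

## The problem

Clinical prognosis from a panel of laboratory indices is a small-n, modest-p
two-class problem: here, predicting death versus survival after acute
poisoning from 20 first-admission coagulation, liver and kidney indices in
about a hundred patients. Two questions matter: how accurately can the
outcome be predicted, and *which* indices carry the prognostic signal. The
package answers both with wrapper feature selection — scoring candidate
feature subsets directly by the cross-validated performance of the
downstream classifier — using an extreme learning machine as the (fast)
classifier and grey wolf optimization as the (global) subset search.

## The classifier

An extreme learning machine is a single-hidden-layer feed-forward network in
which the input weights $W \in \mathbb{R}^{L\times p}$ and biases
$b \in \mathbb{R}^L$ are random and fixed; only the output weights are
estimated. With hidden output matrix $H = \sigma(XW^\top + b)$, the output
weights are the *minimum-norm least-squares* solution
$\hat\beta = H^{+}T$, where $H^{+}$ is the Moore–Penrose pseudoinverse and
$T$ the target matrix. This solution is unique, attains the least-squares
minimum, and has the smallest norm among all minimizers — the property the
test suite verifies against an independent QR solve.

Conventions the field leaves open, fixed here:

* **Weight distribution.** $W$ and $b$ are uniform on $[-1,1]$, drawn in a
  documented order ($W$ column-major, then $b$) from the training seed, so
  training is bitwise reproducible.
* **Targets and decision.** Default one-hot encoding (two columns, 1/0
  targets) with arg-max decision; exact ties go to class 0 (survival), a
  fixed and testable rule. A signed-scalar encoding ($\pm 1$ targets,
  threshold at 0) is available.
* **Pseudoinverse.** SVD-based, with singular values below
  $10^{-12}\max_i \sigma_i$ cut to zero; rank-deficient $H$ (e.g. duplicate
  rows) is handled without error.
* **Hidden-layer size.** Default $L = 45$ with sigmoid activation — the
  tuned operating point for this panel; `sweep_hidden_neurons()` reproduces
  the accuracy-versus-$L$ curve on any table.

## The search

Feature masks are points of $\{0,1\}^n$, searched through a continuous
relaxation: each agent holds a position in $[0,1]^n$, and a position
binarizes by the strict rule $\text{flag}_j = 1 \iff x_j > 0.5$ (exactly 0.5
maps to 0). Binarization happens only at fitness evaluation and at the end;
the dynamics themselves are continuous.

The fitness of a mask is

$$ f = w_1 f_1 + w_2 f_2, \qquad
   f_1 = \tfrac{1}{K}\sum_{i=1}^{K} \mathrm{acc}_i, \qquad
   f_2 = 1 - \tfrac{1}{n}\sum_j \text{bin}_j , $$

with $K = 5$ stratified inner folds. The weights are **not** part of the
original method description; the package defaults to $w_1 = 0.95$,
$w_2 = 0.05$ — the common wrapper-selection convention that accuracy must
dominate and parsimony acts as a tie-breaker — and records them in every
report. The empty mask is *defined* to score 0 (worst) rather than raising,
because all-zero binarizations legitimately occur mid-search.

**Grey wolf optimization.** Per iteration every wolf is clamped to the box,
binarized and scored; the three best-so-far agents are retained as leaders
$\alpha, \beta, \delta$ (strict improvement, so the earlier-evaluated agent
wins ties — determinism); every wolf then moves to the mean of three
leader-anchored candidates
$X_k = X_{\text{leader}} - A_k \cdot |C_k \cdot X_{\text{leader}} - X|$ with
$A = 2a r_1 - a$, $C = 2 r_2$, $r_1, r_2$ uniform per wolf and dimension,
and $a$ decaying linearly from 2 to 0 ($a = 0$ exactly at the final
iteration). Two design points deserve note:

* **Leader retention.** Re-selecting leaders fresh each iteration is a
  legitimate reading of the procedure, but the canonical reference
  implementation retains leaders only when strictly improved; retention is
  the default here because it makes convergence histories monotone (a tested
  invariant) and reproducible. `leader_retention = "per_iteration"` gives
  the other behavior.
* **Update sweep.** Leaders are stored snapshots, and every position row is
  updated — equivalent to "update the rest of the pack" when the leaders'
  coordinates live outside the population array, and exactly what the
  reference code does.

**Baselines.** PSO (global-best topology, inertia 0.9 to 0.4 linearly,
$c_1 = c_2 = 2$, velocity clamp 0.6, same binarization) and a GA (direct
bitstrings, tournament size 2, single-point crossover 0.8, per-bit mutation
$1/n$, elitism 1). Neither has canonical parameter settings for this problem;
these are conventional textbook defaults, documented so deviations are
explainable. All three optimizers share one fitness interface, so every
fitness-level test runs unchanged against each.

**Fitness randomness.** Each fitness evaluation derives a child seed from
(master seed, iteration, agent), so the same mask evaluated at different
times sees different ELM draws. That is deliberate: a mask that only looks
good under one lucky random hidden layer should not survive. A
`frozen_elm = TRUE` option fixes one draw for the whole search when exact
determinism per mask is wanted (used by the enumeration-oracle test).

## The evaluation protocol

`nested_evaluate()` runs a stratified 10-fold outer CV. Within each outer
fold the search sees only the training 9/10; one final ELM is trained on
those rows restricted to the selected mask and scored on the held-out 1/10
with accuracy, MCC, sensitivity (deceased class positive) and specificity.
Means and sample SDs are taken across folds; a fold with an empty class
reports `NaN` for the affected rate and is excluded from that average with a
warning rather than silently biasing it. MCC is reported on $[-1,1]$; a
degenerate marginal (all-positive or all-negative predictions) defines
MCC = 0 with a warning, the standard convention that keeps fold aggregation
total.

**Scaling.** Features are linearly mapped to $[-1,1]$. The historically
common practice scales the full dataset before splitting, which leaks test
information; the default here fits the scaler per outer-training fold and
applies it to the test fold (values may then fall outside $[-1,1]$ —
extrapolated linearly, never clipped). `scaling = "global"` reproduces the
leaky variant for fidelity comparisons.

**Stratification.** Outer and inner folds deal each class round-robin after
a seeded shuffle, with a rotating offset so fold sizes and per-fold class
counts stay within one of perfect proportionality. When a fold count exceeds
the smallest class, folds simply lack that class (with a warning) rather
than silently shrinking `k`; downstream code skips single-class *training*
splits.

## The synthetic generator

`generate_tablelike()` emulates the structure of the reference cohort: two
groups (51 survival / 52 deceased by default), 20 features, independent
draws per feature from a normal distribution truncated below at 0 (negative
laboratory values are impossible). Because truncation shifts moments, the
generator *moment-matches* by default: it solves for parent $(\mu, \sigma)$
such that the truncated distribution's realized mean and SD equal the
specified cell values. That solve is feasible only when the target
coefficient of variation is below about 1; heavy-tailed cells (e.g. an INR
cell specified as 5.08 ± 25.51) are infeasible for *any* truncated normal
and fall back to using the specified values as parent parameters, with
realized moments available in closed form from `truncnorm_moments()`. This
is stated honestly rather than hidden: the generator reproduces the
reference table's marginal moments where a truncated normal can, and
documents what it actually produces where it cannot.

What the generator does **not** model — and therefore what a green test does
not establish: inter-index physiological correlation (an optional
single-factor Gaussian copula `rho` exists for robustness checks but
defaults to 0, since only marginal moments are specified), genuine
heavy-tailed or contaminated measurement distributions (`contamination`
defaults to 0), and any longitudinal first/last-test structure. Results on
synthetic tables bound what the pipeline can do under the *stated* marginal
structure, not performance on the real cohort.

`generate_planted()` is the controlled counterpart: $k$ informative features
with standardized group separation $d$ (class 0 mean 0, class 1 mean $d$,
unit SD) plus pure-noise features, with the ground truth returned for
recovery scoring. Defaults (5 informative at $d = 2$, 15 noise, 51/52
patients) give a controlled analog of the reference cohort's
feature-importance structure.

A note from validating the recovery property: with five redundant
informative features at $d = 2$, dropping one costs roughly one accuracy
point of Mahalanobis separation — below the inner-CV noise floor at
$n \approx 93$ — while the parsimony term rewards the drop. A long search
therefore *correctly* prunes a redundant informative feature in some folds,
and a short search leaves occasional noise features in. "Selected in nearly
every fold" and "informative by construction" are related but not identical
notions, and the package's acceptance test for this property documents the
one marginal bound the stated world does not meet rather than adjusting the
world to meet it.

## Univariate layer

* `group_compare()`: per-feature group means/SDs and a two-sided
  independent two-sample test. Welch's unequal-variance form is the default
  because several reference cells have wildly unequal group SDs; pooled
  Student's t is a flag away. Sub-display-threshold p-values print as
  `<0.001`.
* `roc_auc()`: AUC via midranks (the Mann–Whitney equivalence, ties counted
  1/2), verified exhaustively against pair counting. Orientation is fixed —
  higher score predicts the deceased class — and never auto-flipped, so an
  inversely related index reports AUC < 0.5 as-is. The 95% CI uses the
  Hanley–McNeil standard error with a normal approximation, and the p-value
  tests AUC = 0.5 with the same SE; both choices mirror the nonparametric
  defaults of common statistical packages and are symmetric by construction.
* `fisher_lda()`: two-class Fisher discriminant
  $w = S_w^{-1}(m_1 - m_0)$ with the decision at the midpoint of the
  projected group means, reporting resubstitution accuracy. A singular
  pooled covariance is ridge-regularized with a warning (or raised on
  request). Stepwise variable entry via Wilks' lambda — a tool-specific,
  under-documented procedure — is deliberately not implemented; the plain
  all-variable discriminant is the supported default.

## Numerical and reproducibility conventions

* One master seed per entry point; child seeds derive from it with a
  multiplicative-congruential mix over integer tags (fold, agent,
  iteration), all below $2^{31}$, and every seeded function restores the
  caller's RNG state.
* Model serialization is a documented plain-text format with 17 significant
  digits — exact round trip in double precision.
* Scaling of a constant feature maps to the interval midpoint (0) with a
  warning.
* All tested tolerances are stated in the tests themselves; the ELM oracle
  comparison aligns the independent QR solve's rank tolerance with the
  documented pseudoinverse cutoff ($10^{-12}$), since rank decisions at
  mismatched tolerances would compare two different well-defined problems.

## Known limitations

* Two classes only; no multi-class MCC or discriminant generalizations.
* The wrapper evaluates thousands of small ELM fits; pure-R linear algebra
  is adequate for the study-scale problem (around $10^2$ patients, 20
  features) but not for thousands of features.
* Reference performance figures for this method come from real patient
  data; with stochastic hidden layers and search, desk-scale reproduction
  is possible only in distribution, which is why the package's
  acceptance checks are property-based (oracle agreement, recovery,
  permutation null) rather than point reproductions.
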