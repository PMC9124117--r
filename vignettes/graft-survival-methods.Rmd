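---
title: "Methods: buffalo-optimized survival prediction for kidney grafts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: buffalo-optimized survival prediction for kidney grafts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftann)
```

## The problem and the model

`graftann` predicts whether a transplanted kidney will still function five
years after surgery, as a binary classification from pre-operative donor
and recipient covariates. The pipeline has three phases: preprocessing with
censoring-based label derivation, hybrid feature selection, and a
feed-forward network trained by a swarm metaheuristic.

The classifier is the classical single-hidden-layer perceptron. With
covariates $l_1, \dots, l_p$, hidden node $n$ computes
$t_n = f(m_n + \sum_p \mu_{np} l_p)$ and the output is
$s = g(a + \sum_n b_n t_n)$, where $f$ is the hidden activation
(hyperbolic tangent by default; logistic and linear are available) and $g$
the output function (logistic by default, giving $s$ the semantics of a
survival probability). Nothing about the architecture is unusual; what is
unusual is the training: the flattened weight vector is searched by the
African Buffalo Optimization (ABO) metaheuristic rather than by
backpropagation. No gradients are computed anywhere in the package.

### The ABO metaheuristic

Each of $B$ buffalo carries an exploitation position $w$ (a candidate
solution) and an exploration move $m$. One iteration updates, elementwise,

$$m' = m + le_1\,(bg - w) + le_2\,(bp - w), \qquad w' = w + m'/\lambda^*,$$

where $bg$ is the herd-wide best position (the "democratic" pull), $bp$ the
buffalo's personal best (the "intelligence" pull), and $le_1, le_2$ are
scalar learning factors. Positions are clamped to a box after every update.
Defaults — herd 20, $le_1 = 0.6$, $le_2 = 0.5$, $\lambda^* = 1$ — follow
the conventions of the metaheuristic's originating literature; none is
critical, and all are exposed through `abo_config()`.

Two readings of the position update are typographically possible
(multiplication or division by $\lambda^*$); we divide, consistent with
$\lambda^*$'s role as a unit of time, and at the default $\lambda^* = 1$
the two coincide.

**Why the restart design matters.** The update pair above is, per
dimension, a linear map with determinant 1: the swarm orbits its bests
without damping, and the best-so-far value improves only when an orbit
happens to pass closer to the optimum. In design experiments on the
5-dimensional sphere function this plain dynamic stalls around $10^{-2}$.
The stagnation restart is therefore load-bearing: when the herd best fails
to improve for `restart_patience` (10) consecutive iterations, the best
buffalo is kept untouched (elitism) and the rest are re-seeded — half
uniformly over the box, preserving global exploration, and half uniformly
in a cube around the herd best whose radius contracts by
`restart_shrink` (0.5) at each successive restart, providing the missing
refinement mechanism. With this design the optimizer reliably reaches
$10^{-6}$ or better on the sphere and shifted-quadratic benchmarks within
200 iterations; the test suite asserts `< 1e-3` across seeds.

The best-so-far history is monotone non-increasing by construction, an
invariant asserted throughout the tests. Objectives returning non-finite
values abort with the offending point reported, rather than silently
corrupting the herd.

## Preprocessing

Because the model must be usable *before* transplantation, identifier and
post-operative columns are deleted (`clean_table()`), guided by a column
schema (`identifier | preop | postop | date | outcome`) that travels with
the table and with its CSV exports as a plain-text sidecar.

Missing covariate values are imputed with the mean of the nearest
preceding and next observed values in temporal order, i.e. with records
sorted by transplant date. Degenerate positions fall back to the single
nearest observed neighbour: the first/last record, or one of an adjacent
missing pair, takes the closer observed value, with distance ties broken
toward the past (the value already known at that point in time).
Categorical columns use nearest-neighbour carry, since a mean is
undefined. Rows missing more than `max_missing` (default 0.3) of their
feature cells are deleted instead of imputed — a pragmatic threshold for a
step that the source procedure describes only qualitatively.

The outcome label comes from censoring arithmetic. If the patient returned
to dialysis, graft time is `dialysis start − transplant date`; a graft
time under the horizon (1826 days ≈ 5 × 365.25) is a failure. Otherwise
graft time is `last follow-up − transplant date`: at or past the horizon
the graft *survived*; short of it the record is *censored* — follow-up
ended with the graft still working. For binary modelling, survived and
censored-functioning records form class 1 ("survive") and failures class
0; a graft whose failure occurred after the horizon also counts as class 1
for the five-year endpoint. Treating censored-functioning as class 1 is an
optimistic convention (their true five-year status is unknown) and is the
standard cost of forcing a time-to-event question into a binary one;
proper survival modelling is out of scope.

The outer split is 70/30 train/test (`split_train_test()`), stratified on
the outcome by default (disable with `stratify = FALSE`), with
largest-remainder allocation so the training size is exactly
`round(0.7 n)`. Everything downstream of the split — selection, training,
standardization statistics — sees only the training partition.

## Hybrid feature selection

Three composable stages (`hybrid_select()`), each disableable:

1. **Information-gain filter.** Every feature's gain
   $IG = H(y) - \sum_v \tfrac{n_v}{n} H(y \mid v)$ is computed in bits,
   continuous features first discretized into equal-frequency bins
   (default 10; the discretization is our choice, the source being silent).
   Features with gain strictly above zero pass. In finite samples almost
   every continuous feature has chance-level positive gain, so this stage
   mainly removes constants and near-constants — which is also how the
   original procedure behaves, keeping the large majority of its
   attributes. An empty result is repaired to the single top-ranked
   feature.
2. **ABO wrapper.** A buffalo position over the candidate features is
   binarized through a sigmoid transfer at 0.5 (an all-false mask is
   repaired to the best single coordinate), and the subset's fitness is
   `1 − validation accuracy` of an internal classifier on a stratified
   80/20 split of the training partition, fixed per run. There is
   deliberately no subset-size penalty: accuracy is the stated criterion.
   One buffalo is seeded at the incoming mask, so the result can never
   score worse than the input on that split. Subset evaluations are
   memoized; classifier failures score worst-case and are logged.
3. **Backward elimination.** Selected features are scanned weakest gain
   first; each is tentatively removed and the classifier re-evaluated on
   the same internal split. Removal is made permanent only on *strict*
   improvement — a tie keeps the feature (conservative: a feature that
   does not provably hurt is retained). Passes repeat until a full scan
   removes nothing, so final validation accuracy is never below the
   initial one, an invariant the tests assert on every run.

The internal classifier defaults to a binomial GLM — fast, deterministic,
and the standard linear baseline — with the ABO-trained network available
via `classifier = "abann"` for a fully self-contained (but much slower)
pipeline. Whether the wrapper and the elimination pass are alternative
descriptions of one stage or two sequential ones is ambiguous in the
source; both are implemented and composable, and either can be switched
off.

## Network training

`train_with_abo()` standardizes covariates with training-partition
statistics (reused verbatim at prediction), codes categoricals one
indicator per level, and minimizes the mean squared error between $s$ and
the 0/1 label (misclassification rate is available as an alternative
fitness) over the flattened weights, bounded in $[-5, 5]$ per coordinate.
Defaults: one hidden layer of $\max(3, \lceil\sqrt{p}\rceil)$ tanh nodes
and a logistic output. `scope = "last_layer"` freezes the hidden layer at
random weights and searches only the output bias and weights, echoing the
description of the optimizer acting on the network's last layer; the
default searches all weights. The printed form of the hyperbolic tangent
in the source is a typographical slip (it is the reciprocal); the actual
$\tanh$ is used.

**Known limitation — dimensionality.** A derivative-free swarm with a few
thousand function evaluations trains small networks well (the test suite
demonstrates ≥ 95% training accuracy on separable two-feature problems
across seeds) but degrades as the weight count grows: after hybrid
selection keeps a few dozen features, the weight space has several hundred
dimensions and the search plateaus far above the loss a likelihood-based
fit would reach. This is a property of the method, not of the
implementation (the same trainer on only the planted informative features
scores substantially higher, and the optimizer itself solves its
benchmarks to $10^{-6}$), and it is the main reason the end-to-end
default-pipeline metrics reported by `scripts/acceptance.R` are moderate.
The default training budget (30 buffalo, 500 iterations) sits where the
training objective was observed to plateau in design experiments.

## The synthetic cohort generator

Real transplant registries are private, so `generate_cohort()` produces
cohorts with planted ground truth: by default 2000 patients and 67 columns
— 2 identifiers, 4 post-operative columns, and 61 pre-operative covariates
of which 10 drive the outcome through a logistic model. Numeric covariates
are standard normal; 40% of covariates are three-level categoricals
(levels A/B/C, entering the linear predictor through the fixed coding
−1/0/1). Default effect sizes alternate in sign with magnitudes 0.7–1.2 —
moderate-to-strong effects on standardized covariates, the regime in which
feature selection is meaningfully testable — and the zero intercept puts
prevalence near one half. Dates mirror the censoring arithmetic: failed
grafts get a dialysis date 30–1825 days after transplant, functioning
grafts a last follow-up 0.4–2.2 horizons after transplant, so a minority
of class-1 records are administratively censored. One percent of feature
cells are set missing completely at random, except that no two vertically
adjacent cells of a column are ever both missing, so temporal-neighbour
imputation is always defined.

What the generator does *not* emulate — realistic clinical marginals (HLA
typing, immunosuppressive regimens), correlated covariates, informative
censoring, competing risks — bounds what green tests mean: they validate
the pipeline's mechanics and its ability to recover planted signal, not
clinical performance on registry data. The planted-recovery acceptance
check (median recall of the informative set ≥ 0.8 over ten seeds at
n = 2000, with a strictly smaller selected set) is run by the test suite
at exactly those sizes.

## Numerical choices and degenerate inputs

- Information gain is clipped at zero against floating-point round-off;
  gains are compared to oracles at the bit scale because the defining
  subtraction $H(y) - \sum_v p_v H(y|v)$ loses relative precision when the
  true gain is near zero.
- Zero-denominator metric conventions: precision/recall/F return 0 with a
  warning (arises only for degenerate all-one-class predictions);
  `accuracy()` on an empty confusion table is an error. The widely used
  definition `precision = tp/(tp+fp)` is implemented; a `variant_formula`
  audit flag reproduces a non-standard printed variant for comparison
  purposes only.
- Classification at the boundary `s == cutoff` is positive (class 1).
- Single-class training labels, fully missing columns, tables with no
  pre-operative columns, and dialysis dates preceding transplantation are
  errors with typed conditions, not silent repairs.
- Every randomized stage derives its seed from the single pipeline seed,
  and all artifacts are plain text written deterministically: two runs
  with the same configuration are byte-identical, which the acceptance
  suite asserts file by file.

## Problem sizes used in the checks

The shipped checks use the generator's default study scale: cohorts of
n = 2000 (61 pre-operative features, 10 informative) for selection
recovery, n = 200 two-cluster problems for classifier sanity, 10 seeds for
the stochastic criteria, the 5-dimensional sphere with 20 buffalo and 200
iterations for optimizer convergence, and reduced cohorts (n = 200–300)
for the byte-identity pipeline checks.
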