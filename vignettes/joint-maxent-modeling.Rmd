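---
title: "Joint maximum-entropy modeling of paired directed networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint maximum-entropy modeling of paired directed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadmaxent)
```

## The modeling problem

Social behavior rarely comes one network at a time. The same group of
animals grooms, fights, forms alliances and signals status, and the
interesting biology is often in how these behaviors are coupled *on the
same pair of individuals*: does grooming flow toward aggressors, do the
behaviors avoid each other, is reciprocity behavior-specific? dyadmaxent
models a pair of directed binary networks jointly at the dyad level.

Every ordered pair (i, j) carries the linkage vector
$(x_1, x_2, x_3, x_4)$: the two directions of network A followed by the
two directions of network B. Reading the pair the other way around maps a
state to its mirror $(x_2, x_1, x_4, x_3)$, so the 16 states fall into 10
biologically distinct classes, four of them symmetric (`0000`, `1100`,
`0011`, `1111`). The class counts over all pairs are a sufficient
statistic for every model fitted here.

Two assumptions are built in and worth stating plainly:

* **Mean field.** Every pair of nodes is treated as exchangeable — the
  model has no node covariates, degree heterogeneity or matriline
  structure. This is what makes the null tractable (a product of four
  Bernoullis), and it is the intended point of comparison: deviations it
  cannot absorb are what the constraints measure.
* **Binary edges.** Edge weights are ignored; anything nonzero is an
  edge. Inputs with weights are binarized with a warning.

## Counting conventions

The package supports three censuses, selected by the `convention`
argument of `linkage_tally()`:

* `paper-n2` (default): all $n^2$ ordered cells, the diagonal tallied as
  the all-zero state. Observed class counts report asymmetric classes in
  the representative orientation only (equivalently: dyads in that
  configuration) and symmetric classes by their full ordered count. This
  reproduces the reference census exactly: with $n = 77$ the 16-state
  total is 5929, the implied directed edge totals are 187 (grooming) and
  645 (aggression), and the null expected counts match the published
  table to the printed 0.01.
* `offdiag`: the $n(n-1)$ off-diagonal cells. This is the convention the
  synthetic-data path uses, because the generator samples dyads and the
  diagonal is never data.
* `dyad`: each unordered dyad once, folded into the representative
  orientation. Mirror symmetry of the stored counts is deliberately
  waived here.

Marginal edge rates are always computed as implied edge totals divided by
the census size. For the reference data that gives an aggression rate of
$645/5929 \approx 0.1088$; the source analysis prints a density that
implies 646 aggression edges, a one-edge inconsistency with its own class
counts. We follow the counts, since they reproduce every downstream
expected value; `edge_rates()` makes the derivation explicit.

## The constraint library

A constraint function assigns a real value to each of the 16 states. Four
are shipped; users can supply any 16-value function via
`constraint_function()`. All shipped constraints are mirror-invariant, so
tilting preserves the mirror symmetry of the model.

* **Reciprocity** (`f1` for A, `f2` for B):
  $(x_1 - r)(x_2 - r)$ with $r$ the current model's per-direction rate.
  Mean-zero whenever the network's two directions are independent at rate
  $r$ — exactly the feature absent from the null.
* **Direction opposition** (`f3`): $(x_1 - x_2)(x_4 - x_3)$, which is
  $+1$ on the two states with one-way edges pointing opposite ways,
  $-1$ on the same-way states, 0 elsewhere. A positive multiplier moves
  probability from same-direction to opposite-direction one-way pairs; at
  multiplier $\lambda$ the ratio $p(1001)/p(1010)$ scales by exactly
  $e^{2\lambda}$.
* **Presence covariance** (`f4`):
  $(\max(x_1,x_2) - a)(\max(x_3,x_4) - b)$, the centered product of the
  "any A" and "any B" indicators of the cell.

### The two centerings of `f4`

Unlike an additive recentering — which a tilt absorbs into the partition
value and which therefore cannot change the fit — the constants $a$ and
$b$ multiply the complementary indicator, so they genuinely change the
fitted family. Two policies ship:

* `"model"` (default): $a$ and $b$ are the current model's probabilities
  of any-A and any-B on a cell. This is the principled choice: the
  constraint is (approximately) the model covariance of the two presence
  indicators.
* `"paper-table-1-compat"`: $a$ as above, but $b$ is the empirical
  frequency of one-way-B-only cells (both orientations). Back-solving the
  reference table's final column identifies this centering; with it the
  final chi-squared total is 18.93 and the multiplier 0.390, matching the
  published trajectory. With the model centering the final total is
  16.79 — a *better* fit, also below the stopping threshold, but not the
  published arithmetic.

## Fitting: sequential accommodation

`maxent_fit()` implements the greedy scheme. Step 0 is the independence
null at the tally's edge rates. At step $k$ the next constraint is built
against the current model, its mean under the current model is recorded
(the "mean-zero deviation" — recorded, not enforced, since enforcing it
by subtracting a constant provably cannot alter the fit), and the
multiplier is solved from the moment condition
$\mathrm{d}\log Z/\mathrm{d}\lambda = \hat{E}[f_k]$. The tilted mean is
strictly increasing in $\lambda$ (its derivative is the tilted variance),
so the root is unique; the solver expands a bracket from $[-1, 1]$ and
then takes Newton steps safeguarded by bisection, to a residual of
$10^{-10}$ on the moment, with tilts computed in log space under
max-subtraction so large multipliers cannot overflow. Probabilities are
never floored: a zero expected count is legitimate and surfaces as an
explicit error only if the corresponding observed count is positive.

Earlier multipliers are frozen — the previous model is the new null. The
per-cell ratios between adjacent columns of the reference table confirm
this is the published procedure. A `refit = "joint"` mode (cyclic
coordinate ascent to simultaneous moment matching) is available as an
explicitly non-reference option; on the packaged census it redistributes
weight between the opposition and presence constraints and ends at a
final total no worse than the sequential one.

Stopping uses the 10-class chi-squared total against
`critical_value(df, level)` with `df = 9` — ten classes minus one — held
fixed regardless of how many multipliers have been fitted, following the
reference procedure. This is anticonservative late in the sequence (each
fitted multiplier should in principle cost a degree of freedom); the df
and level are exposed as parameters rather than silently corrected. At
the default 99% level the packaged analysis stops after the fourth
constraint (18.93 < 21.666); at 95% it would not stop (18.93 > 16.919),
which is presumably why the looser level was the published choice.

```{r fit}
fit <- maxent_fit(table1_fixture()$tally, centering = "paper-table-1-compat")
fit
tidy(fit)
```

## The synthetic generator

`sample_networks()` draws iid dyads from any model in the tilted family:
build the cell distribution (base rates plus ordered tilts), reduce it to
the 10-class dyad distribution ($2p$(representative) for asymmetric
classes, $p$ for symmetric), sample each of the $n(n-1)/2$ dyads
independently, and orient asymmetric dyads by a fair coin from the same
seeded stream. What it emulates is precisely the model's own sampling
assumptions: exchangeable dyads, no degree heterogeneity, no
transitivity, no covariates. Real animal networks violate all three, so
a passing recovery experiment certifies the estimator, not the biological
realism of the mean-field family.

One subtlety the recovery experiments (`recovery_experiment()`) surface:
the refit re-derives its centering constants from the *sampled* data
(rates from the realized tally), so the fitted exponential family differs
slightly from the generating one and the multiplier estimates carry a
small systematic offset on top of Monte-Carlo noise — for a single
reciprocity tilt of $\lambda = 1$ at rates 0.05/0.1 the infinite-data
limit is about 0.97 rather than 1. At the calibration size used in the
tests (500 nodes, ~125k dyads, 3 seeds) the mean absolute error stays
well under 0.15 per multiplier, which is the guarantee the package
asserts. Test problem sizes throughout were chosen so the whole suite
runs in well under a minute: census-level checks are exact and instant,
and the sampling checks use 150–500 nodes with fixed seeds.

## Auxiliary contingency statistics

`pearson_chisq()` and `proportion_test()` cover the companion analyses
that compare edge composition between two observation periods. The
continuity-correction policy is `auto`: Yates-corrected exactly when the
table is 2×2 (this reproduces all published comparison statistics —
uncorrected, the status comparison would give 26.34 rather than 25.90),
overridable per call. The uncorrected 2×2 statistic equals the squared
pooled two-proportion z statistic, which the tests assert.

## Known limitations

* Mean-field only: no covariates, no degree correction; the null is a
  straw man by design.
* Two networks at a time; multi-behavior systems are analyzed pairwise.
* Binary edges; interaction frequencies are discarded.
* Constraint choice is manual. The library covers the four shipped
  association types; discovery/selection of constraints from data is out
  of scope.
* The stopping rule's fixed df = 9 ignores fitted multipliers (see
  above).
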