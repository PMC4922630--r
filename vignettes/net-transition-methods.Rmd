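---
title: "Estimating one-year net transitions between BMI categories from cross-sectional surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating one-year net transitions between BMI categories from cross-sectional surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmitrans)
```

## The problem

Longitudinal cohorts spanning early childhood through late adulthood in
multiple population groups essentially do not exist, and older cohorts are
outdated by strong secular trends in overweight and obesity. Repeated
cross-sectional surveys, by contrast, are plentiful. This package estimates
the *net* movement between the three ordered BMI categories — normal weight
(adult BMI < 25 kg/m², child BMI percentile < 85th), overweight (25–29.99,
85th–95th) and obese (≥ 30, > 95th) — over single years of age, from
cross-sections alone.

The estimand is a net, not a gross, flow. If among 100 normal-weight
18-year-olds ten move up to overweight by 19 while three overweight people
move down to normal, the normal→overweight net transition is 7 people and
the net transition probability is 7/100 = 7%; the opposing direction is
reported as 0. Gross (individual) transition probabilities are not
identifiable from cross-sections and are out of scope.

## The estimator in three steps

**1. Prevalence smoothing.** For each sex × group stratum we fit a
survey-weighted multinomial logit for the category probabilities
$p_k(a)$, $k \in \{\text{normal}, \text{overweight}, \text{obese}\}$, with
each non-reference log-odds a cubic B-spline in age carrying a
second-order difference penalty (a P-spline: ~20 equally spaced interior
knots over ages 2–80, penalty $\lambda \sum_j (\Delta^2 \beta_j)^2$).
Normal weight is the reference category — any choice yields identical
probabilities; one is fixed for reproducibility. A single smooth spans ages
2–80: the classification rule switches from child percentiles to adult
cut-points at age 20, but the prevalence surface itself shows no
discontinuity there, so no break is modelled. The coefficient covariance is
a cluster-robust sandwich over PSUs nested in design strata (each record is
its own cluster when no design columns are supplied), computed around the
penalized information.

**2. Net transitions by minimum-cost transport.** For each consecutive age
pair, the joint one-year flow matrix $x_{ij} \ge 0$ is the solution of a
transportation linear program: minimize $\sum_{ij} c_{ij} x_{ij}$ subject
to row marginals $p(a)$ and column marginals $p(a+1)$. The cost depends
only on the number of category steps, $c_{ij} = c_{|i-j|}$, and encodes an
*economy of movement*: staying is cheapest ($c_0 < c_1$) and two one-step
moves are cheaper than one two-step move ($2c_1 < c_2$), reflecting that a
full jump from normal weight to obesity within one year is unlikely. The
default constants (0, 6, 17) come from calibration against longitudinal
weight-category trajectories; `calibrate_costs()` re-runs that calibration
against any longitudinal file.

Under these constraints the optimal net flows have a closed form for three
categories: the signed net across the normal/overweight boundary is
$p_1(a) - p_1(a+1)$ and across the overweight/obese boundary
$p_3(a+1) - p_3(a)$, *for every valid cost matrix*. The package therefore
carries two routes — `solve_transport()` (simplex LP) and
`closed_form_net()` — and the test suite drives tens of thousands of random
instances through both, requiring agreement to $10^{-9}$ and exact
invariance across cost triples. The LP also resolves ties toward the unique
monotone (non-crossing) coupling so that reported *plans* are reproducible;
net flows are unaffected by the tie-break. Net probabilities divide the
favored direction's net flow by the origin category's prevalence
(normal for up-moves across the first boundary, overweight for up-moves
across the second; overweight and obese for the respective down-moves).

**3. Parametric bootstrap.** Spline coefficients are drawn from a
multivariate normal with the fitted mean and sandwich covariance, the
prevalence surface and the nets are rebuilt per draw, and percentile
intervals are taken per (age, boundary, direction). Sampling in coefficient
space keeps every simulated surface a proper probability vector after the
inverse-logit map. The point estimate stays the plug-in value, so for
skewed replicate distributions near 0 it can sit outside the percentile
interval; intervals themselves are always ordered and inside $[0, 1]$.
Default 1000 replicates, 95% level, mandatory seed.

## Tunable parameters and their defaults

| parameter | default | meaning |
|---|---|---|
| knots / degree / penalty order | 20 / cubic / 2nd difference | P-spline basis over ages 2–80 |
| `lambda_grid` | $10^{-2} \ldots 10^{0.5}$ | AIC search range for the penalty |
| cost constants | (0, 6, 17) | economy-of-movement step costs |
| bootstrap | 1000 replicates, 95% | percentile intervals |
| `chi2_bound` | 3 | stability decision bound |
| two-step cap (simulator) | 0.01 | max one-year two-step rate |

**Why the smoothing grid is deliberately light.** The downstream estimand
is the *year-over-year increment* of the prevalence surface, rescaled by a
prevalence. Prediction-optimal smoothing — what AIC or cross-validation
selects over an unrestricted grid — balances squared bias against variance
for the *level* of the curve; the retained bias is first-order for
increments and concentrates exactly where the curves bend hardest, at the
early-childhood obesity peak: prediction-optimal penalties flatten the
age-2 overweight→obese net by multiples of its standard error and push
bootstrap interval coverage far below nominal.
Undersmoothing relative to the prediction optimum is the
standard remedy when inference targets derivatives or differences: with the
default grid the penalty stabilizes an ample basis rather than shrinking
the curve, increment bias stays well below sampling error, and nominal 95%
intervals achieve their stated coverage in the package's own simulations.
The grid is configurable; fitting for pure prevalence description (a
Fig-1-style surface) can legitimately use heavier smoothing.

Knots are equally spaced in years by default. A log-age option exists
(`transform = "log"`), which concentrates knots in childhood, but with
uniformly sampled ages it amplifies early-childhood variance enough to be
counterproductive; it is kept for age distributions heavily weighted toward
children.

## Cost-constant calibration

`calibrate_costs()` scores candidate $(c_1, c_2)$ pairs (with $c_0 = 0$) by
the mean squared difference between LP nets from the cross-sectional
prevalence and empirical nets counted in a longitudinal file. Because nets
are cost-invariant whenever the economy-of-movement constraints hold, the
profile over valid candidates is flat to numerical precision and the
selection falls to the documented tie-break (first valid candidate in grid
order); candidates violating the constraints are flagged and never fitted.
The calibration machinery is retained because it is the step that justifies
the constraint structure against real trajectories, and because it exposes
any violation of cost-invariance as a bug.

## Stability validation

Cross-sectional net-transition estimation assumes the age-specific
transition regime is stable across survey cycles. `validate_stability()`
tests this by chaining `project_forward()` — the exact algebraic inverse of
estimation, so one projection step subtracts the boundary-1 net flow from
normal weight and adds the boundary-2 net flow to obesity — for $h$ years
from an earlier cycle's surface and comparing with a later, independent
cycle at the aged positions. Discrepancies are standardized by bootstrap
SEs of prediction and observation combined in quadrature.

The *decision* statistic is the per-cycle mean squared standardized
discrepancy (a reduced chi-square), flagged when it exceeds 3. A
maximum-over-cells rule at 3 SEs was evaluated first and discarded: a
maximum taken over hundreds of correlated age × category cells (79 ages ×
3 categories per compared cycle) false-alarms far above the intended rate
purely through multiplicity, while a secular shift moves the whole surface
coherently — exactly what a mean-type statistic detects. Under the
simulated study conditions the reduced chi-square sits comfortably below
the bound for a shared regime and several-fold above it under a +50%
upward-rate shift; the acceptance checks measure both error rates over 200
simulations per scenario. Per-cell 3-SE exceedances are still reported to
localize a flagged shift.

## The synthetic cohort and what it does (not) show

`make_truth()` builds an age-varying Markov regime: smooth one-year
transition rates, two-step rates capped at 0.01, an initial category
distribution at age 2, and the implied marginal prevalences and true nets.
The `early_peak` preset mirrors the qualitative life-course pattern of the
U.S. populations this method targets — overweight→obese nets peaking at age
2 (~13% of the overweight) and declining with age, normal→overweight nets
peaking in the early 20s. `sample_cross_section()` draws survey records
from the implied marginals with a multistage design: 15 strata × 2 PSUs per
cycle (cycle-specific labels, so pooling three cycles yields ~90 clusters —
enough for a full-rank cluster sandwich over ~48 spline coefficients),
lognormal weights drawn independently of category (keeping the weighted
estimator unbiased), optional PSU random intercepts, and BMI values emitted
inside the drawn category's band (via the inverse LMS transform for
children) so classification is exercised end-to-end.

The simulator reproduces category-level dynamics only. It does not model
continuous BMI tracking, growth spurts, within-person autocorrelation
beyond the Markov property, informative weighting, or nonresponse. Passing
recovery and coverage tests therefore demonstrates the estimator chain is
correct and its uncertainty honest *under the stated design*; it cannot
certify robustness to informative sampling or non-Markov dynamics in real
surveys.

## Numerical choices and degenerate inputs

- Marginals passed to the transport step must sum to 1 within $10^{-6}$
  (renormalized inside that tolerance, an error beyond it — a larger
  mismatch signals pipeline misuse, since smoothed prevalences are
  normalized upstream).
- LP ties break to the monotone coupling; the LP optimum is cross-checked
  against the monotone plan's cost on every call.
- An all-one-category stratum returns the degenerate curve ($p = 1$) with a
  warning; absent categories keep probability 0; the multinomial reference
  is the lowest category present.
- Non-PSD covariances are repaired by eigenvalue clipping, with a warning.
- Child classification uses age in months, `12*age + 6` when only integer
  years are supplied; the adult/child switch sits at exactly age 20.
- Boundary conventions: adult intervals are half-open ([25, 30) is
  overweight); the child 85th and 95th percentiles are both overweight;
  underweight folds into normal weight (it is under 1% of the populations
  targeted) and the fold count is logged.
- The 85th/95th boundary inclusiveness is a fixed convention of this
  package; source surveys may round percentiles differently at machine
  precision.

## Problem sizes used in the checks

The bundled tests and the acceptance script run: parameter recovery on one
stratum of 50,000 records pooled over three cycles (MAE criterion: under 1
percentage point across ages 2–79); interval coverage on 200 replicate
datasets of three 1,500-record cycles with 200 bootstrap replicates each;
stability size and power on 200 simulations per scenario with 2,500-record
cycles; and 10,000 random marginal pairs through both transport routes.
These sizes were chosen to make Monte-Carlo error small relative to the
bands being checked while keeping a full run in minutes on one core.

## Known limitations

- Nets, not gross flows: a zero net is compatible with large balanced
  churn.
- Survey variance uses a PSU-level sandwich; full design-based replication
  (BRR/Fay) is not implemented, and with fewer clusters than spline
  coefficients the sandwich is rank-deficient — pool cycles or reduce the
  basis in that case.
- Smoothing-parameter selection is not propagated into the bootstrap; the
  light default grid keeps the unpropagated component small.
- Peak ages are reported as the integer-grid argmax of the smoothed curve.
- The census extrapolation multiplies by a fixed population table; it does
  not age or project the population itself.
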