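---
title: "Measuring school-system effects on health inequality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring school-system effects on health inequality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthineq)
```

## The question and the estimand

Britain's move from a selective secondary system (grammar/private versus
secondary-modern schools, allocated by an age-11 examination) to a
comprehensive system was motivated partly by equity.  `healthineq`
implements the analysis needed to ask whether that kind of policy change
altered *socio-economic inequality* in adult health, not just its average:
compare, between people schooled under the two systems, how strongly good
health concentrates among the socially advantaged — after removing the
confounding that arises because selective-system pupils were drawn from
more advantaged, higher-ability homes.

The estimand is whole-population ("imagine everyone had attended each
system"): inverse probability weights `1/p` and `1/(1-p)` reweight each arm
to the full cohort, so weighted arm contrasts are average-population
effects rather than effects among the treated.

## The inequality measure

The core statistic is the concentration index of a health outcome against
an ordered socio-economic variable (origin social class by default, a
four-category NS-SEC-style classification).

**Fractional ranks.** Each class is coded at the midpoint of its ranked
cumulative population share, ordered from most disadvantaged to most
advantaged: group *g* gets rank `sum(share[h < g]) + share[g]/2`.  Five
equal groups code to 0.1, 0.3, 0.5, 0.7, 0.9.  All members of a group share
the midpoint (no within-group jitter), and the weighted mean rank is
exactly 0.5 for any non-negative weights — a property the test suite checks
and that several identities below rely on.

**Orientation and scaling.** Every outcome is coded both as *attainment*
(larger = better health) and as its complement *shortfall*, each scaled to
[0, 1] so the index is scale invariant.  Binary outcomes map to {0, 1};
ordinal outcomes are spread evenly over their level codes; continuous
outcomes are min–max scaled with theoretical instrument bounds when known
and the observed weighted range otherwise (the choice is recorded in the
coding object).  Relative indices genuinely differ between the two
orientations, which is why both are reported; absolute indices only flip
sign.

**The regression transform.** For the relative index the scaled outcome is
multiplied by `2 * var_w(rank) / mu_w` and regressed (weighted least
squares) on the rank; the slope is the index.  For the absolute
(Erreygers-type) index the relative dependent variable is further
multiplied by `4 * mu_w`.  Both are algebraically identical to the direct
covariance forms `2 cov_w(y, r) / mu_w` and `8 cov_w(y, r)`; the package
computes the regression route and the tests verify equality against the
covariance oracle to 1e-10 over a thousand random tables.  All weighted
moments use the population convention (denominator = total weight), which
is what makes these identities exact rather than approximate.

Two mirror identities are exposed via `mirror_checks()`: the absolute index
is sign-symmetric between orientations, and
`mu * C_attain = -(1 - mu) * C_shortfall`.

**System contrasts.** `system_contrast()` fits one weighted regression of
the transformed outcome on rank, a system dummy, and their interaction.
The rank coding is computed once on the full weighted sample (the
socio-economic variable is ranked once, as in the source analyses), while
the transform's `mu` and `var(rank)` are computed *within each arm*.  That
scoping decision was genuinely open; it is resolved this way because it
makes each arm's slope equal its stand-alone index and the interaction
coefficient exactly the selective-minus-comprehensive difference in
indices, so the "difference in inequality" reading of the contrast is
literal rather than approximate.

## Uncertainty

No single SE convention is canonical for weighted concentration indices, so
two are provided.  The default is a nonparametric bootstrap (resample
records, recompute ranks, transforms and — through the `weight_refit` hook —
the weights themselves; 999 replicates, percentile intervals), because it
propagates rank- and weight-estimation uncertainty.  The alternative is a
heteroskedasticity-robust (HC1) sandwich on the final transformed
regression, which conditions on the estimated ranks and weights and is much
cheaper; it is what the pipeline's permutation-calibration test uses.  On
synthetic cohorts the bootstrap's empirical coverage of the planted truth
sits inside [0.92, 0.98] at the sizes exercised in the tests (200
replicates of n = 1000 with 299 bootstrap draws — sizes chosen to make the
check sharp but affordable).

## Confounder balance

`fit_propensity()` offers three candidates for the probability of selective
attendance: a main-effects logistic model; a flexible logistic model with a
natural cubic spline basis (default 4 df) on each continuous confounder —
the smoother settings of the flexible model in the source analyses are not
published, so a transparent spline-expanded GLM is used; and a
ridge-penalized logistic model with the penalty chosen by 5-fold
cross-validated deviance under a fixed fold seed.  `entropy_balance()`
solves the exact-mean-balance problem through its convex dual: weights are
a softmax in the confounders, found by BFGS on the log-sum-exp objective
with analytic gradients and polished by Newton steps until the worst
moment error is at machine precision (tolerance 1e-8; infeasible targets —
outside an arm's convex hull — are reported as errors rather than met with
negative weights, which exact balancing would otherwise require).

`select_weights()` replaces stacked model selection with a transparent
criterion: the candidate minimising the mean absolute standardized mean
difference over all confounder levels wins, with ties broken by the smaller
coefficient of variation of the weights (less extreme weights at equal
balance).  SMDs use weighted means and weighted population variances,
`(m1 - m0) / sqrt((v1 + v0) / 2)`.  When both arms are constant and equal
the SMD is defined as 0; constant-but-unequal arms are an error, not a 0.

Weight truncation is off by default (the source analyses do not mention
trimming); an optional percentile cap is available for positivity-fragile
data.

## Missing data

The two-stage strategy mirrors common cohort practice: unit non-response
(attrition) is handled by inverse-probability-of-response weights fitted on
fully observed baseline confounders, with the final analysis weight the
product of response and confounding weights; item non-response among
responders is handled by chained-equation multiple imputation (default
m = 5, 10 sweeps), with Rubin pooling of estimates.  This stage is a
reconstruction of the cited two-stage approach from its general form, not a
replication of an unpublished recipe, and is documented as such.

Imputation models are proper (parameters drawn from their approximate
posteriors): type-1 predictive mean matching with 5 donors for continuous
variables — chosen over a Gaussian draw because matched donors respect the
bounded, non-Gaussian support of 0–1 scaled outcomes — logistic draws for
binaries, and proportional-odds draws for ordered factors.  Analyses of
fully complete data reproduce the no-missingness pipeline exactly (the
imputer returns identical copies and response weights collapse to 1).

## The synthetic cohort generator

Because the real cohort extracts cannot be redistributed, every stage is
validated on synthetic cohorts whose inequality is *known by
construction*:

* Categorical confounders are drawn independently from marginals echoing a
  1958-style British birth cohort baseline table; origin class (four
  ordered NS-SEC-style categories, default shares 0.16/0.05/0.21/0.58 from
  most to least advantaged) and cognitive ability share a latent advantage
  factor (default correlation 0.3).  Real cohorts publish only marginals,
  so this joint structure is an explicit stand-in.
* Selective attendance is a logistic function of ability, class and
  primary-school type, reproducing the advantaged/higher-ability enrichment
  of selective pupils (about 40% selective overall by default).
* Outcomes are planted on the *realised* fractional rank of the generated
  table.  Continuous outcomes draw from a method-of-moments Beta with mean
  `alpha + beta * rank` (plus selective-system shifts in level and slope):
  the Beta keeps values strictly inside (0, 1) — so theoretical scaling
  bounds are honest — while leaving the planted mean and covariance, hence
  the planted index, exact.  Binary and ordinal outcomes use logit and
  proportional-odds links in the rank.
* `SimulationTruth` is computed by exact enumeration over the realised
  class shares, so a noise-free outcome analysed with
  `concentration_index()` reproduces its truth to 1e-10, and
  `planted_ci_outcome()` solves `alpha`/`beta` so the planted relative
  indices take requested values (e.g. 0.10 comprehensive vs 0.20
  selective).
* `allocation = "balanced"` is a validation mode: largest-remainder class
  counts and within-class alternating exposure make realised shares equal
  the specified probabilities exactly, which turns noise-free planted
  contrasts into machine-precision identities.  The default allocation is
  stochastic.
* A BMI-style baseline score generated independently of class serves as
  the negative control; `run_pipeline()` estimates its index with the
  analysis weights and flags (does not fail) intervals excluding zero.

What passing these tests shows — and does not.  The generator emulates the
*statistical shape* the estimator assumes: ordered-class gradients that are
linear in the fractional rank, missingness that is MAR in observed
baseline variables, and a correctly specified propensity family.  Real
cohort data offer none of those guarantees: gradients may be non-linear in
rank, missingness may be non-ignorable, and confounding may be residual.
Green tests certify the estimator and its identities, not those substantive
assumptions.

## Numerical choices and degenerate inputs

* Weighted moments: population denominator everywhere (weights are mass,
  not sampling corrections); Kish effective n is reported with every
  estimate.
* Relative indices require the scaled mean strictly inside (0, 1);
  constant outcomes, all-zero weights, single-rank-value inputs,
  single-level exposures and 100%-missing variables are errors with
  explicit messages, not NaNs.
* Near-separation in the logistic propensity (fitted probabilities at
  0/1) is an error advising the ridge candidate.
* Entropy balancing detects infeasible targets both a priori (target
  outside an arm's observed range) and a posteriori (residual moment error
  above tolerance after optimisation).
* Ordered stratifiers other than origin class (destination class,
  education bands) work identically: any ordered factor column can be the
  ranking variable, with weighted fractional ranks over its observed
  categories.
* Determinism: generation, missingness, imputation and the pipeline are
  byte-reproducible given their integer seeds; the pipeline derives its
  stage seeds from the single master seed.

## Problem sizes in the shipped tests

The test suite exercises: exact identities on up to 1000 random small
tables; parameter recovery of planted indices 0.10/0.20 and their contrast
over 200 replicates of n = 50,000 with estimated IPW; bootstrap coverage
over 200 replicates of n = 1000 (299 draws); permutation calibration of
the contrast test over 1000 permutations of n = 3000; negative-control
coverage over 100 replicates of n = 2000; and MI-versus-complete-case
recovery over 100 replicates of n = 10,000.  These sizes are the package's
own validation choices; larger runs only sharpen the same checks.

## Known limitations

* The balance criterion is mean |SMD|; distributional balance beyond first
  moments is reported (per-level tables) but not optimised, and full
  cross-validated model stacking for weight selection is out of scope.
* The robust SE conditions on estimated ranks, means and weights; use the
  bootstrap when those sources of uncertainty matter.
* Generalized boosted propensity models are accommodated only through
  `make_ipw()` on externally supplied probabilities.
* The MI stage assumes MAR given baseline confounders and co-observed
  outcomes; non-ignorable mechanisms are out of scope.
* Synthetic cohorts do not calibrate to any real cohort's joint
  distribution, and no claim about results in the real British birth
  cohorts follows from them.
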