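---
title: "Estimating price elasticities from survey unit values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating price elasticities from survey unit values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deatonuv)
```

## The problem

Household expenditure surveys in low- and middle-income countries rarely
record market prices, but they do record, per household, how much was spent
on a good and how much of it was bought. The ratio — the *unit value*
$v_{hct} = c_{hct}/q_{hct}$ — carries price information, yet it is not a
price: richer households buy dearer varieties (*quality shading*), and both
expenditure and quantity are reported with error. Deaton's unit-value method
turns this around by exploiting the survey design: households in the same
primary sampling unit (a ward, here called a *cluster*) face a common market
price at a given time, while prices vary substantially *between* clusters.
`deatonuv` implements that method for cigarette demand on a three-wave
household panel, together with a synthetic-survey generator so that every
stage can be validated without any external microdata.

## Model and procedure

Stage one fits two household-level regressions by OLS,

$$\ln v_{hct} = \alpha_1 + \beta_1 \ln x_{hct} + Z_{hct}\gamma_1
  + \psi \ln \pi_c + y_t + u^1_{hct},$$
$$w_{hct} = \alpha_0 + \beta_0 \ln x_{hct} + Z_{hct}\gamma_0
  + \theta \ln \pi_c + f_c + y_t + u^0_{hct},$$

where $x$ is total household consumption per week, $w = c/x$ the cigarette
budget share, $Z$ socio-demographics (household size and composition,
head's sex and education, maximum education, consumption quintiles,
urbanicity), $\ln\pi_c$ the unobserved cluster log price, $f_c$ and $y_t$
cluster and wave effects, and $u^1, u^0$ errors that absorb measurement
error in both outcomes. The unit-value equation runs over consuming
records only; the budget-share equation runs over the entire sample, zeros
included. Both equations are estimated *omitting* $\ln\pi_c$; the price
coefficients $\psi$ and $\theta$ are recovered later. Standard errors are
clustered by household, since the same household is observed in three
waves.

Stage two purges each outcome of its estimated systematic parts
(expenditure, demographics, year effects) and averages the purged values
within each survey cluster, pooling the waves:
$\hat y^1_c$ (consumers, $n_c^+$ records) and $\hat y^0_c$ (all records,
$n_c$). Both means still contain averaged-down household noise, so the
regression of $\hat y^0_c$ on $\hat y^1_c$ is corrected by
errors-in-variables:

$$\hat\phi = \frac{\mathrm{cov}(\hat y^1_c, \hat y^0_c) -
  \hat\sigma_{10}/\tilde n}{\mathrm{var}(\hat y^1_c) -
  \hat\sigma_{11}/\tilde n^+},$$

with $\hat\sigma_{11}, \hat\sigma_{10}$ the first-stage residual variance
and cross-equation covariance. Finally the quality-correction identities
convert $\hat\phi$ into structural elasticities:

$$\hat\zeta = \frac{\hat\beta_1}{\hat\beta_0 + \bar w(1-\hat\beta_1)},
\qquad
\hat\theta = \frac{\hat\phi}{1 + (\bar w - \hat\phi)\hat\zeta},
\qquad
\hat\varepsilon_p = \frac{\hat\theta}{\bar w} - \hat\psi,
\qquad
\hat\varepsilon_I = 1 + \frac{\hat\beta_0}{\bar w} - \hat\beta_1.$$

Two algebraic variants of the $\hat\psi$ identity circulate in applied
work; both are implemented (`psi_formula`):

* `"as_printed"` (default): $\hat\psi = 1 - \hat\beta_1(\bar w -
  \hat\theta)/(\hat\beta_1 + \bar w)$;
* `"deaton_1997"`: $\hat\psi = 1 + \hat\zeta(\hat\theta - \bar w)$.

Both satisfy $\hat\psi = 1$ when $\hat\theta = \bar w$ or $\hat\beta_1 = 0$.
At budget shares of a few percent they diverge sharply: the default keeps
$\hat\psi$ near one (unit values track prices nearly one-for-one, with
quality absorbing little of the price change), while the alternative
multiplies the gap $\hat\theta - \bar w$ by a $\zeta$ that grows like
$1/\bar w$ and can push $\hat\psi$ far from one or below zero. On synthetic
data generated with $\psi$ near one, the default recovers the generating
value to well within 0.02 and the alternative misses by an order of
magnitude more; that simulation evidence (recorded in the test suite) is
why `"as_printed"` is the default, but on real data the choice is a
substantive one the user should probe.

## Panel adjustments

Three departures from the cross-sectional method accommodate the
three-wave panel:

1. **Year effects** in both equations remove common temporal trends, so
   between-cluster price variation is not confounded with inflation or
   secular consumption shifts. Cluster prices are treated as constant
   across waves once year effects are removed, and the three waves of a
   cluster are pooled into a single cluster average (tripling effective
   cluster size).
2. **Temporal error clustering**: with `temporal_clustering = TRUE`
   (default), residuals are summed within household across waves before the
   (co)variance cross-products are averaged. For an AR(1) error with
   autocorrelation $\rho$ and $T$ waves this scales the moments by
   $1 + (4\rho + 2\rho^2)/3$ at $T = 3$ — exactly the factor by which
   serial correlation inflates the error variance of a cluster mean, which
   is what the corrections in $\hat\phi$ must match.
3. **Stable preferences** are assumed over the short panel; smoking status
   in the generator is a household-level draw, constant across waves.

## Numerical and design choices

* **Correction divisors.** The covariance correction is divided by the
  cluster size $n_c$ and the variance correction by the consumer count
  $n_c^+$ (both summarised by harmonic means, matching the average of
  per-cluster $1/n$ noise moments). The asymmetry is not a typo: the
  share mean runs over all $n_c$ records but only its $n_c^+$ consumer
  records carry a unit-value error, so the noise covariance of the two
  means is $\sigma_{10}/n_c$, while the noise variance of the unit-value
  mean is $\sigma_{11}/n_c^+$. Both divisor and size-summary conventions
  are configurable (`eiv_sigma10_divisor`, `eiv_size_summary`).
* **$\bar w$.** The default is the unconditional mean budget share over the
  full estimation sample, matching the unconditional budget-share
  regression whose $\hat\beta_0$ enters the same identities; the
  conditional (consumers-only) mean is available via `wbar_mode`. The
  structural elasticities are invariant to the choice because the
  participation rate scales $\hat\beta_0$, $\hat\phi$ and $\bar w$ alike.
* **Unit-value equation fixed effects.** By default cluster effects are
  absorbed in *both* equations (`fe_mode_eq1 = "cluster_and_year"`): the
  quality elasticity $\hat\beta_1$ is then identified purely from
  within-cluster variation, uncontaminated by the spatial price signal.
  The textbook variant without cluster absorbers (`"year_only"`) is
  provided; it requires cluster prices to be uncorrelated with household
  resources.
* **Aliased columns.** Covariates constant within clusters (e.g. an
  urbanicity flag defined at the ward level) are indistinguishable from the
  absorbed effects; they are dropped with a note and their effect remains
  in the cluster component of the purged values. Without absorbers, a
  rank-deficient design is an error naming the collinear columns.
* **Bootstrap.** Inference resamples the 400 survey-design clusters with
  replacement, keeping all waves of a cluster together. Each replicate
  reruns the entire two-stage pipeline; replicates whose corrected EIV
  denominator is non-positive are dropped and counted (an error above
  20%). Confidence intervals are 2.5/97.5 bootstrap percentiles, which
  tolerate the asymmetry that the ratio structure of $\hat\phi$ induces.
* **Degenerate inputs.** Clusters without consumers contribute to the
  budget-share equation but not to the EIV step; a non-positive corrected
  variance aborts with a recommendation (more or larger clusters); unit
  values are undefined (never zero) for non-consumers, and positive
  expenditure with zero quantity is rejected as a data inconsistency.

## The synthetic survey

`synthetic_truth()` parameterises the generating model;
`simulate_survey()` draws cluster log prices ($\mathrm{SD} = 0.25$,
independent of cluster wealth), cluster share effects, household
demographics (size, composition, education, headship near national survey
magnitudes), log-normal total expenditure with cluster- and household-level
components, household-level smoking participation (15%), and jointly
correlated AR(1) errors. Quantities follow from the accounting identities
$c = wx$, $q = c/v$, which hold exactly in every generated record. The
default design is 400 clusters × 15 households × 3 waves (18,000 records),
with a quality elasticity $\beta_1 = 0.78$ and a mean conditional budget
share near 0.05.

The conditional share dispersion is kept at about 0.02 — well below what
real surveys show — because a linear-normal share equation with realistic
dispersion would place a large mass of shares outside $(0,1)$; the
generator clamps stray consumer shares to the interior and refuses
parameter sets where more than 1% need clamping. Real budget shares are
zero-inflated and right-skewed; the generator reproduces the zero mass via
participation but not the skew, so passing recovery tests validate the
estimation machinery, not distributional robustness. Other absent features:
attrition (the generator's panel is balanced), endogenous smoking
participation, integer-valued quantities, and cluster prices that move
idiosyncratically across waves (common movement is carried by the year
effects).

### What "recovery" means here

`implied_elasticities()` reports two quantities. The *structural* value,
$\theta/\bar w - \psi$ evaluated at the generating parameters, is the
household-level price elasticity in the generating model. The *estimator
limit* applies the quality-correction identities to the exact large-sample
limits of the pipeline's inputs ($\beta_0^* = p\beta_0$,
$\phi^* = p\theta/\psi$, $\bar w^*$). The two coincide only when the
generating $(\theta, \psi)$ satisfy the quality-theory restriction that the
identities embed; for a generator whose price coefficients are free
parameters they generally do not, and the gap measures the identities'
modelling error rather than any estimation failure. Recovery and coverage
checks therefore target the estimator limit — they validate purging,
aggregation, the EIV correction and the bootstrap end to end, which is what
simulation *can* validate.

The attenuation experiment (does removing the corrections shrink
$|\hat\phi|$?) uses near-zero cross-equation error correlation and 600
clusters: a large $\sigma_{10}$ moves the *numerator* of the uncorrected
slope upward, confounding the variance-driven attenuation whose direction
is being tested, and the extra clusters stabilise the per-replicate sign of
the comparison.

### Problem sizes

Validation runs use 20 recovery replicates at full design scale, 60
attenuation replicates, and 100 coverage replicates at a reduced scale of
150 clusters × 10 households with 200 bootstrap replications each; the
acceptance script scales the recovery set to 200 replicates and the
attenuation set to 100. These sizes put Monte-Carlo error comfortably
inside the tolerances being tested while keeping a full validation run in
the minutes range on a single CPU.

## A worked run

```{r example, eval = FALSE}
truth <- synthetic_truth(seed = 1)
records <- simulate_survey(truth)$records
fit <- bootstrap_elasticities(records, pipeline_config(), reps = 400,
                              seed = 2)
print(fit)
elasticity_table(fit)
implied_elasticities(truth, method = "estimator_limit")
```

For file-based data, `load_survey()` maps a delimited table onto the
canonical schema (with CPI deflation to a base year and annual-to-weekly
recall conversion, default divisor $365/7$), and `run_pipeline()` drives
everything from a YAML configuration, writing descriptives, first-stage
tables, cluster aggregates, elasticities and a manifest.

## Limitations

The method identifies a *market-level* demand response from spatial price
variation: it assumes prices are exogenous to cluster-level demand shocks
(a standard caveat — local demand may move local prices), common within
cluster-wave, and that quality substitution follows the separable structure
behind the correction identities. Estimates are for the smoking population
implicitly pooled across waves; participation is treated as price-inert, so
the elasticity is an intensive-margin quantity. With ~15% of households
consuming and ~6–7 consuming records per cluster, the EIV denominator is
noisy; the bootstrap propagates that noise, but designs much smaller than
~100 clusters risk non-positive corrected variances.
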