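---
title: "Spatial ecological modelling of drinking-water THMs and cancer incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial ecological modelling of drinking-water THMs and cancer incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thmspatial)
```

## The problem

Chlorination of drinking water produces trihalomethanes (THMs: chloroform,
bromoform, bromodichloromethane, dibromochloromethane, and their total),
and long-term exposure to these by-products has been linked — inconsistently
— to bowel cancer. An ecological (area-level) design relates the incidence
of colorectal cancer in administrative areas to the THM concentration of
the water supplied to them. Three methodological obstacles shape this
package:

1. **Spatial misalignment.** THMs are sampled in water *distribution
   systems*, which do not share boundaries with the administrative areas
   in which cases are counted; an area is typically covered by several
   systems (and a system supplies several areas).
2. **Incomplete, left-censored monitoring.** Monthly concentrations are
   missing at appreciable rates in early study years, and a substantial
   share of bromoform values fall below the detection limit (DL).
3. **Ecological (pure specification) bias.** Aggregating a log-linear
   individual-level risk model over the within-area exposure distribution
   biases area-level coefficients unless the within-area variance is
   modelled.

`thmspatial` implements the full chain — exposure reconstruction, indirect
standardization, a Bayesian hierarchical spatial Poisson model, the
variance-term bias correction, and posterior summaries — together with a
synthetic-study generator with known parameters, so that every stage can
be validated end to end without access to restricted registry or utility
data.

## Exposure reconstruction

Monthly site samples are processed as follows:

* **DL substitution.** Censored values are replaced by two thirds of their
  DL (`substitute_below_dl()`). The alternative rule DL/sqrt(2), a common
  epidemiological convention, is available for sensitivity analysis.
  Substitution is deterministic in the stored DL, hence idempotent.
* **Two-stage means.** Sites are averaged within system-months, observed
  months within years (`aggregate_to_zone_year()`), so an over-sampled
  month cannot dominate the annual mean.
* **Cluster-mean imputation.** A missing system-month takes the mean of
  its sister systems (same delivery system) for that month; what is still
  missing takes the system's own annual mean over observed months; the
  remainder is flagged missing (`impute_cluster_mean()`). Observed values
  are never modified, and imputed values lie inside the donor range.
* **Area weighting.** Annual system means are carried onto areas with
  weights equal to the fraction of area surface covered by each system.
  Weights are renormalized over systems with non-missing means rather
  than dropping the area — partial coverage is tolerated, only area-years
  with no covering information are dropped (and logged). The weighted
  between-system variance uses the population form and the same area
  weights; with fewer than two contributing systems it is flagged
  unavailable rather than set to zero, which feeds the variance-missing
  sensitivity analysis below.
* **Lag alignment.** Exposure in calendar year *y* informs outcomes in
  year *y + lag* (default 5), so exposure 1995–2001 covers outcomes
  2000–2006; the lag is a configuration integer. The alternative design
  (`average_years`) assigns every outcome year the mean exposure over all
  calendar years, pooling variances as the mean of yearly variances.
* **IQR scaling.** The design exposure is divided by the pooled
  interquartile range over all area-years in the analysis dataset
  (quantile type 7, linear interpolation between order statistics), so a
  unit change of the model covariate is one IQR and `exp(beta)` is the
  IRR per IQR. The within-area variance is divided by IQR^2 to stay on
  the same axis.

## Standardization

Expected counts are computed by indirect standardization from an input
table of reference age–sex rates (never estimated from the study data,
which would be circular at synthetic scale): `E = sum(person-years x
rate)` over 5-year bands from 35–39 to an open-ended 85+ stratum.
`sir()` reports O/E with exact Poisson (chi-square quantile) limits — the
interval method is the package's choice, made where the field tolerates
several conventions — and `standardized_rate()` rescales the SIR by the
reference crude rate, conventionally per 100,000.

## The hierarchical model

For area *i* and year *t* (one sex and cancer site per run; strata are
fitted as separate models, not jointly):

$$O_{it} \sim \mathrm{Poisson}(E_{it}\, e^{\eta_{it}}), \qquad
\eta_{it} = \alpha + \beta x_{it} + \tfrac{\beta^2}{2} s^2_{it}
 + \gamma' z_{it} + u_i + v_i,$$

with the log expected count as offset, `x` the IQR-scaled exposure mean,
`z` area-level covariates (calendar year as a continuous linear term,
socioeconomic score, smoking, high-risk drinking, tap-water use, region),
`u_i` iid Normal(0, 1/tau_u) exchangeable effects and `v` an intrinsic
conditional autoregressive (ICAR) field: conditional on its neighbours,
`v_i` is normal around their mean with precision `n_i tau_v`. The
pairwise form of the ICAR log-density,
`(n - G)/2 log(tau_v) - tau_v/2 sum_(i~j) (v_i - v_j)^2`, is proper only
on the sum-to-zero subspace of each of the `G` connected components; the
tests verify it against a brute-force eigendecomposition of the graph
Laplacian on small graphs.

The optional `beta^2/2 * s^2` term is the **pure-specification-bias
correction**: if individual exposures within an area are Normal(x, s^2)
and individual risk is `exp(beta X)`, the area mean risk is
`exp(beta x + beta^2 s^2 / 2)`. Its coefficient is computed from the
current `beta` draw inside the sampler — tied by construction, never a
free parameter. Records whose variance is unavailable either contribute a
zero term (`zero_term`, default) or are dropped (`restrict`), with the
retained fraction logged.

### Sampler

A bespoke Metropolis-within-Gibbs sampler (C++ core) updates `alpha`,
`beta`, each `gamma`, each `u_i` and each `v_i` by Gaussian random-walk
Metropolis and the precisions by their conjugate Gamma full conditionals.
Numerical choices:

* **Priors** (configurable): Normal(0, 10^2) on fixed effects applied to
  internally standardized covariates (draws are rescaled to the original
  covariate units on extraction); Gamma(0.5, 0.0005) on `tau_u`, `tau_v`
  — the conventional disease-mapping default.
* **Sum-to-zero** is enforced by re-centring `v` within each connected
  component after every sweep; isolated areas carry only `u`.
* **Adaptation**: proposal scales are tuned towards 0.44 acceptance in
  windows of 50 iterations during burn-in only, then frozen, so the
  post-burn-in kernel satisfies detailed balance.
* **Chains**: at least two, from dispersed starting points, with seeds
  derived deterministically from one integer; identical seed and
  specification give bit-identical chains. Burn-in defaults to half the
  iterations.
* Convergence is summarized by the variance-ratio form of the
  Gelman–Rubin statistic, `sqrt(1 + B/(nW))` — bounded below by 1 and
  exactly 1 for identical chains; it converges to the conventional
  statistic with chain length. The orchestrator flags R-hat > 1.1.
* **DIC** = Dbar + pD with pD = Dbar − D(posterior mean); the deviance is
  stored per retained draw.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults are the study conditions: 50 areas on a 10 x 5
rook-contiguity grid split 45/5 into a large and a small region; 33
distribution systems nested in 14 delivery systems, each area covered by
1–8 systems (mean 3) with Dirichlet weights; monthly THM series with
system-level lognormal variation, a seasonal sinusoid and a mild upward
trend, anchored to realistic magnitudes (chloroform ~38, bromoform ~2.8
ug/L); 15% monthly missingness before 2000 and 5% after; a bromoform DL
of 1 ug/L stepping to 3 ug/L in 1999; populations aged 35+ in eleven
bands with reference rates rising steeply with age; outcomes drawn from
the model above with true per-IQR log-IRR log(1.025) for bromoform and
sigma_u = sigma_v = 0.1. Weaker covariate effects mimic the reported
directions (incidence falling by year, lower incidence in disadvantaged
areas — RII about 0.93 across the gradient — and a higher-incidence small
region).

The generator does **not** emulate: hydraulic realism or spatially
continuous exposure surfaces; population mobility between areas;
individual-level confounders; non-normal within-area exposure
distributions; multiple correlated cancer sites. Passing tests therefore
demonstrate the correctness of the estimators under the stated generative
model, not robustness to these real-data features.

Because the outcome generator consumes the *reconstructed* exposure, the
fitted model is correctly specified and parameter recovery can be scored
exactly; reconstruction error would otherwise act as measurement-error
attenuation, which is a property of the data, not a defect of the
estimator.

## Validation strategy and problem sizes

The test suite checks, among others: exact hand-computed values for every
aggregation rule; equality of the complete-data pipeline with a
brute-force weighted-mean oracle (1e-10); exact shift equivariance;
equality of the ICAR pairwise density with the constrained-normal oracle
on random small graphs (1e-8); the Metropolis kernel against a conjugate
Gamma posterior (3 Monte-Carlo SEs at 20,000 retained draws); coverage of
the 95% credible interval for the exposure coefficient in at least 16 of
20 replicated studies at the default size (4,000 iterations, 2 chains per
fit); smaller absolute bias of the variance-term model than the naive
model in at least 16 of 20 aggregation replicates; a mean SIR of 1 over
500 null areas; and DIC preferring the spatial model in the majority of
10 replicates. The DIC comparison is run in the rare-outcome small-area
regime (about 7 expected events per area, strong spatial field): with
information-rich areas the likelihood determines the area effects almost
alone, both models fit equally and the spatial variant merely pays a
small complexity overhead, so sparse counts are where the comparison is
scientifically meaningful. These problem sizes keep the whole suite to a
few minutes while leaving the Monte-Carlo checks well-powered.

## Known limitations and open choices

* The within-area exposure variance available from monitoring is the
  *between-system* variance inside an area, used as a proxy for the
  within-area population exposure variance the bias correction formally
  requires; the two coincide only when within-system variation is
  negligible. This interpretation gap is inherent to the design.
* The socioeconomic gradient is coded as a unit-interval quintile score
  ascending in the socioeconomic index (so RII = exp(-beta) < 1 means
  less incidence in disadvantaged areas); alternative codings rescale
  `beta` but not the RII.
* Posterior point estimates are medians (order-preserving under `exp`);
  all intervals are equal-tailed 95% credible intervals computed as the
  monotone transform of coefficient percentiles, so transform and
  percentile commute exactly.
* Overlap weights are an input; deriving them from polygon geometry, and
  exposure routes other than ingestion (showering, dermal), are out of
  scope.

## A worked example

```{r example, eval = FALSE}
study <- simulate_study(seed = 1)
fit <- fit_bym(study$records, study$graph,
               covariates = c("yearc", "ses", "smoking", "drinking",
                              "tap", "region"),
               spec = model_spec(iterations = 10000), seed = 1)
summary(fit)
irr_per_iqr(fit)
rii(parameter_draws(fit, "gamma_ses"))
dic(fit)
```

Sensitivity variants (no spatial effect, averaged exposure, variance
term, restricted to non-missing variances) are separate `fit_bym()` calls
assembled with `sensitivity_grid()`; `run_study()` orchestrates the whole
pipeline and writes every input and output table plus a summary JSON.
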