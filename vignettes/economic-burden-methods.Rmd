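---
title: "Methods: measuring the household economic burden of illness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring the household economic burden of illness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `oopburden`: the models,
their assumptions, the tunable parameters, the synthetic-data generator the
test suite relies on, and the numerical and design choices made where
conventions differ across the health-economics literature.

## The setting

Household surveys in low-income settings record, for each person, illness
episodes and the out-of-pocket (OOP) amount paid for each, alongside the
household's consumption aggregates. Three questions drive the analysis:

1. **How much does illness X cost on average per month?** OOP cost data are
   zero-inflated (many episodes are treated free or not treated) and heavily
   right-skewed.
2. **How often does health spending become a catastrophe or push a household
   into poverty?** These are small-probability household-level incidences,
   often with thin illness-specific samples.
3. **Who bears the burden — the poor or the rich?**

## Data model and harmonisation

Costs are analysed in NPR per month. Acute illnesses and injuries are
reported over a 30-day recall window and taken as-is; chronic illnesses are
reported over 12 months and divided by 12, which assumes chronic care
spending is spread evenly across the year — a deliberate simplification that
understates month-to-month spikes (episodic hospitalisations).

Households are compared through consumption per *equivalent adult*,
`size^beta` with `beta = 0.56` by default, the WHO convention in
capacity-to-pay analyses. `beta` is exposed everywhere it matters
(`survey_config()`, `assign_quintiles()`, `subsistence_line()`) because the
source methodology does not pin the exponent down; `beta = 1` recovers plain
per-capita comparisons. Expenditure quintiles are formed on the weighted
ranking of consumption per equivalent adult: a household whose weight
midpoint falls at fraction *f* of total weight lands in quintile
`ceiling(5 f)`. Ties share ranks (midpoint of the tied block), so the
assignment is deterministic and independent of input order up to exact ties,
which are broken by stable input order.

## The two-stage hurdle cost model

For one illness code with episode costs `y_i >= 0`:

* **Participation hurdle** — `I(y_i > 0) ~ Bernoulli(p)`, with
  `logit(p)` given a diffuse Normal(0, 100) prior (plus optional covariates,
  also Normal(0, 100)). With no covariates the likelihood is collapsed to a
  single binomial count, which is exact and makes the fit O(1) in n.
* **Consumption hurdle** — `log y_i | y_i > 0 ~ Normal(mu, sigma^2)`, with
  `mu ~ Normal(0, 100)` and `sigma ~ half-Normal(10)`. Without covariates
  the likelihood is expressed through the sufficient statistics
  (`ybar ~ Normal(mu, 1/(n tau))`, `ss ~ Gamma((n-1)/2, tau/2)` with
  `ss = sum (log y_i - ybar)^2`), again exact and O(1) in n.
* **Combination** — applied draw by draw,
  `m = p * exp(mu + sigma^2 / 2)`,
  the probability of incurring any cost times the log-normal mean of the
  positive cost. The log-normal closed form is used rather than a smearing
  estimator, consistent with the normality assumption on the log scale; if
  the positive costs are not log-normal the combined mean inherits that
  misspecification.

Sampling runs on JAGS through `rjags`, two chains by default. Convergence is
judged by the split-chain potential scale reduction factor (PSRF) computed
in the package; a fit is accepted when every monitored parameter is below
1.1 ("close to 1" is not a number, so the conventional 1.1 cut-off is
adopted, with the split-chain variant because it also catches within-chain
trends). `fit_hurdle()` doubles the iteration count, up to three times, if
the criterion fails, then raises an error naming the offending parameters.

Degenerate inputs are handled explicitly rather than left to the sampler:

* all costs zero — there is no consumption stage; the combined mean is
  exactly zero draw-wise, participation is estimated from its prior-regularised
  posterior, and a separation warning is emitted (this occurs in practice:
  some illnesses show 0% or 100% zero-cost episodes);
* fewer than two positive costs — an explicit insufficient-data error, since
  `sigma` is unidentified;
* all positive costs identical — the posterior genuinely collapses to the
  point (`mu = log c`, `sigma = 0`) because the likelihood puts unbounded
  mass at `sigma -> 0`; the fit returns that point mass with a warning.

## Catastrophic payment, capacity to pay, impoverishment

A payment is catastrophic when it *strictly exceeds* `z` times a resource
base; "exceeds" is read literally, and the boundary case has measure zero on
continuous data. Four standard rules ship: 10% and 15% of total consumption,
40% of non-food consumption, 40% of capacity to pay. Disease-specific flags
compare the episode's own monthly cost against its household's base;
household-level flags use the household's summed OOP.

Capacity to pay is total consumption minus a subsistence allowance. The
subsistence line is the weighted mean food spending per equivalent adult
among households whose food share sits in the 45th–55th weighted percentile
window (widened symmetrically with a warning if empty) — the WHO
construction. Households spending less on food than the norm have their
actual food spending subtracted instead, and the result is floored at a
small positive value with a warning.

Impoverishment uses the differencing convention: a household counts only if
its per-capita consumption is at or above the poverty line before
subtracting OOP and strictly below it after, so the already-poor are never
flagged. The poverty line is required configuration; the synthetic default
places it at the 20th percentile of per-capita consumption so that
impoverishment code paths are actually exercised. Headcounts are
person-weighted (household weight times household size).

## Bayesian incidence models and pooled priors

Incidences are estimated by Bayesian logistic regression on the 0/1 flags.
The default prior on every coefficient is the weakly informative
Cauchy(0, 2.5); following the convention that motivates that prior, numeric
covariates are centred and scaled to SD 0.5 and binary covariates centred
(internally — reported incidences are unaffected because prediction uses the
same transformed design). For household-level indicators an informative
alternative replaces only the intercept prior: published incidences are
pooled by DerSimonian–Laird random-effects meta-analysis on the logit scale
(`pool_estimates()`), and the pooled mean and SD become a
Normal(logit mean, logit SD) intercept prior (`prior_from_pooled()`). A
pooled-prior table for South and South-East Asia ships with the package; its
rows are treated as fixture priors, not as reproduction targets, because the
underlying study-level inputs are not public. Study-level standard errors
come from the CI width divided by 2×1.96, or from the delta-method binomial
SE when counts are given; boundary proportions get a 0.5/(n+1) continuity
correction. Degenerate prior SDs are floored at 0.05 with a warning.

The *adjusted* incidence is a marginal quantity: per posterior draw, the
mean of the fitted probabilities over the observed covariate distribution
(age, sex, wealth quintile, urban/rural). This reproduces
"incidence adjusted by ..." as sample standardisation rather than as a
covariate-profile prediction. For household-level flags the individual-level
covariates are proxied by the household's first listed member.

## Inequality measurement

The concentration index is the convenient-covariance form
`C = 2 cov_w(y, r) / mean_w(y)` over weighted fractional ranks
`r_i = (cumulative weight before i + w_i/2) / total weight`, poorest first.
This form is exact for microdata and trivially checkable against a direct
covariance evaluation, which is why it was preferred over grouped formulas.
Negative C means the burden concentrates among the poor. The concentration
curve accumulates burden share against population share in rank order; twice
the area between curve and diagonal equals C up to discretisation, a
geometric identity the tests exploit. The ranking variable defaults to
consumption per equivalent adult and is configurable; no standard errors are
attached to C. Erreygers/Wagstaff corrections for bounded variables are out
of scope.

## Trends and reporting

Average annual rate of change is compound growth:
`100 ((v_end / v_start)^(1/years) - 1)`, applied to values already expressed
in a common price year. Conversions use GDP deflators (65.8 for 1995, 192.8
for 2010) and the fixed 2010 exchange rate of 73.16 NPR/USD. The compound
form is not stated in the published tables this package mirrors, but
applying it to the printed 1995/2010 value pairs reproduces the printed
rate column to one decimal for 31 of 38 rows; the seven misses are off by
exactly one final-digit unit, the signature of the publishers rounding from
unrounded inputs. The shipped reference tables carry an `exact` flag making
that distinction explicit, and the tests assert exactness only where it
holds and one-digit agreement everywhere. Display rounding is
half-away-from-zero (matching published tables); full precision is kept
internally.

## The synthetic survey generator

`simulate_survey()` emulates the structure of a national living-standards
survey: negative-binomial household sizes (mean 4.9), log-normal total
monthly consumption (median NPR 9,000, log-SD 0.55), Beta food shares (mean
0.47, SD 0.10 — between the 41% and 53% food shares seen across survey
rounds), 25% urban households, a four-band age pyramid typical of a young
population, and an eight-code illness table whose prevalences and
zero-expenditure fractions (0.05–0.35) echo the magnitudes reported in
national tabulations. Costs follow the hurdle model's own generative
process — a point mass at zero with probability `pi0`, otherwise
log-normal — so parameter recovery is a fair test of the estimator, not of
model misspecification. Optional covariate effects shift both hurdles'
linear predictors; they are generator-level vectors shared across codes
(simpler than per-code effect tables and sufficient to test adjusted
models), and default to zero so the analytic mean
`(1 - pi0) exp(mu + sigma^2/2)` is exact.

Each generated dataset carries its ground truth: analytic mean costs, and
catastrophic/impoverishment incidences counted by `enumerate_truth()`, a
deliberately plain loop-based enumerator kept independent of the vectorised
pipeline so the two can be compared exactly. Costs are drawn independently
of consumption, so a few percent of households draw OOP above total
consumption — real surveys embed OOP inside the consumption aggregate, which
this generator does not emulate; the pipeline floors post-OOP consumption at
zero with a warning. Other features of real data the generator does not
attempt: cluster sampling and design weights beyond a constant, seasonality,
recall bias, and correlation between illness risk and wealth. Passing tests
therefore demonstrate correctness of the estimators under the stated
generative process, not robustness to those real-data complications.

## Problem sizes and runtime choices

The test-suite fits use 2 chains with 1,000–1,500 post-warm-up iterations;
the sufficient-statistic likelihood collapse makes each hurdle fit fractions
of a second, so interval calibration is checked over 50 independent
replicates at 2,000 episodes each, and estimator consistency over 10 seeds
at each of 500/2,000/8,000 episodes. The default synthetic population is
1,000 households (~4,800 persons); this is ample for every property tested
while keeping the full suite under half a minute.

## Known limitations

* The log-normal consumption hurdle has no robustness guard against heavy
  tails beyond log-normal; with very few positive costs and diffuse priors
  the posterior of `sigma` (hence of the combined mean) can be extremely
  wide — the published analyses flag exactly this for rare conditions.
* Survey-design variance (strata, PSU) is out of scope; credible intervals
  are model-based.
* Quintile construction and the Bayesian fits treat weights as relative
  frequencies; weighted likelihoods for the Bayesian models are not
  implemented (weights in the shipped generator are 1).
* The concentration index is reported without uncertainty.
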