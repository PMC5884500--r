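# oopburden

Measuring the household economic burden of illness from survey data:
disease-specific out-of-pocket (OOP) health expenditure, catastrophic health
payment, impoverishment, and the socioeconomic inequality in that burden.

The package is aimed at health economists and epidemiologists working with
living-standards-style household surveys (a household table with consumption
aggregates, an individual roster, an illness-episode table with reported OOP
amounts), in settings where OOP payments dominate health financing and cost
data are zero-inflated and right-skewed.

## What it computes

**Mean OOP cost per illness — Bayesian two-stage hurdle model.** For episode
costs *y ≥ 0* of one illness:

- participation: `I(y > 0) ~ Bernoulli(p)`, logistic regression with diffuse
  Normal(0, 100) priors;
- consumption: `log y | y > 0 ~ Normal(μ, σ²)`, with `σ ~ half-Normal(10)`;
- combined mean, draw by draw: `m = p · exp(μ + σ²/2)`,

with 95% credible intervals from the posterior of `m`, two MCMC chains (via
JAGS), and convergence checked with a split-chain potential scale reduction
factor (PSRF < 1.1, iterations doubled automatically until met).

**Catastrophic payment and impoverishment.** Flags at the four standard
thresholds — OOP strictly exceeding 10% or 15% of total consumption, 40% of
non-food consumption, or 40% of capacity to pay (total consumption minus a
food-needs subsistence allowance built from the 45th–55th food-share
percentile window) — plus poverty headcounts with and without OOP, whose
difference is the impoverishing effect of health spending. Incidences are
estimated by Bayesian logistic regression with a weakly informative
Cauchy(0, 2.5) prior, or with an informative intercept prior built by
DerSimonian–Laird meta-analytic pooling of published incidences
(`pool_estimates()` → `prior_from_pooled()`), with optional adjustment for
age, sex, wealth quintile and residence via sample standardisation.

**Inequality.** Concentration curves and the concentration index
`C = 2 cov_w(y, r) / ȳ` over weighted fractional wealth ranks (negative C:
burden concentrated among the poor).

**Trends.** GDP-deflator conversion, NPR→USD conversion, and compound
average annual rates of change `100((v_end/v_start)^{1/T} − 1)`, with report
assembly across survey rounds.

A seeded synthetic-survey generator (`simulate_survey()`) with brute-force
ground truth makes the whole pipeline testable end to end without any
external data.

## Worked example

```r
library(oopburden)
library(dplyr)

sim  <- simulate_survey(sim_config(n_households = 1000), seed = 42)
data <- assign_quintiles(sim$data)
data
#> <survey_dataset>
#>   households:  1000
#>   individuals: 4875
#>   episodes:    1262 (8 illness codes)

# 1. Mean monthly OOP cost of heart conditions (NPR/month)
fit_hurdle(data, "heart_condition", hurdle_spec(), seed = 1)
#> <hurdle_fit> code=heart_condition n=56 (positive 49)
#>   mean monthly OOP: 3851.073 (95% CrI 2648.465-5716.916), max PSRF 1.000
```

The generator's analytic truth for this code is `(1 − π₀)exp(μ + σ²/2) ≈
3518` NPR/month, inside the credible interval; with 56 episodes the interval
is wide, as it is for rare conditions in real surveys.

```r
# 2. Household catastrophic payment at 10% of total consumption
fl <- catastrophic_flags(data, threshold_rule("total_consumption", 0.10), "household")
fit_incidence(fl, spec = hurdle_spec(), seed = 1, scope = "household")
#> <incidence_fit> scope=household unadjusted n=1000 events=278
#>   incidence 0.2785 (95% CrI 0.2503-0.3073), max PSRF 1.000, prior cauchy(0, 2.5)

# 3. Impoverishment: poverty headcount with and without OOP payments
headcounts(data, sim$truth$poverty_line)
#>   pre_oop post_oop difference
#> 1   0.199    0.298     0.0995
```

27.8% of households exceed the 10% threshold, and subtracting OOP payments
from consumption raises the poverty headcount by 10.0 percentage points
under the synthetic poverty line (the 20th pre-OOP percentile).

```r
# 4. Who bears the burden? Concentration index over wealth ranks
df <- mutate(data$households,
             flag = fl$flag[match(household_id, fl$household_id)],
             pea  = total_exp / equivalent_size(size))
concentration(df, flag, pea, weight, scope = "household")
#> <concentration> scope=household n=1000 index=-0.3289

# 5. Trend: published mean chronic-illness OOP went 5.9 -> 11.6 USD over 15 years
annual_rate_of_change(5.9, 11.6, 15)
#> [1] 4.610128   # 4.6 %/year
```

The negative concentration index says catastrophic payments fall
disproportionately on poorer households. `autoplot()` draws the
concentration curve; `tidy()`/`glance()` return tibbles from every fitted
object.

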