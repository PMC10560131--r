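# frailtyEH

Individual frailty excess hazard models for relative survival.

## The problem

In population-based cancer survival studies the cause of death is usually
unavailable or unreliable, so cancer-specific survival is studied in the
*relative survival* framework: an individual's mortality hazard is decomposed
as

    h(t; x) = hP(age + t; year + t, z) + hE(t; x),

where `hP` is the expected background mortality rate taken from a life table
(indexed by attained age, calendar year and demographic strata `z`) and `hE`
is the *excess hazard* attributable to the cancer. The *net survival*
`SN(t; x) = exp{-HE(t; x)}` — the survival implied by the excess hazard
alone — is the quantity used for international comparisons and
policy-making.

Registry data never record every relevant covariate. Unobserved individual
heterogeneity (UIH) biases excess hazard estimates and distorts net
survival. `frailtyEH` addresses this with an *individual frailty* on the
excess hazard: a unit-mean positive random effect `λ` with variance `b`
multiplying `hE`, so the conditional hazard is `hP + λ hE`. Marginalizing
over a gamma frailty gives closed forms:

    marginal net survival   S̃N(t; x) = (1 + b·HE(t; x))^(-1/b)
    marginal hazard         h̃(t; x)  = hP + hE(t; x) / (1 + b·HE(t; x))

The weight `ω = 1/(1 + b·HE)` is the conditional mean frailty among
survivors — frailties progressively select the healthier patients, and `b`
measures how much unobserved heterogeneity the data carry. As `b → 0` the
classical excess hazard model is recovered.

The excess hazard itself follows the flexible *general hazard* (GH)
structure

    hE(t; x) = h0(t · exp(wᵀα); θ) · exp(xᵀβ),     w ⊆ x,

which nests proportional hazards (`α = 0`), accelerated hazards (`β = 0`)
and accelerated failure time (`α = β, w = x`). The default baseline `h0` is
the power generalized Weibull (PGW) distribution
`S0(t) = exp{1 - [1 + (t/σ)^ν]^(1/γ)}`, which covers increasing,
decreasing, unimodal and bathtub hazard shapes; log-normal and log-logistic
baselines are also available.

The package provides:

* exact hazard / cumulative hazard / quantile functions for the baselines
  and the GH structure, including exact inverse-transform simulation of
  event times (with or without a frailty multiplier);
* life-table handling: long-format readers/writers, piecewise-constant rate
  lookup on 1-year Lexis squares, cumulative background hazard over
  follow-up, exact simulation of other-cause death times, and a synthetic
  Gompertz table generator;
* maximum-likelihood fitting of the classical and gamma-frailty models
  against life-table background mortality, with Wald confidence intervals,
  AIC comparison, and Monte-Carlo confidence bands for net survival curves;
* net survival at individual, subgroup and population scope, classical or
  frailty-marginalized;
* a deterministic simulation engine with the built-in scenarios used by the
  replication studies (`Sc1`, `Aim2_close`, `Aim2_far`), performance
  tabulation (bias, coverage, empirical SD) and a missing-covariate
  analysis workflow.

## Worked example

Fit the classical and frailty models to a simulated cohort of 2000 patients
(the `Sc1` design: PGW baseline, four covariates acting on both the time
scale and the hazard level, gamma frailty `b = 0.5`, life-table other-cause
deaths, ~5% drop-out, administrative censoring at 5 years):

```r
library(frailtyEH)

lt <- read_life_table(system.file("extdata",
        "synthetic_gompertz_lifetable.tsv", package = "frailtyEH"))
sc <- builtin_scenario("Sc1", n = 2000)
d  <- generate_cohort(sc, lt, seed = 7)

covs  <- c("agec", "sex", "X1", "X2")
fit_c <- fit_excess_hazard(d, lt, model = "classical",
                           hazard_covs = covs, time_covs = covs)
fit_f <- fit_excess_hazard(d, lt, model = "frailty",
                           hazard_covs = covs, time_covs = covs)
fit_f
#> Excess hazard model (frailty, pgw baseline, gamma frailty)
#> n = 2000  events = 1212  logLik = -2179  AIC = 4383
#>   parameter estimate      se  lower   upper
#>       sigma   0.5889 0.13525 0.3755  0.9237
#>          nu   1.7978 0.16580 1.5005  2.1539
#>       gamma   8.5489 2.09700 5.2859 13.8263
#>  alpha:agec   1.0920 0.09308 0.9095  1.2744
#>   alpha:sex   0.8824 0.16894 0.5512  1.2135
#>    alpha:X1   0.7472 0.16482 0.4242  1.0703
#>    alpha:X2   0.9787 0.16513 0.6550  1.3023
#>   beta:agec   1.0368 0.05179 0.9353  1.1383
#>    beta:sex   0.9836 0.10345 0.7809  1.1864
#>     beta:X1   0.7731 0.10283 0.5716  0.9747
#>     beta:X2   0.9114 0.10240 0.7107  1.1121
#>           b   0.5468 0.34026 0.1615  1.8514
```

All estimates sit near their generating values (`σ = 0.75, ν = 1.75,
γ = 8`, all coefficients 1, `b = 0.5`); intervals for the positive
parameters are computed on the log scale, so their endpoints are always
positive. AIC prefers the frailty model on this heterogeneous cohort:

```r
aic_compare(list(classical = fit_c, frailty = fit_f))
#>       model  k    loglik      aic delta_aic
#> 1   frailty 12 -2179.307 4382.614  0.000000
#> 2 classical 11 -2181.196 4384.393  1.778785
```

Population net survival (the average of the individual frailty-marginal
curves over the cohort), with a Monte-Carlo confidence band from the
asymptotic normality of the MLE:

```r
population_net_survival(fit_f, d, t_grid = seq(0, 5, 1))[, 1:2]
#>   t  estimate
#> 1 0 1.0000000
#> 2 1 0.6465110
#> 3 2 0.5554065
#> 4 3 0.5040284
#> 5 4 0.4689322
#> 6 5 0.4426325

mc_ci_net_survival(fit_f, d, t_grid = seq(0, 5, 1), n_draws = 500, seed = 1)
#>   t estimate lower upper
#> 1 0    1.000 1.000 1.000
#> 2 1    0.647 0.629 0.688
#> 3 2    0.555 0.538 0.611
#> ...
```

So an estimated 44% of this simulated population would survive 5 years if
the cancer were the only cause of death.

A thin command-line wrapper (`exec/frailtyeh`) exposes the same
functionality as `fit`, `netsurv` and `simulate` subcommands for
shell-based pipelines.

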