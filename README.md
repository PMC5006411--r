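# rdgee

Absolute risk-difference estimation for clustered binary outcomes, built for
multicenter and cluster randomized trials where subjects treated at the same
center have correlated outcomes.

## The problem

Reporting guidelines ask for the absolute risk difference
RD = π(1) − π(0) — the difference in outcome probability between the
treatment and control conditions — alongside any relative measure. In a
multicenter trial this has to be estimated while accounting for
within-center correlation (and, often, a baseline covariate), yet the
regression models that deliver the RD directly are exactly the ones with
convergence problems near the probability boundary. `rdgee` implements the
six population-averaged (marginal) regression routes to the RD, all fitted
by generalized estimating equations (GEE) with an exchangeable working
correlation, plus the naive pooled 2×2 comparator, and a simulation
framework for benchmarking them.

The mean models are

```
g(pi_ij) = alpha + beta * x_ij (+ gamma * z_ij)
```

for subject *i* in center *j*, with treatment indicator *x*, optional binary
baseline covariate *z*, and link *g*:

| method | family / link | RD estimate |
|---|---|---|
| `binomial-identity` | binomial, identity | β̂ directly |
| `poisson-identity` | Poisson, identity | β̂ directly |
| `normal-identity` | normal (linear model), identity | β̂ directly |
| `binomial-log` | binomial, log | marginal standardization |
| `poisson-log` | Poisson, log | marginal standardization |
| `binomial-logit` | logistic | marginal standardization |
| `unadjusted` | pooled 2×2 table | p̂₁ − p̂₀ |

Marginal standardization averages each subject's two counterfactual fitted
probabilities over the whole sample, RD = (1/n) Σᵢⱼ (π̂ᵢⱼ(1) − π̂ᵢⱼ(0)), with
a delta-method standard error. All GEE standard errors are robust
(sandwich), and with J centers and p non-intercept regressors the robust
variance is multiplied by the small-sample factor J/(J − p − 1) before the
95 % Wald interval RD ± 1.96·SE is formed. The Poisson and normal families
are deliberate working misspecifications for Bernoulli data — the sandwich
variance is what makes them valid.

## Worked example

The packaged dataset is an 8-center randomized trial of an active drug
against control for curing an infection (273 subjects; success rates range
from 0 to 86 % across centers, ICC ≈ 0.22).

```r
library(rdgee)
td <- beitler_landis(expand = TRUE)
rd_table(td)
#>              method         rd         se      ci_low   ci_high       icc converged
#> 1 binomial-identity 0.12624775 0.05861507  0.01136222 0.2411333 0.2168909      TRUE
#> 2  poisson-identity 0.12505658 0.05772632  0.01191299 0.2382002 0.2175108      TRUE
#> 3   normal-identity 0.12732724 0.05957026  0.01056954 0.2440849 0.2156090      TRUE
#> 4      binomial-log 0.12624776 0.05861507  0.01136222 0.2411333 0.2168909      TRUE
#> 5       poisson-log 0.12505658 0.05772632  0.01191299 0.2382002 0.2175108      TRUE
#> 6    binomial-logit 0.12624776 0.05861507  0.01136222 0.2411333 0.2168909      TRUE
#> 7        unadjusted 0.09440559 0.05848541 -0.02022580 0.2090370        NA      TRUE
```

All six GEE routes agree: the active drug improves the cure probability by
about 12.6 percentage points (95 % CI roughly 1 to 24 points), a
statistically significant effect. The pooled 2×2 analysis, which ignores
the centers, gives a smaller and non-significant 9.4 points — the gap comes
from the large between-center variability (ICC ≈ 0.22) interacting with
imbalanced arm sizes per center. Dropping the most imbalanced center
(center 2, 20 active vs 32 control) reconciles the two:

```r
td7 <- with(td, trial_data(center[center != "2"], treatment[center != "2"],
                           outcome[center != "2"]))
rd_from_identity(fit_gee(td7, "binomial", "identity"))
#> binomial-identity: RD = 0.133  SE = 0.073  95% CI (-0.011, 0.277)
unadjusted_rd(td7)
#> unadjusted: RD = 0.129  SE = 0.060  95% CI (0.011, 0.248)
```

## Simulation framework

`simulate_trial()` generates trials from an additive-risk (identity) or
multiplicative-risk (log) true model with a normal random center effect
calibrated to a target ICC; `run_scenario()`/`run_grid()` fit all seven
methods to each replicate and report convergence rate, bias and 95 % CI
coverage, conditioning on convergence per method:

```r
sp <- scenario_spec("identity", pi_c = 0.25, true_rd = 0.10, icc = 0.05,
                    n_per_center = 10)
run_scenario(sp, n_reps = 100, seed = 7)[, 1:4]
#>              method convergence_rate         bias coverage
#> 1 binomial-identity                1 -0.002555556     0.96
#> ...
#> 7        unadjusted                1 -0.002555556     0.95
```

A thin command-line wrapper (subcommands `analyze`, `simulate`, `grid`)
lives at `system.file("cli", "rdgee.R", package = "rdgee")`.

See `vignettes/risk-difference-gee.Rmd` for the estimators, the generator
calibration, and the numerical decisions.

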