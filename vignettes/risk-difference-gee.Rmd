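---
title: "Estimating risk differences for clustered binary outcomes with GEE"
author: "rdgee"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating risk differences for clustered binary outcomes with GEE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdgee)
```

## The estimation problem

In a multicenter randomized trial with a binary outcome, subjects enrolled
at the same center tend to have correlated outcomes: centers differ in
case mix, practice and baseline risk. When randomization is stratified by
center, or when between-center variability is large, an analysis that
ignores the centers gets the standard error of the treatment effect wrong —
usually too small when center variability is large, sometimes conservatively
too large. This package estimates the absolute risk difference
$\mathrm{RD} = \pi(1) - \pi(0)$ under that correlation structure.

All models are *marginal* (population-averaged) and fitted by generalized
estimating equations with an **exchangeable working correlation**: any two
subjects in the same center share a common correlation $\rho$, subjects in
different centers are uncorrelated. The mean model for subject $i$ in
center $j$ is

$$ g(\pi_{ij}) = \alpha + \beta\, x_{ij} + \gamma\, z_{ij}, $$

with treatment indicator $x_{ij}$, an optional binary baseline covariate
$z_{ij}$, and no center term — center effects enter only through the
working covariance, which is what makes counterfactual prediction
unambiguous. Six family/link pairs are supported: binomial, Poisson and
normal families with the identity link, binomial and Poisson with the log
link, and the logistic model. The Poisson and normal families are knowingly
misspecified for Bernoulli data; the robust sandwich covariance makes their
inference valid anyway, and their weighting often behaves better near the
probability boundary than the binomial's $\mu(1-\mu)$ variance.

### From coefficients to a risk difference

* **Identity link.** $\hat\beta$ *is* the RD.
* **Log and logit links.** $\hat\beta$ is a log relative risk or log odds
  ratio. The RD comes from marginal standardization: predict each subject's
  outcome probability twice, with treatment set to 1 and to 0 while keeping
  the subject's own covariate value, and average the differences,
  $$ \widehat{\mathrm{RD}} = \frac1n \sum_{ij} \left(\hat\pi_{ij}(1) -
     \hat\pi_{ij}(0)\right). $$
  Without a covariate this collapses to
  $g^{-1}(\hat\alpha+\hat\beta) - g^{-1}(\hat\alpha)$, which the test suite
  asserts exactly.

The delta method propagates the robust coefficient covariance $V$ into the
standardized RD: $\mathrm{SE} = \sqrt{\nabla g^\top V \nabla g}$ with the
gradient averaged over subjects; writing $v_t = \pi_t(1-\pi_t)$,

* log link: $\partial_\alpha = \pi_1-\pi_0$, $\partial_\beta = \pi_1$,
  $\partial_\gamma = z(\pi_1-\pi_0)$;
* logit link: $\partial_\alpha = v_1-v_0$, $\partial_\beta = v_1$,
  $\partial_\gamma = z(v_1-v_0)$.

Every analytic gradient is checked in the test suite against a central
finite-difference oracle to six significant digits.

### Small-sample correction and intervals

Cluster-robust variances are biased downward with few clusters. With $J$
centers and $p$ non-intercept regressors, the robust *variance* of the RD
is multiplied by $J/(J-p-1)$ — equivalently the SE by its square root —
before forming the Wald interval $\widehat{\mathrm{RD}} \pm 1.96\,
\mathrm{SE}$. Published corrected SEs and intervals for the packaged
8-center trial reconstruct exactly under this variance-scale reading (raw
sandwich SE 0.0508, corrected $0.0508\sqrt{8/6}=0.0586$, interval
$(0.011, 0.241)$), and would not under an SE-scale reading; that
reconstruction is pinned by a regression test. The $z$-quantile is fixed at
1.96, not a $t$-quantile, and the unadjusted 2×2 method gets the plain Wald
SE with no correction.

## The GEE engine

The fitter is a direct Fisher-scoring implementation. For the
compound-symmetry working correlation the inverse is closed-form,
$R^{-1} = \tfrac{1}{1-\rho}\left(I - \tfrac{\rho}{1+(n_j-1)\rho}
\mathbf{1}\mathbf{1}^\top\right)$, so all cluster sums reduce to grouped
row sums and no per-cluster matrix inversion is needed; one fit on a
180-subject trial takes well under a millisecond, which is what makes the
factorial simulation cheap.

Choices that matter:

* **Correlation estimate.** $\hat\rho$ is the scale-adjusted moment
  estimator from Pearson-residual cross-products,
  $\hat\rho = \frac{1}{\hat\phi}\sum_j \sum_{i<i'} e_{ij}e_{i'j} \big/
  \left(\sum_j n_j(n_j-1)/2 - q\right)$, with $q$ the number of regression
  coefficients and $\hat\phi$ the Pearson dispersion. Software conventions
  differ in the denominator by a few units; on the packaged data the
  resulting $\hat\rho$ spread across the six models is 0.216–0.218.
* **Initialization.** Coefficients start at the independence GLM fit, the
  convention of estimating-equation software. R's unguarded log-binomial
  IRLS is the first place that model hits the probability boundary; a
  failed initializer is reported as the model failing to run. The other
  models fall back to moment starting values from the arm rates, because
  step-halving protects their iterations.
* **Convergence and admissibility.** Convergence means the largest
  coefficient change fell below `tol` (default $10^{-6}$) within `max_iter`
  (default 100) *and* all estimates and SEs are finite. Iterates must keep
  fitted means inside the family's admissible range (binomial $(0,1)$,
  Poisson $(0,\infty)$); up to 20 step-halvings are used to repair an
  inadmissible update — except for the **log-binomial**, where any iterate
  with a fitted mean at or above 1 counts as non-convergence outright. That
  model's fragility near the boundary is a finding to be measured, not a
  defect to engineer away; rescuing it with step-halving would hide the
  phenomenon the simulation study exists to quantify. Numerical failure is
  never an exception: the fit returns `converged = FALSE` so harness code
  can count it.
* **Identifiability guard.** Estimating $\rho$ needs at least one center
  with two subjects beyond the coefficient count; all-singleton clustering
  is a structural error.

## The data generators

`simulate_trial()` emulates a stratified multicenter RCT. Defaults: 18
centers (a small-number-of-centers regime typical of perinatal trials),
treatment allocated within center by permuted blocks of four (two treated
per block; a trailing incomplete block splits its extra subject by a fair
coin, so arms within a center never differ by more than one), covariate
prevalence 0.3, and a normal random center effect $\nu_j$ on the link
scale:

* identity link: $\pi_{ij} = \alpha + \beta x_{ij} + \gamma z_{ij} +
  \nu_j$, with $\alpha = \pi_c$, $\beta = \mathrm{RD}$,
  $\gamma \in \{0, 0.5\pi_c\}$ (a 50 % risk increase), and
  $\sigma^2 = \rho\,\bar\pi(1-\bar\pi)$ where
  $\bar\pi = \alpha + 0.5\beta + 0.3\gamma$;
* log link: $\log \pi_{ij} = \alpha + \beta x_{ij} + \gamma z_{ij} +
  \nu_j$, with $\alpha = \log\pi_c$, $\gamma \in \{0, \log 1.5\}$,
  $\beta = \log(1 + \mathrm{RD}/e^{\alpha + 0.3\gamma})$, and the
  delta-method variance transfer $\sigma^2 = \rho\,(1-\bar\pi)/\bar\pi$
  with $\bar\pi = e^{\alpha+0.5\beta+0.3\gamma}$.

If any subject's $\pi_{ij}$ falls outside $(0,1)$ a fresh $\nu_j$ is drawn
for that center — allocation and covariates stay fixed, since $\nu_j$ is
the only center-level random quantity — until all probabilities are
strictly interior (open interval: a center that is deterministically all
events or all non-events is not a usable cluster). Scenarios whose highest-
risk cell already exceeds 1 at $\nu_j = 0$ fail at construction.

Two calibration facts worth knowing before interpreting simulation output:

* **Truncation.** The rejection step truncates the normal center-effect
  distribution, shrinking realized between-center variance when the $(0,1)$
  bounds sit within about 3 standard deviations. This mirrors the design
  being emulated and is left uncorrected; the parameter-recovery tests
  therefore use cells where the bounds are far away (e.g. the ICC-recovery
  check at $\pi_c = 0.50$, $\rho = 0.10$, where shrinkage is under 3 %).
* **The log-link marginal RD is not exactly the nominal RD.** Within a
  center, the identity-link RD is $\beta$ regardless of $\nu_j$, so the
  identity generator's population marginal RD equals the nominal value
  exactly. Under the log link the center effect is multiplicative:
  the population marginal RD is
  $E[e^{\nu}]\,(0.7 + 0.3\cdot 1.5)\, e^{\alpha}(e^{\beta}-1)$, where
  $E[e^{\nu}] \approx e^{\sigma^2/2}$ (truncated) and the covariate mixture
  mean $0.7+0.3\cdot1.5 = 1.15$ differs from the $e^{0.3\gamma} = 1.129$
  used in the $\beta$ calibration. At $\pi_c=0.10$, RD $=0.15$,
  $\rho=0.05$ with covariate this gives 0.167 rather than 0.150 — the
  generator is exact to its own formulas, and correctly fitted models will
  estimate *its* marginal RD, so performance measured against the nominal
  value shows an apparent upward bias that grows with RD and ICC. This is a
  property of the design under study; the recovery tests for the log link
  use a low-heterogeneity cell ($\pi_c=0.25$, RD $=0.05$, $\rho=0.01$)
  where the factor is negligible, and a separate test checks the generator
  against its analytic population value in the harsh cell.

Seeding: every replicate's dataset is a pure function of (master seed,
scenario index, replicate index) through a 31-bit mixing function, so grid
results are reproducible independent of execution order.

## The simulation harness

`run_scenario()` applies all seven methods to each replicate and reports,
per method: convergence rate, bias (mean of estimate minus truth) and 95 %
CI coverage with closed-interval inclusion. Bias and coverage condition on
the replicates where *that* method converged — non-convergence is
informative, and a complete-case-across-methods rule would let the fragile
log-binomial censor the others' evaluation. `factorial_grid()` enumerates
the full benchmark design (2 true links × 4 RDs ∈ {0, 0.05, 0.10, 0.15} ×
3 control rates {0.10, 0.25, 0.50} × 3 ICCs {0.01, 0.05, 0.10} × 3 center
sizes {10, 50, 100} × 2 covariate settings = 432 scenarios).

Problem sizes used by the shipped checks, chosen to give useful Monte-Carlo
precision on a single core: the bias and coverage checks run targeted
scenarios at 1000 replicates (binomial half-width on a 95 % coverage
estimate ≈ 1.4 points, which the acceptance bands absorb); non-convergence
checks use 200 replicates; the reproducibility script sweeps the 36
additive-risk no-covariate cells at 10 subjects per center, 1000
replicates each. The full 432 × 1000 × 7 design runs with
`run_grid(factorial_grid(), 1000)` in a few hours.

## What the tests do and do not establish

The fitter is validated on real multicenter data against an independent
GEE implementation (coefficients, robust SEs and $\hat\rho$ frozen to six
decimals), against closed-form least squares and GLM fits under forced
independence, and against a cluster-robust sandwich oracle. The simulation
checks establish behaviour *under the generator's assumptions*: equal
center sizes, a single binary covariate, normal center effects on the link
scale, no treatment-by-center or treatment-by-covariate interaction, and
missing-free data. Real trials violate several of these at once —
unequal center sizes, multiple or continuous covariates, and informative
missingness are all out of scope here — so passing tests certify the
estimators' calibration in this reference regime, not universally.

Known limitations: identity- and log-link fitted probabilities (and hence
RD estimates standardized from them) can escape $[0,1]$ and are flagged
with a warning rather than truncated; model-based (non-robust) SEs,
alternative small-sample corrections and bootstrap intervals are not
implemented; the unadjusted method is the plain Wald 2×2 analysis without
continuity correction, matching its conventional presentation.
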