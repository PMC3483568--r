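---
title: "Borrowing historical trial data with power priors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Borrowing historical trial data with power priors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Secondary subgroup questions in randomized trials -- "does a baseline
characteristic moderate the treatment effect?" -- are chronically
under-powered: a trial sized for a main effect has only a fraction of the
power needed to detect an interaction of the same magnitude.  When a
completed trial of the same medication in a comparable population exists,
it is statistically attractive to let that historical evidence sharpen the
interaction estimate, *provided* the analyst can control how much weight
the old data receive.

`powerpriornb` implements this program for the setting that motivated it:
two double-blind placebo-controlled trials of levodopa/carbidopa for
cocaine dependence, a count outcome (the Treatment Effectiveness Score,
one point per cocaine-negative urine sample, zero for positive or missing
samples), and baseline marijuana use (self-reported days of use in the
past 30) as the candidate moderator.

## Model

For subject $i$ with treatment indicator $med_i$ (placebo = 0, active = 1)
and moderator $mj_i$ (raw days, not centered or scaled), the outcome is
negative binomial (NB2):

$$
y_i \sim \mathrm{NB}(\mu_i, r), \qquad
\log \mu_i = \beta_0 + \beta_1\, med_i + \beta_2\, mj_i +
             \beta_3\, med_i \times mj_i ,
$$

with variance $\mu + \mu^2/r$.  Exponentiated coefficients are risk
ratios: $e^{\beta_2}$ is the multiplicative change in expected score per
additional day of use under placebo, $e^{\beta_2 + \beta_3}$ the same
under active treatment, and $e^{\beta_3}$ -- the estimand of interest --
the ratio of those two slopes.  Because the moderator enters raw, "per
additional day" is the literal unit of the slopes.

### Priors and the power prior

The initial priors are deliberately vague and centered on the null:
independent Normal$(0, 10^6)$ on each coefficient, and Uniform$(0, 1)$ on
the *inverse* dispersion $1/r$.  The change of variables gives the density
$r^{-2}$ on $(1, \infty)$; the Jacobian is part of the stated contract
(`log_prior()`), and the sampler works on $\log(r - 1)$ with its own
Jacobian so the two representations agree.  Reading the dispersion rows of
the motivating analysis as an NB2 *size* (values near 30--40 are plausible
as a size, implausible as a multiplicative over-dispersion factor) is the
one place where the source material is ambiguous; the package adopts the
size reading throughout rather than carrying a second convention through
every interface.

Historical data $D_0$ enter through the power prior: the posterior given
the current data $D_1$ is

$$
p(\theta \mid D_1, D_0, a_0) \;\propto\;
  L(\theta; D_1)\, L(\theta; D_0)^{a_0}\, p(\theta),
  \qquad 0 \le a_0 \le 1 .
$$

$a_0 = 0$ discards the historical trial, $a_0 = 1$ weights it like current
data, and on the log scale the target is affine in $a_0$ -- a property the
test suite exploits as an exact oracle.  Estimating $a_0$ from the data is
known to collapse toward zero even for identical datasets, so the package
follows the *conditional* power-prior practice: fix $a_0$ on a grid
(default $0, 0.1, \ldots, 1$) and present the whole sensitivity path
(`a0_sweep()`), including the credible-interval-width and
posterior-variance reductions relative to $a_0 = 0$, computed on the
risk-ratio scale.

## Sampling

`sample_posterior()` runs an adaptive Gaussian random-walk Metropolis
sampler (compiled, but driven by R's RNG so runs are reproducible from one
integer seed) on $(\beta_0, \ldots, \beta_3, \log(r - 1))$:

* chains start at the maximum-likelihood estimate plus Normal jitter
  (SD 0.1 by default).  Starting from draws of the vague prior would put
  chains thousands of units from the mass and make burn-in impractical;
* during burn-in (default 5,000 iterations) the proposal covariance is
  adapted to the empirical covariance of the chain (scaled $2.38^2/d$)
  and a global scale is tuned toward a 0.3 acceptance rate; both are
  frozen afterwards so the retained chain (default 20,000 iterations
  $\times$ 4 chains) is Markov;
* diagnostics are split R-hat and effective sample size, with a pass flag
  at R-hat < 1.01 and ESS > 400 per sampled parameter.

Parameters can be pinned (`fixed =`), which both supports reduced models
and makes the sampler checkable against dense grid quadrature in three
dimensions -- the primary correctness surface of the test suite.

Point summaries are posterior means of *exponentiated* draws with
equal-tailed percentile intervals, matching the default monitored-quantity
summaries of the software used in the motivating analysis; medians and
highest-density intervals would be a one-line change but are deliberately
not the default.  Ties at a directional threshold count as "less than or
equal".

## The synthetic-trial generator

No subject-level data accompany the motivating analysis, so the generator
*is* the study-conditions oracle.  Defaults encode:

* arm sizes 29/35 (historical) and 58/55 (current); maximum scores 27 and
  36 (9 vs 12 weeks of thrice-weekly collection);
* a zero-heavy moderator: zero days with probability 0.7, otherwise a
  negative binomial with mean 11 and size 2 truncated to 1..30.  The size
  was moment-matched once against the published baseline summaries (arm
  means $\approx 3.3$ days, SDs $\approx 6$--$7$); a truncated count
  mixture cannot push the SD much above 6 while holding the mean at 3.3,
  which is the main respect in which the emulation is approximate;
* outcome coefficients equal to the fitted fully-pooled model
  (risk ratios 3.376, 2.376, 1.050, 0.899) and NB size 38.695.

Two design points deserve emphasis.  First, the moderator and outcome are
drawn from independent substreams of one seed, so changing outcome
parameters never perturbs the covariates.  Second, `cap_mode` defaults to
*uncapped*: the inferential model has no upper-truncation term, so capping
scores at the maximum would inject a bias that is a realism feature, not
an estimator defect.  Parameter-recovery and coverage tests therefore use
uncapped draws; capped mode exists for realism studies and its bias is
documented rather than asserted away.  The generator does not simulate
visit-level urine panels, informative missingness, or marijuana use
*during* treatment -- passing tests say nothing about those features of
real trials.

A caution about the calibrated regime: with means of 3--15 and size 38.7
the counts are only mildly over-dispersed, so the data contain little
information about $r$; its posterior is heavy-tailed (the $r^{-2}$ prior
tail decays only just fast enough) and its posterior *mean* is a fragile
summary there, even though the coefficient inferences are unaffected.
Fixtures for dispersion-sensitive checks use strongly over-dispersed
configurations ($r \approx 2$) where $r$ is well identified.

## Frequentist comparator

`fit_mle()` maximizes the same log-likelihood over $(\beta, \log r)$ by
BFGS with observed-information Wald intervals, and `lrt_interaction()`
refers $2(\ell_{\mathrm{full}} - \ell_{\mathrm{reduced}})$ to
$\chi^2_1$.  The fit is written against the package's own likelihood
rather than an alternating mean/dispersion routine because, in the
mildly over-dispersed regime above, dispersion-moment iterations
routinely diverge while the joint quasi-Newton maximization is stable;
on well-dispersed data the fit is verified against `MASS::glm.nb` to
four decimals.  The frequentist dispersion is unconstrained -- it does
not inherit the $r > 1$ prior support.

## Numerical choices

* The NB log-pmf uses the exact rising-factorial form
  $\sum_{j<y} \log(r+j)$ for integer counts plus `log1p(mu/r)`, so it is
  stable from $r$ near 1 through the Poisson limit ($r = 10^{14}$ is
  routine); the naive `lgamma` difference loses all precision long before
  that.
* Equal-tailed intervals use type-7 quantiles of the exponentiated draws;
  exponentiation and percentiles commute up to interpolation.
* The sweep requires its grid to contain 0 (the reduction reference), and
  each grid value refits from scratch with seed = base + grid index, so
  results are order-independent.
* Complete-case handling: rows with missing cells or invariant violations
  are dropped at read time with a warning naming them, never silently.

## Problem sizes used in the checks

The packaged checks run at deliberately desk-scale sizes chosen to keep
Monte-Carlo error well inside the asserted tolerances: grid quadrature at
$100^3$ nodes against $10^6$ retained draws on a frozen 24-record
fixture; 200 replicate pairs at the study arm sizes for interval
coverage; one $2{,}000$-per-arm pair for the
information-doubling asymptote ($50\%$ variance reduction,
$1 - 1/\sqrt{2} \approx 29.3\%$ width reduction); 500 null replicates at
200 per arm for the type-I error of the likelihood-ratio test.

## Known limitations

* The sampler is a random-walk method; for much larger models a gradient
  sampler would be preferable.  Here the posterior is 5-dimensional and
  the compiled kernel makes long chains cheap.
* A single dispersion is shared by both trials, as in the motivating
  analysis; per-study dispersion is out of scope.
* The "interval containment" pattern -- the $a_0 = 0$ interval entirely
  containing the $a_0 = 1$ interval -- is a feature of one observed pair
  of datasets, not a high-probability event under exchangeable
  replication: borrowing shifts the center by an amount comparable to the
  margin by which it narrows the interval, so containment in any single
  replicate is close to a coin flip weighted by how similar the two
  realized interaction estimates happen to be.  The sweep reports both
  the widths and the locations so users can see which situation they are
  in.
* Zero-inflated or truncated outcome likelihoods, hierarchical (random
  $a_0$) power priors, and empirical estimation of $a_0$ are deliberately
  out of scope.
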