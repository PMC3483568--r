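# powerpriornb

Bayesian subgroup analysis for over-dispersed count outcomes in two-arm
randomized trials, with a completed historical trial folded into the
analysis through a **power prior**.  The package was built around a
concrete question — does baseline marijuana use moderate the effect of
levodopa/carbidopa on cocaine-treatment response? — but the machinery is
generic: a count outcome (here the Treatment Effectiveness Score, one
point per cocaine-negative urine sample), a treatment indicator, a
baseline moderator, and their interaction.

## Model

For subject *i*:

```
y_i ~ NB(mu_i, r),   log mu_i = b0 + b1*med_i + b2*mj_i + b3*med_i*mj_i
```

with NB2 variance `mu + mu^2/r`.  Exponentiated coefficients are risk
ratios; `exp(b3)` — the ratio of the moderator slope under active
treatment to the slope under placebo — is the estimand.  Historical data
`D0` enter via the power prior

```
p(theta | D1, D0, a0)  ∝  L(theta; D1) * L(theta; D0)^a0 * p(theta),   0 <= a0 <= 1,
```

with vague initial priors: Normal(0, 1e6) on each coefficient and
Uniform(0, 1) on `1/r`.  `a0` is never estimated; the package fixes it on
a grid and reports the whole sensitivity path, including the
credible-interval-width and posterior-variance reductions bought by
borrowing.

The package provides:

* `simulate_pair()` — seeded synthetic historical/current trial pairs with
  the study's structure (zero-heavy moderator, over-dispersed counts,
  optional exchangeability-violating drift);
* `sample_posterior()` — compiled adaptive random-walk Metropolis sampler
  for the power-prior posterior, with split R-hat/ESS `diagnostics()`;
* `summarize_draws()`, `prob_direction()`, `simple_effects()` — risk-ratio
  summaries, directional probabilities, per-arm slopes;
* `a0_sweep()` / `sweep_report()` — the discount-weight sensitivity
  analysis with tables and figures;
* `fit_mle()`, `lrt_interaction()`, `three_panel_comparison()` — the
  frequentist comparator;
* `run_simulate()` / `run_fit()` / `run_sweep()` — YAML-config pipelines
  (also exposed by the thin CLI at `inst/cli/powerpriornb.R`), with
  provenance sidecars.

## Worked example

Simulate a study-sized pair (historical 29/35, current 58/55, outcome
coefficients at the calibrated risk ratios 3.376 / 2.376 / 1.050 / 0.899)
and fit with full borrowing:

```r
library(powerpriornb)
pair <- simulate_pair(generator_config(), seed = 42)
fit1 <- sample_posterior(pair$current, pair$historical,
                         power_prior_spec(1), chain_config(seed = 43))
summarize_draws(fit1)
#> # A tibble: 5 × 7
#>   name        rr_point rr_lower rr_upper raw_mean     raw_sd posterior_variance_rr
#> 1 intercept      3.53     3.08     4.01    1.26      0.0666                5.51e-2
#> 2 medication     2.30     1.95     2.70    0.828     0.0828                3.64e-2
#> 3 marijuana      1.05     1.04     1.07    0.0524    0.00607               4.08e-5
#> 4 interaction    0.892    0.870    0.914  -0.114     0.0125                1.25e-4
#> 5 dispersion   126.      13.2    517.    126.     1549.                    2.40e+6
```

The interaction risk ratio 0.892 (95% CrI 0.870–0.914) recovers the
generating value 0.899: each additional day of baseline use lowers the
expected score about 11% more under active treatment than under placebo.
`prob_direction(fit1, c(0, 0, 0, 1))` gives the posterior probability that
the interaction RR is at or below 1 (here 1, since this synthetic pair is
larger-signal than a marginal case), and `simple_effects(fit1)` splits the
slope by arm.  The frequentist panel for the same pair:

```r
three_panel_comparison(pair$historical, pair$current)
#> # A tibble: 3 × 6
#>   sample        rr ci_lower ci_upper lrt_statistic  p_value
#> 1 historical 0.867    0.839    0.896          47.4 5.92e-12
#> 2 current    0.925    0.892    0.958          18.2 1.99e- 5
#> 3 combined   0.893    0.872    0.915          74.4 6.52e-18
```

Note the dispersion row above: at these study conditions the counts are
only mildly over-dispersed, so `r` is weakly identified and its posterior
is heavy-tailed — the coefficient inferences are unaffected.  See the
methods vignette (`vignettes/power-prior-borrowing.Rmd`) for the model,
the sampler, the generator's design and its limits.

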