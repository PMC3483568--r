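# Sampler and diagnostics: reproducibility, support, grid-oracle agreement
# on the reduced-parameter fixture, and R-hat/ESS behavior.

short_cc <- function(seed, n = 2000, burn = 1000, chains = 2) {
  chain_config(n_chains = chains, n_iterations = n, burn_in = burn,
               seed = seed)
}

test_that("chain_config validates its fields", {
  expect_error(chain_config(n_chains = 1), class = "pp_validation_error")
  expect_error(chain_config(target_accept = 0.05), class = "pp_validation_error")
  expect_error(chain_config(burn_in = 0), class = "pp_validation_error")
  expect_error(chain_config(seed = 1.5), class = "pp_validation_error")
})

test_that("a fixed seed reproduces the draw matrix exactly", {
  ds <- fixture24()
  f1 <- sample_posterior(ds, spec = power_prior_spec(0),
                         chain_config = short_cc(71))
  f2 <- sample_posterior(ds, spec = power_prior_spec(0),
                         chain_config = short_cc(71))
  expect_identical(f1$draws, f2$draws)
  f3 <- sample_posterior(ds, spec = power_prior_spec(0),
                         chain_config = short_cc(72))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a0 = 0 with historical data equals the current-only run", {
  pair <- simulate_pair(generator_config(dispersion_r = 2), seed = 9)
  f_a0 <- sample_posterior(pair$current, pair$historical,
                           spec = power_prior_spec(0),
                           chain_config = short_cc(73))
  f_none <- sample_posterior(pair$current, historical = NULL,
                             spec = power_prior_spec(0),
                             chain_config = short_cc(73))
  expect_identical(f_a0$draws, f_none$draws)
})

test_that("retained dispersion draws respect the prior support r > 1", {
  ds <- fixture24()
  fit <- sample_posterior(ds, spec = power_prior_spec(0),
                          chain_config = short_cc(74))
  expect_true(all(fit$draws[, "dispersion"] > 1))
  expect_true(all(fit$accept_rate > 0.1 & fit$accept_rate < 0.6))
})

test_that("degenerate outcomes are refused", {
  flat <- make_dataset(tes = rep(5, 10), med = rep(c(0, 1), 5))
  expect_error(sample_posterior(flat, spec = power_prior_spec(0),
                                chain_config = short_cc(75)),
               class = "pp_degenerate_error")
})

test_that("fixed parameters stay fixed and are excluded from sampling", {
  ds <- fixture24()
  fit <- sample_posterior(ds, spec = power_prior_spec(0),
                          chain_config = short_cc(76),
                          fixed = c(marijuana = 0, interaction = 0))
  expect_true(all(fit$draws[, "marijuana"] == 0))
  expect_true(all(fit$draws[, "interaction"] == 0))
  expect_gt(var(fit$draws[, "intercept"]), 0)
})

test_that("posterior means match a dense grid oracle on the reduced fixture", {
  ds <- fixture24()
  oracle <- grid_oracle_3param(ds, n_grid = 60)
  fit <- sample_posterior(ds, spec = power_prior_spec(0),
                          chain_config = chain_config(n_chains = 4,
                                                      n_iterations = 20000,
                                                      burn_in = 4000,
                                                      seed = 77),
                          fixed = c(marijuana = 0, interaction = 0))
  est <- colMeans(fit$draws)
  expect_lt(abs(est["intercept"] - oracle["intercept"]), 0.03)
  expect_lt(abs(est["medication"] - oracle["medication"]), 0.03)
  expect_lt(abs(est["dispersion"] - oracle["dispersion"]), 0.3)
})

test_that("diagnostics separate converged from divergent chains", {
  set.seed(91)
  iid <- fake_draws(matrix(rnorm(4 * 2000 * 5),
                           ncol = 5,
                           dimnames = list(NULL, pp_names <- c(
                             "intercept", "medication", "marijuana",
                             "interaction", "dispersion"))),
                    n_chains = 4)
  d <- diagnostics(iid)
  expect_true(all(abs(d$summary$rhat - 1) < 0.005))
  expect_true(d$pass)

  shifted <- iid
  shifted$draws[shifted$chain == 1, ] <- shifted$draws[shifted$chain == 1, ] + 5
  d2 <- diagnostics(shifted)
  expect_true(all(d2$summary$rhat > 1.5))
  expect_false(d2$pass)

  one <- fake_draws(iid$draws[iid$chain == 1, ], n_chains = 1)
  expect_error(diagnostics(one), class = "pp_validation_error")
})

test_that("default chains pass diagnostics on a packaged fixture", {
  pair <- simulate_pair(generator_config(dispersion_r = 2), seed = 10)
  fit <- sample_posterior(pair$current, pair$historical,
                          spec = power_prior_spec(1),
                          chain_config = chain_config(seed = 78))
  d <- diagnostics(fit)
  expect_true(d$pass)
})

test_that("quadrupling the iterations roughly halves the MCSE", {
  ds <- fixture24()
  mcse_of <- function(n_iter, seed) {
    fit <- sample_posterior(ds, spec = power_prior_spec(0),
                            chain_config = chain_config(n_chains = 4,
                                                        n_iterations = n_iter,
                                                        burn_in = 2000,
                                                        seed = seed))
    d <- diagnostics(fit)$summary
    i <- d$parameter == "medication"
    sd(fit$draws[, "medication"]) / sqrt(d$ess[i])
  }
  ratio <- mcse_of(4000, 79) / mcse_of(16000, 79)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.6)
})

test_that("draws export to a labeled delimited file", {
  ds <- fixture24()
  fit <- sample_posterior(ds, spec = power_prior_spec(0),
                          chain_config = short_cc(80, n = 500, burn = 500))
  path <- tempfile(fileext = ".csv")
  export_draws(fit, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(nrow(back), nrow(fit$draws))
  expect_true(all(c("chain", "iteration", "dispersion") %in% names(back)))
  expect_equal(back$intercept, unname(fit$draws[, "intercept"]))
})
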