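# Probability core: NB pmf contract, likelihood, priors, and the
# power-prior log-posterior identities.

test_that("nb_log_pmf matches closed forms and normalizes", {
  # geometric special case: p(0) = r / (r + mu) = 1/2 at mu = r = 1
  expect_equal(nb_log_pmf(0, 1, 1), log(0.5), tolerance = 1e-12)
  expect_lt(abs(sum(exp(nb_log_pmf(0:1000, 3, 5))) - 1), 1e-10)
  expect_equal(nb_log_pmf(0:50, 7.3, 2.4),
               dnbinom(0:50, mu = 7.3, size = 2.4, log = TRUE),
               tolerance = 1e-12)
  expect_error(nb_log_pmf(-1, 1, 1), class = "pp_validation_error")
  expect_error(nb_log_pmf(2.5, 1, 1), class = "pp_validation_error")
  expect_error(nb_log_pmf(1, -1, 1), class = "pp_validation_error")
  expect_error(nb_log_pmf(1, 1, 0), class = "pp_validation_error")
})

test_that("nb_log_pmf approaches the Poisson limit as r grows", {
  y <- 0:15
  gap8 <- max(abs(nb_log_pmf(y, 4, 1e8) - dpois(y, 4, log = TRUE)))
  expect_lt(gap8, 1e-6)
  # the residual gap decays like 1/r
  gap6 <- max(abs(nb_log_pmf(y, 4, 1e6) - dpois(y, 4, log = TRUE)))
  expect_equal(gap6 / gap8, 100, tolerance = 0.01)
  # stable deep into the limit (naive lgamma differencing blows up here)
  expect_equal(nb_log_pmf(0:15, 4, 1e14), dpois(0:15, 4, log = TRUE),
               tolerance = 1e-10)
})

test_that("log_likelihood sums per-record NB terms over the design", {
  single <- make_dataset(tes = 0, med = 0, mj = 0)
  p0 <- model_params(c(0, 0, 0, 0), 1)
  expect_equal(log_likelihood(single, p0), nb_log_pmf(0, 1, 1),
               tolerance = 1e-12)

  set.seed(12)
  ds <- make_dataset(tes = rpois(20, 6), med = rep(c(0, 1), 10),
                     mj = sample(0:30, 20, replace = TRUE))
  params <- model_params(c(1.1, 0.4, 0.03, -0.05), 7)
  expect_equal(log_likelihood(ds, params), oracle_loglik(ds, params),
               tolerance = 1e-12)
  expect_equal(log_likelihood(ds, params, offset = TRUE),
               oracle_loglik(ds, params, offset = TRUE), tolerance = 1e-12)
  # additivity: a duplicated dataset doubles the log-likelihood
  ds2 <- bind_trials(ds, ds)
  expect_equal(log_likelihood(ds2, params), 2 * log_likelihood(ds, params),
               tolerance = 1e-10)
  expect_error(log_likelihood(ds[0, ], params),
               class = "pp_validation_error")
})

test_that("the compiled likelihood agrees with the R contract", {
  set.seed(13)
  ds <- make_dataset(tes = rnbinom(30, mu = 8, size = 2),
                     med = rep(c(0, 1), 15),
                     mj = sample(0:30, 30, replace = TRUE))
  for (i in 1:10) {
    params <- random_params()
    d <- powerpriornb:::as_design(ds, offset = FALSE)
    expect_equal(
      powerpriornb:::nb_loglik_cpp(d$y, d$med, d$mj, d$off, params$beta,
                                   params$dispersion_r),
      log_likelihood(ds, params), tolerance = 1e-10
    )
  }
})

test_that("log_prior has the stated closed form and support", {
  # at the prior mode with r = 2: four normal ordinates plus log(1/4)
  expect_equal(log_prior(model_params(rep(0, 4), 2)),
               4 * dnorm(0, 0, 1000, log = TRUE) + log(1 / 4),
               tolerance = 1e-12)
  # r <= 1 lies outside the support induced by Uniform(0,1) on 1/r
  expect_identical(log_prior(model_params(rep(0, 4), 0.5)), -Inf)
  expect_identical(log_prior(model_params(rep(0, 4), 1)), -Inf)
  # independent density oracle at an arbitrary point
  p <- model_params(c(1, 1, 1, 1), 5)
  oracle <- sum(dnorm(c(1, 1, 1, 1), 0, 1000, log = TRUE)) +
    dunif(1 / 5, 0, 1, log = TRUE) - 2 * log(5)
  expect_equal(log_prior(p), oracle, tolerance = 1e-12)
  # non-default interval
  pr <- prior_spec(inv_dispersion_lower = 0.1, inv_dispersion_upper = 0.5)
  expect_equal(log_prior(model_params(rep(0, 4), 5), pr),
               sum(dnorm(rep(0, 4), 0, 1000, log = TRUE)) -
                 log(0.4) - 2 * log(5),
               tolerance = 1e-12)
  expect_identical(log_prior(model_params(rep(0, 4), 1.5), pr), -Inf)
})

test_that("power-prior endpoints and linearity in a0 hold exactly", {
  set.seed(14)
  cur <- make_dataset(tes = rnbinom(15, mu = 6, size = 3),
                      med = rep(c(0, 1), length.out = 15),
                      mj = sample(0:20, 15, replace = TRUE))
  hist <- make_dataset(tes = rnbinom(10, mu = 5, size = 3),
                       med = rep(c(0, 1), 5),
                       mj = sample(0:20, 10, replace = TRUE),
                       study = "historical")
  for (i in 1:25) {
    params <- random_params()
    lp0 <- log_power_posterior(cur, hist, power_prior_spec(0), params)
    lp1 <- log_power_posterior(cur, hist, power_prior_spec(1), params)
    # a0 = 0: historical data fully discounted
    expect_equal(lp0, log_likelihood(cur, params) + log_prior(params),
                 tolerance = 1e-12)
    # a0 = 1: pooled-data identity
    expect_equal(lp1,
                 log_likelihood(bind_trials(cur, hist), params) +
                   log_prior(params),
                 tolerance = 1e-10)
    # affine in a0: midpoint is the mean of the endpoints
    lp_half <- log_power_posterior(cur, hist, power_prior_spec(0.5), params)
    expect_equal(lp_half, (lp0 + lp1) / 2, tolerance = 1e-10)
    a <- runif(1)
    expect_equal(log_power_posterior(cur, hist, power_prior_spec(a), params),
                 lp0 + a * (lp1 - lp0), tolerance = 1e-10)
  }
  # historical = current at a0 = 1 doubles the data term
  fixed_p <- model_params(c(1, 0.2, 0.01, -0.02), 4)
  expect_equal(
    log_power_posterior(cur, cur, power_prior_spec(1), fixed_p),
    2 * log_likelihood(cur, fixed_p) + log_prior(fixed_p),
    tolerance = 1e-10
  )
})

test_that("spec constructors validate their domains", {
  expect_error(power_prior_spec(1.2), class = "pp_validation_error")
  expect_error(power_prior_spec(-0.1), class = "pp_validation_error")
  expect_error(prior_spec(coef_variance = 0), class = "pp_validation_error")
  expect_error(prior_spec(inv_dispersion_lower = 0.5,
                          inv_dispersion_upper = 0.2),
               class = "pp_validation_error")
  expect_error(model_params(c(1, 2, 3), 2), class = "pp_validation_error")
  expect_error(model_params(rep(0, 4), -1), class = "pp_validation_error")
})
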