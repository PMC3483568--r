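# Fixtures and independent oracles shared across test files.  Everything is
# built in code; no binary data.

make_dataset <- function(tes, med, mj = 0, study = "current", tes_max = 99,
                         label = "fixture") {
  n <- length(tes)
  trial_dataset(
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      study = study,
      arm = ifelse(rep_len(med, n) == 1, "active", "placebo"),
      marijuana_days = rep_len(mj, n),
      tes = tes,
      tes_max = rep_len(tes_max, n),
      stringsAsFactors = FALSE
    ),
    label = label
  )
}

# Frozen 24-record two-arm fixture with strong over-dispersion (generated
# once from NB(mu = 10 / 22, r = 1.8) and hard-coded).  Used for the
# reduced-parameter grid-quadrature comparisons: with the moderator columns
# zero, only (intercept, medication, dispersion) are identified.
fixture24 <- function() {
  y_placebo <- c(13, 13, 17, 8, 8, 10, 6, 18, 13, 12, 16, 4)
  y_active <- c(37, 42, 37, 12, 15, 30, 22, 50, 29, 16, 75, 25)
  make_dataset(c(y_placebo, y_active), med = rep(c(0, 1), each = 12))
}

# Random parameter vectors inside the default prior support (r > 1).
random_params <- function() {
  model_params(rnorm(4, 0, 0.5), 1 + rexp(1, 1 / 10))
}

# Hand-rolled posterior_draws object for summary/diagnostic unit tests.
fake_draws <- function(mat, n_chains = 1) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) {
    colnames(mat) <- c("intercept", "medication", "marijuana",
                       "interaction", "dispersion")[seq_len(ncol(mat))]
  }
  n_keep <- nrow(mat) / n_chains
  structure(
    list(draws = mat, chain = rep(seq_len(n_chains), each = n_keep),
         n_chains = n_chains, n_keep = n_keep,
         accept_rate = rep(0.3, n_chains), spec = power_prior_spec(0),
         config = NULL, fixed = NULL, offset = FALSE),
    class = "posterior_draws"
  )
}

# Full-rank beta-draw matrix: columns beta0..beta3 + dispersion.
fake_beta_draws <- function(b0 = 0, b1 = 0, b2 = 0, b3 = 0, r = 2) {
  n <- max(lengths(list(b0, b1, b2, b3, r)))
  fake_draws(cbind(
    intercept = rep_len(b0, n), medication = rep_len(b1, n),
    marijuana = rep_len(b2, n), interaction = rep_len(b3, n),
    dispersion = rep_len(r, n)
  ))
}

# Independent log-likelihood oracle: per-record dnbinom summation.
oracle_loglik <- function(dataset, params, offset = FALSE) {
  total <- 0
  for (i in seq_len(nrow(dataset))) {
    med <- as.numeric(dataset$arm[i] == "active")
    mj <- dataset$marijuana_days[i]
    eta <- params$beta[1] + params$beta[2] * med + params$beta[3] * mj +
      params$beta[4] * med * mj +
      if (offset) log(dataset$tes_max[i]) else 0
    total <- total + dnbinom(dataset$tes[i], size = params$dispersion_r,
                             mu = exp(eta), log = TRUE)
  }
  total
}

# Grid-quadrature oracle for the reduced 3-parameter model on fixture24:
# posterior means of (b0, b1, r) under the default priors, computed from
# dnbinom/dnorm on a dense grid (independent of the package's likelihood
# and sampler code paths).
grid_oracle_3param <- function(dataset, n_grid = 100,
                               b0_range = c(1.3, 3.6),
                               b1_range = c(-0.5, 2.6),
                               r_range = c(1.001, 40)) {
  y_p <- dataset$tes[dataset$arm == "placebo"]
  y_a <- dataset$tes[dataset$arm == "active"]
  b0g <- seq(b0_range[1], b0_range[2], length.out = n_grid)
  b1g <- seq(b1_range[1], b1_range[2], length.out = n_grid)
  rg <- seq(r_range[1], r_range[2], length.out = n_grid)
  lp <- array(NA_real_, c(n_grid, n_grid, n_grid))
  for (i in seq_along(b0g)) {
    mu_p <- exp(b0g[i])
    ll_p <- sapply(rg, function(r) sum(dnbinom(y_p, size = r, mu = mu_p,
                                               log = TRUE)))
    for (j in seq_along(b1g)) {
      mu_a <- exp(b0g[i] + b1g[j])
      ll_a <- sapply(rg, function(r) sum(dnbinom(y_a, size = r, mu = mu_a,
                                                 log = TRUE)))
      lp[i, j, ] <- ll_p + ll_a +
        dnorm(b0g[i], 0, 1000, log = TRUE) +
        dnorm(b1g[j], 0, 1000, log = TRUE) - 2 * log(rg)
    }
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  c(intercept = sum(apply(w, 1, sum) * b0g),
    medication = sum(apply(w, 2, sum) * b1g),
    dispersion = sum(apply(w, 3, sum) * rg))
}
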