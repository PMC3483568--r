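# The probability core: NB2 log-pmf, the regression log-likelihood, the
# initial priors, and the power-prior log-posterior
#   log p(theta | D1, D0, a0) = logL(D1) + a0 * logL(D0) + log p(theta) + C.

#' Model parameters for the NB interaction regression
#'
#' @param beta Length-4 vector of log-mean-scale coefficients
#'   (intercept, medication, marijuana, medication x marijuana).
#' @param dispersion_r NB size parameter r > 0; variance = mu + mu^2 / r.
#' @export
model_params <- function(beta, dispersion_r) {
  if (length(beta) != 4 || any(!is.finite(beta))) {
    pp_stop("beta must be a finite 4-vector")
  }
  if (!is.finite(dispersion_r) || dispersion_r <= 0) {
    pp_stop("dispersion_r must be > 0")
  }
  structure(list(beta = as.numeric(beta), dispersion_r = dispersion_r),
            class = "model_params")
}

#' Initial prior specification
#'
#' Vague priors centered on the null: independent Normal(`coef_mean`,
#' `coef_variance`) on each regression coefficient (default variance 1e6)
#' and a Uniform(`inv_dispersion_lower`, `inv_dispersion_upper`) prior on
#' the *inverse* of the NB size.  Under the default Uniform(0, 1) the
#' induced density on r is proportional to r^-2 on (1, Inf).
#'
#' @param coef_mean,coef_variance Normal prior moments for the coefficients.
#' @param inv_dispersion_lower,inv_dispersion_upper Support of the uniform
#'   prior on 1/r.
#' @export
prior_spec <- function(coef_mean = 0, coef_variance = 1e6,
                       inv_dispersion_lower = 0, inv_dispersion_upper = 1) {
  if (!is.finite(coef_variance) || coef_variance <= 0) {
    pp_stop("coef_variance must be > 0")
  }
  if (inv_dispersion_lower < 0 ||
      inv_dispersion_upper <= inv_dispersion_lower) {
    pp_stop("inverse-dispersion interval must satisfy 0 <= lower < upper")
  }
  structure(list(coef_mean = coef_mean, coef_variance = coef_variance,
                 inv_dispersion_lower = inv_dispersion_lower,
                 inv_dispersion_upper = inv_dispersion_upper),
            class = "prior_spec")
}

#' Power prior specification
#'
#' @param a0 Discount weight on the historical likelihood, in \[0, 1\]:
#'   0 excludes the historical data, 1 weights it equally with the current
#'   data.
#' @param priors A [prior_spec()] for the initial prior p(theta).
#' @export
power_prior_spec <- function(a0, priors = prior_spec()) {
  if (!is.finite(a0) || a0 < 0 || a0 > 1) {
    pp_stop("a0 must lie in [0, 1]")
  }
  stopifnot(inherits(priors, "prior_spec"))
  structure(list(a0 = a0, priors = priors), class = "power_prior_spec")
}

#' Negative binomial log-pmf (mean/size parameterization)
#'
#' `nb_log_pmf(y, mu, r)` is the log of NB(y; mean mu, size r), with
#' variance mu + mu^2/r, written in log-gamma form so it stays finite for
#' large counts.  As r -> Inf it approaches the Poisson(mu) log-pmf.
#'
#' @param y Nonnegative integer count(s).
#' @param mu Positive mean(s).
#' @param r Positive size parameter(s).
#' @return Log-probability, vectorized over the arguments.
#' @export
nb_log_pmf <- function(y, mu, r) {
  if (any(!is_count(y))) pp_stop("y must be a nonnegative integer")
  if (any(!is.finite(mu) | mu <= 0)) pp_stop("mu must be > 0")
  if (any(!is.finite(r) | r <= 0)) pp_stop("r must be > 0")
  n <- max(length(y), length(mu), length(r))
  y <- rep_len(y, n)
  mu <- rep_len(mu, n)
  r <- rep_len(r, n)
  # Rising-factorial term lgamma(y+r) - lgamma(r), accumulated as
  # sum_j log(r + j) for modest y so it stays exact for huge r (the
  # lgamma difference cancels catastrophically in the Poisson limit).
  lrf <- mapply(function(yi, ri) {
    if (yi <= 128) {
      sum(log(ri + seq_len(yi) - 1))
    } else {
      lgamma(yi + ri) - lgamma(ri)
    }
  }, y, r)
  lrf - lgamma(y + 1) - r * log1p(mu / r) + y * (log(mu) - log(r + mu))
}

#' Log-likelihood of a trial dataset under the interaction model
#'
#' Sums `nb_log_pmf(tes_i, mu_i, r)` with
#' `log mu_i = b0 + b1 med_i + b2 mj_i + b3 med_i mj_i (+ log tes_max_i)`,
#' where `med` is the active-arm indicator and `mj` the raw moderator (so
#' exponentiated slopes are risk ratios per additional day of use).
#'
#' @param dataset A [trial_dataset()].
#' @param params A [model_params()].
#' @param offset Include `log(tes_max)` as an exposure offset?  Off by
#'   default: the inferential model carries no exposure term.
#' @export
log_likelihood <- function(dataset, params, offset = FALSE) {
  if (!inherits(dataset, "trial_dataset") || nrow(dataset) == 0) {
    pp_stop("log_likelihood requires a non-empty trial_dataset")
  }
  stopifnot(inherits(params, "model_params"))
  d <- as_design(dataset, offset)
  b <- params$beta
  eta <- b[1] + b[2] * d$med + b[3] * d$mj + b[4] * d$med * d$mj + d$off
  sum(nb_log_pmf(d$y, exp(eta), params$dispersion_r))
}

#' Log initial prior density
#'
#' Normal log-densities on the four coefficients plus the density induced
#' on r by the uniform prior on 1/r, including the change-of-variables
#' Jacobian: under Uniform(l, u) on 1/r the density on r is
#' 1/((u - l) r^2) for 1/r in (l, u) and 0 outside (so -Inf is returned for
#' r <= 1 under the default Uniform(0, 1)).
#'
#' @param params A [model_params()].
#' @param priors A [prior_spec()].
#' @export
log_prior <- function(params, priors = prior_spec()) {
  stopifnot(inherits(params, "model_params"), inherits(priors, "prior_spec"))
  inv <- 1 / params$dispersion_r
  if (inv <= priors$inv_dispersion_lower || inv >= priors$inv_dispersion_upper) {
    return(-Inf)
  }
  sum(dnorm(params$beta, priors$coef_mean, sqrt(priors$coef_variance),
            log = TRUE)) -
    log(priors$inv_dispersion_upper - priors$inv_dispersion_lower) -
    2 * log(params$dispersion_r)
}

#' Power-prior log-posterior (up to a constant)
#'
#' `logL(current) + a0 * logL(historical) + log prior`.  At `a0 = 0` the
#' historical data are fully discounted; at `a0 = 1` they carry the same
#' weight as the current data and the value equals the pooled-data
#' log-posterior.  The function is affine in `a0` at fixed parameters.
#'
#' @param current,historical [trial_dataset()]s; `historical` may be `NULL`
#'   (equivalent to `a0 = 0`).
#' @param spec A [power_prior_spec()].
#' @param params A [model_params()].
#' @param offset Passed to [log_likelihood()].
#' @export
log_power_posterior <- function(current, historical, spec, params,
                                offset = FALSE) {
  stopifnot(inherits(spec, "power_prior_spec"))
  lp <- log_likelihood(current, params, offset)
  if (!is.null(historical) && spec$a0 > 0) {
    lp <- lp + spec$a0 * log_likelihood(historical, params, offset)
  }
  lp + log_prior(params, spec$priors)
}
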