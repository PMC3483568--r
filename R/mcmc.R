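# MCMC front end: chain configuration, the sample_posterior() wrapper
# around the compiled adaptive RW-Metropolis kernel, and convergence
# diagnostics (split R-hat, effective sample size).

#' MCMC chain configuration
#'
#' @param n_chains Number of chains (>= 2 so R-hat is defined).
#' @param n_iterations Post-burn-in iterations per chain.
#' @param burn_in Burn-in iterations per chain; proposal adaptation happens
#'   only here and is frozen afterwards.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chain seeds are derived from it.
#' @param adapt_window Iterations between proposal-scale updates.
#' @param target_accept Target acceptance rate for scale adaptation; must
#'   lie in (0.1, 0.6), the efficient band for random-walk proposals.
#' @param init_jitter_sd SD of the Normal jitter applied to the MLE-based
#'   starting point of each chain.
#' @export
chain_config <- function(n_chains = 4L, n_iterations = 20000L,
                         burn_in = 5000L, thin = 1L, seed = 1L,
                         adapt_window = 50L, target_accept = 0.3,
                         init_jitter_sd = 0.1) {
  if (!is_count(n_chains, 2)) pp_stop("n_chains must be an integer >= 2")
  if (!is_count(n_iterations, 1) || !is_count(burn_in, 1) ||
      !is_count(thin, 1) || !is_count(adapt_window, 1)) {
    pp_stop("n_iterations, burn_in, thin and adapt_window must be positive integers")
  }
  if (!is_count(seed)) pp_stop("seed must be an integer")
  if (target_accept <= 0.1 || target_accept >= 0.6) {
    pp_stop("target_accept must lie in (0.1, 0.6)")
  }
  if (!is.finite(init_jitter_sd) || init_jitter_sd <= 0) {
    pp_stop("init_jitter_sd must be > 0")
  }
  structure(
    list(n_chains = as.integer(n_chains),
         n_iterations = as.integer(n_iterations),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         seed = as.integer(seed), adapt_window = as.integer(adapt_window),
         target_accept = target_accept, init_jitter_sd = init_jitter_sd),
    class = "chain_config"
  )
}

empty_design <- function() {
  list(y = numeric(0), med = numeric(0), mj = numeric(0), off = numeric(0))
}

# Fallback start when the MLE fit fails (e.g. tiny or awkward fixtures).
crude_init <- function(current) {
  list(beta = c(log(mean(current$tes) + 0.5), 0, 0, 0), dispersion_r = 5)
}

#' Sample the power-prior posterior
#'
#' Runs `n_chains` adaptive random-walk Metropolis chains on
#' `(beta, log(r - r_lo))`, where `r_lo` is the lower support bound induced
#' by the uniform prior on `1/r` (1 under the default prior).  Each chain
#' starts at the current-data MLE plus Normal jitter; the proposal
#' covariance adapts to the empirical posterior covariance during burn-in
#' only.  Results are deterministic given `chain_config$seed`.
#'
#' @param current Current [trial_dataset()].
#' @param historical Historical [trial_dataset()] or `NULL` (forces
#'   `a0 = 0` semantics).
#' @param spec A [power_prior_spec()].
#' @param chain_config A [chain_config()].
#' @param offset Include the `log(tes_max)` exposure offset?
#' @param fixed Optional named numeric vector freezing parameters at given
#'   values, e.g. `c(marijuana = 0, interaction = 0)`; names from
#'   `c("intercept", "medication", "marijuana", "interaction", "dispersion")`.
#' @return A `posterior_draws` object: retained draws (rows) by parameter
#'   (columns), chain index, acceptance rates, and a config echo.
#' @export
sample_posterior <- function(current, historical = NULL,
                             spec = power_prior_spec(0),
                             chain_config = powerpriornb::chain_config(),
                             offset = FALSE, fixed = NULL) {
  stopifnot(inherits(spec, "power_prior_spec"),
            inherits(chain_config, "chain_config"))
  if (!inherits(current, "trial_dataset") || nrow(current) == 0) {
    pp_stop("current must be a non-empty trial_dataset")
  }
  if (var(current$tes) == 0) {
    pp_stop("outcome column has zero variance: degenerate data",
            class = "pp_degenerate_error")
  }
  if (spec$priors$inv_dispersion_lower != 0) {
    pp_stop("the sampler requires an inverse-dispersion prior with lower bound 0")
  }
  if (is.null(historical)) spec$a0 <- 0
  r_lo <- 1 / spec$priors$inv_dispersion_upper
  pnames <- pp_param_names()

  free <- rep(TRUE, 5)
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% pnames)) {
      pp_stop("fixed must be a named vector using the canonical parameter names")
    }
    free[match(names(fixed), pnames)] <- FALSE
  }

  init <- tryCatch(fit_mle(current, offset = offset),
                   error = function(e) NULL)
  if (is.null(init)) {
    init <- crude_init(current)
  } else {
    init <- list(beta = init$params$beta, dispersion_r = init$params$dispersion_r)
  }
  base <- c(init$beta, log(max(init$dispersion_r, r_lo + 0.5) - r_lo))
  if (!is.null(fixed)) {
    for (nm in names(fixed)) {
      j <- match(nm, pnames)
      base[j] <- if (nm == "dispersion") log(fixed[[nm]] - r_lo) else fixed[[nm]]
    }
  }

  d_c <- as_design(current, offset)
  d_h <- if (!is.null(historical) && spec$a0 > 0) {
    as_design(historical, offset)
  } else {
    empty_design()
  }
  lp_at <- function(th) {
    r <- r_lo + exp(th[5])
    nb_loglik_cpp(d_c$y, d_c$med, d_c$mj, d_c$off, th[1:4], r) +
      (if (length(d_h$y) && spec$a0 > 0) {
        spec$a0 * nb_loglik_cpp(d_h$y, d_h$med, d_h$mj, d_h$off, th[1:4], r)
      } else 0) +
      log_prior(model_params(th[1:4], r), spec$priors) + th[5]
  }

  chain_seeds <- derive_seeds(chain_config$seed, chain_config$n_chains)
  n_keep <- chain_config$n_iterations %/% chain_config$thin
  chains <- vector("list", chain_config$n_chains)
  accept <- numeric(chain_config$n_chains)
  coef_sd <- sqrt(spec$priors$coef_variance)
  log_inv_width <- log(spec$priors$inv_dispersion_upper -
                         spec$priors$inv_dispersion_lower)

  for (k in seq_len(chain_config$n_chains)) {
    res <- eval_with_seed(chain_seeds[k], {
      th0 <- NULL
      for (try in seq_len(100L)) {
        cand <- base
        cand[free] <- cand[free] + rnorm(sum(free), 0, chain_config$init_jitter_sd)
        if (is.finite(lp_at(cand))) {
          th0 <- cand
          break
        }
      }
      if (is.null(th0)) {
        pp_stop("could not find a finite starting point after 100 jitter attempts",
                class = "pp_init_error")
      }
      rw_metropolis_cpp(
        d_c$y, d_c$med, d_c$mj, d_c$off,
        d_h$y, d_h$med, d_h$mj, d_h$off, spec$a0,
        th0, free,
        spec$priors$coef_mean, coef_sd, r_lo, log_inv_width,
        chain_config$burn_in, n_keep, chain_config$thin,
        chain_config$adapt_window, chain_config$target_accept
      )
    })
    chains[[k]] <- res$draws
    accept[k] <- res$accept_rate
  }

  draws <- do.call(rbind, chains)
  colnames(draws) <- pnames
  if (any(accept < 0.1 | accept > 0.6)) {
    warning(sprintf("acceptance rate outside (0.1, 0.6) in chain(s) %s",
                    paste(which(accept < 0.1 | accept > 0.6), collapse = ", ")),
            call. = FALSE)
  }
  structure(
    list(draws = draws,
         chain = rep(seq_len(chain_config$n_chains), each = n_keep),
         n_chains = chain_config$n_chains, n_keep = n_keep,
         accept_rate = accept, spec = spec, config = chain_config,
         fixed = fixed, offset = offset),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "<posterior_draws: %d draws (%d chains x %d), a0 = %g, mean accept %.2f>\n",
    nrow(x$draws), x$n_chains, x$n_keep, x$spec$a0, mean(x$accept_rate)))
  invisible(x)
}

# iterations x chains matrix for one parameter, chains split in half.
split_chain_matrix <- function(x, chain) {
  chains <- split(x, chain)
  n <- min(lengths(chains))
  n <- n - n %% 2L
  halves <- lapply(chains, function(v) {
    v <- v[seq_len(n)]
    list(v[seq_len(n / 2)], v[n / 2 + seq_len(n / 2)])
  })
  do.call(cbind, unlist(halves, recursive = FALSE))
}

rhat_split <- function(m) {
  n <- nrow(m)
  W <- mean(apply(m, 2, var))
  B <- n * var(colMeans(m))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size across split chains (BDA3-style: chain-averaged
# autocovariances with Geyer's initial positive-pair truncation).
ess_split <- function(m) {
  n <- nrow(m)
  nch <- ncol(m)
  W <- mean(apply(m, 2, var))
  B <- n * var(colMeans(m))
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus <= 0) {
    return(NA_real_)
  }
  max_lag <- min(n - 2L, 1000L)
  acov <- sapply(seq_len(nch), function(j) {
    a <- acf(m[, j], lag.max = max_lag, type = "covariance", plot = FALSE,
             demean = TRUE)
    as.numeric(a$acf)
  })
  rho <- 1 - (W - rowMeans(acov)[-1]) / var_plus
  # sum initial positive pairs
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- nch * n / (1 + 2 * s)
  min(ess, nch * n)
}

#' Convergence diagnostics for posterior draws
#'
#' Split R-hat and effective sample size per parameter; the `pass` flag
#' requires R-hat < 1.01 and ESS > 400 for every sampled (non-fixed)
#' parameter.
#'
#' @param draws A `posterior_draws` object from [sample_posterior()].
#' @return A list with a per-parameter `summary` tibble, the `pass` flag,
#'   and the per-chain acceptance rates.
#' @export
diagnostics <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$n_chains < 2) {
    pp_stop("diagnostics require at least 2 chains")
  }
  pnames <- colnames(draws$draws)
  varying <- apply(draws$draws, 2, function(v) var(v) > 0)
  rows <- lapply(pnames[varying], function(p) {
    m <- split_chain_matrix(draws$draws[, p], draws$chain)
    tibble::tibble(parameter = p, rhat = rhat_split(m), ess = ess_split(m))
  })
  summary <- do.call(rbind, rows)
  pass <- all(summary$rhat < 1.01) && all(summary$ess > 400)
  structure(list(summary = summary, pass = pass,
                 accept_rate = draws$accept_rate),
            class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat(sprintf("<mcmc_diagnostics: %s>\n", if (x$pass) "PASS" else "FAIL"))
  print(x$summary)
  invisible(x)
}

#' Export retained draws to a delimited text file
#'
#' One row per retained draw with chain and iteration indices, for
#' external inspection.
#'
#' @param draws A `posterior_draws` object.
#' @param path Destination path.
#' @export
export_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  df <- data.frame(chain = draws$chain,
                   iteration = rep(seq_len(draws$n_keep), draws$n_chains),
                   draws$draws, check.names = FALSE)
  readr::write_csv(tibble::as_tibble(df), path)
  invisible(path)
}
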