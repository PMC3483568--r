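# Posterior functionals: risk-ratio summaries, directional probabilities,
# and per-arm simple effects of the moderator.

# Summary of one coefficient's draws on the risk-ratio scale.  The point
# estimate is the mean of the exponentiated draws; limits are equal-tailed
# percentiles of the exponentiated draws (equivalently, exponentiated
# percentiles -- the map is monotone).
rr_summary_row <- function(name, x, level, exponentiate = TRUE) {
  a <- (1 - level) / 2
  ex <- if (exponentiate) exp(x) else x
  q <- unname(quantile(ex, c(a, 1 - a)))
  tibble::tibble(
    name = name,
    rr_point = mean(ex), rr_lower = q[1], rr_upper = q[2],
    raw_mean = mean(x), raw_sd = sd(x),
    posterior_variance_rr = var(ex)
  )
}

#' Summarize posterior draws on the risk-ratio scale
#'
#' For each regression coefficient: the posterior mean of the exponentiated
#' draws (risk ratio), equal-tailed credible limits, the mean and SD on the
#' coefficient scale, and the posterior variance of the exponentiated
#' coefficient.  The dispersion parameter is summarized on its own scale,
#' without exponentiation.
#'
#' @param draws A `posterior_draws` object.
#' @param credible_level Credible mass for the equal-tailed interval,
#'   in (0.5, 1).
#' @return A tibble with one row per parameter.
#' @export
summarize_draws <- function(draws, credible_level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!is.finite(credible_level) || credible_level <= 0.5 ||
      credible_level >= 1) {
    pp_stop("credible_level must lie in (0.5, 1)")
  }
  if (nrow(draws$draws) == 0) pp_stop("no draws to summarize")
  pnames <- colnames(draws$draws)
  rows <- lapply(pnames, function(p) {
    rr_summary_row(p, draws$draws[, p], credible_level,
                   exponentiate = p != "dispersion")
  })
  do.call(rbind, rows)
}

#' Posterior probability of a directional contrast
#'
#' Fraction of retained draws with `contrast . beta <= threshold`.  Since
#' the risk ratio is the exponentiated coefficient, `RR <= 1` is exactly
#' `contrast . beta <= 0`; ties at the threshold count as "less than or
#' equal".
#'
#' @param draws A `posterior_draws` object.
#' @param contrast Length-4 numeric contrast over the regression
#'   coefficients, e.g. `c(0, 0, 0, 1)` for the interaction.
#' @param threshold Boundary on the coefficient scale (default 0).
#' @return A probability in \[0, 1\].
#' @export
prob_direction <- function(draws, contrast, threshold = 0) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (length(contrast) != 4 || any(!is.finite(contrast))) {
    pp_stop("contrast must be a finite 4-vector")
  }
  if (nrow(draws$draws) == 0) pp_stop("no draws")
  lc <- draws$draws[, 1:4, drop = FALSE] %*% contrast
  mean(lc <= threshold)
}

#' Simple effects of the moderator within each treatment arm
#'
#' The placebo-arm slope is `exp(b2)` and the active-arm slope is
#' `exp(b2 + b3)`, summarized draw-by-draw on the risk-ratio scale.  The
#' per-arm "harm" probability is the posterior probability that the arm's
#' slope is at or below zero on the log scale (RR <= 1): more moderator use
#' predicting fewer negative urines.
#'
#' @param draws A `posterior_draws` object.
#' @param credible_level Credible mass for the intervals.
#' @return A list with a two-row `summary` tibble (placebo, active) and a
#'   named `harm_probability` vector.
#' @export
simple_effects <- function(draws, credible_level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  slope_placebo <- draws$draws[, "marijuana"]
  slope_active <- slope_placebo + draws$draws[, "interaction"]
  summary <- rbind(
    rr_summary_row("placebo_slope", slope_placebo, credible_level),
    rr_summary_row("active_slope", slope_active, credible_level)
  )
  list(
    summary = summary,
    harm_probability = c(
      placebo = prob_direction(draws, c(0, 0, 1, 0)),
      active = prob_direction(draws, c(0, 0, 1, 1))
    )
  )
}
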