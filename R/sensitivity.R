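# Sensitivity of the interaction posterior to the discount weight a0:
# refit across a grid, track the interaction summary, the directional
# probability, and precision-gain metrics relative to a0 = 0.

#' Sweep the discount weight a0
#'
#' Re-fits the power-prior posterior at each grid value (each grid point
#' refits from scratch with its own derived seed, base seed + grid index)
#' and records, for the interaction coefficient: the risk-ratio summary,
#' `P(b3 <= 0)`, the credible-interval width and the posterior variance of
#' the exponentiated coefficient, plus percentage reductions of the last
#' two relative to the `a0 = 0` row,
#' `100 * (1 - metric(a0) / metric(0))`.
#'
#' @param current,historical [trial_dataset()]s sharing the schema.
#' @param grid Unique values in \[0, 1\]; must contain 0 (the reduction
#'   reference).  Default 0 to 1 in steps of 0.1.
#' @param chain_config A [chain_config()].
#' @param priors A [prior_spec()].
#' @param offset Include the exposure offset?
#' @param credible_level Credible mass for the intervals.
#' @return A `pp_sweep` tibble (one row per grid value, sorted ascending);
#'   the interaction draws for each grid value are kept in
#'   `attr(x, "interaction_draws")` for density displays.
#' @export
a0_sweep <- function(current, historical, grid = seq(0, 1, by = 0.1),
                     chain_config = powerpriornb::chain_config(),
                     priors = prior_spec(), offset = FALSE,
                     credible_level = 0.95) {
  if (anyDuplicated(grid)) pp_stop("grid values must be unique")
  if (any(!is.finite(grid) | grid < 0 | grid > 1)) {
    pp_stop("grid values must lie in [0, 1]")
  }
  if (!any(grid == 0)) {
    pp_stop("grid must contain 0 (reductions are relative to a0 = 0)")
  }
  grid <- sort(grid)
  rows <- vector("list", length(grid))
  idraws <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cc <- chain_config
    cc$seed <- chain_config$seed + (i - 1L)
    fit <- tryCatch(
      sample_posterior(current, historical,
                       spec = power_prior_spec(grid[i], priors),
                       chain_config = cc, offset = offset),
      error = function(e) {
        pp_stop(sprintf("fit failed at a0 = %g: %s", grid[i],
                        conditionMessage(e)),
                class = class(e)[1])
      }
    )
    s <- summarize_draws(fit, credible_level)
    int <- s[s$name == "interaction", ]
    rows[[i]] <- tibble::tibble(
      a0 = grid[i],
      rr_point = int$rr_point, rr_lower = int$rr_lower,
      rr_upper = int$rr_upper, raw_mean = int$raw_mean,
      raw_sd = int$raw_sd,
      prob_le_null = prob_direction(fit, c(0, 0, 0, 1)),
      ci_width = int$rr_upper - int$rr_lower,
      posterior_variance_rr = int$posterior_variance_rr
    )
    idraws[[i]] <- fit$draws[, "interaction"]
  }
  out <- do.call(rbind, rows)
  ref <- out[out$a0 == 0, ]
  out$width_reduction_pct <- 100 * (1 - out$ci_width / ref$ci_width)
  out$variance_reduction_pct <-
    100 * (1 - out$posterior_variance_rr / ref$posterior_variance_rr)
  names(idraws) <- format(grid)
  attr(out, "interaction_draws") <- idraws
  attr(out, "credible_level") <- credible_level
  class(out) <- c("pp_sweep", class(out))
  out
}

#' Build the sweep report: table plus four figures
#'
#' Figures: interaction estimate (with credible band) vs a0, `P(b3 <= 0)`
#' vs a0, the two precision-reduction curves vs a0, and overlaid posterior
#' densities of the interaction risk ratio at the grid endpoints and
#' midpoint.
#'
#' @param result A `pp_sweep` from [a0_sweep()].
#' @return A `pp_sweep_report` list with `table` and a named `plots` list
#'   (`estimate`, `probability`, `precision`, `densities`).
#' @export
sweep_report <- function(result) {
  if (!inherits(result, "pp_sweep") || nrow(result) == 0) {
    pp_stop("sweep_report requires a non-empty pp_sweep")
  }
  tbl <- tibble::as_tibble(result)
  p_est <- ggplot2::ggplot(tbl, ggplot2::aes(x = a0, y = rr_point)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = rr_lower, ymax = rr_upper),
                         fill = "grey80") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "a0 (historical discount weight)",
                  y = "Interaction risk ratio",
                  title = "Interaction estimate vs a0")
  p_prob <- ggplot2::ggplot(tbl, ggplot2::aes(x = a0, y = prob_le_null)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "a0", y = "P(interaction RR <= 1)",
                  title = "Directional probability vs a0")
  red <- rbind(
    data.frame(a0 = tbl$a0, metric = "CI width",
               reduction = tbl$width_reduction_pct),
    data.frame(a0 = tbl$a0, metric = "posterior variance",
               reduction = tbl$variance_reduction_pct)
  )
  p_prec <- ggplot2::ggplot(red,
                            ggplot2::aes(x = a0, y = reduction,
                                         colour = metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "a0", y = "Reduction vs a0 = 0 (%)",
                  title = "Precision gain from borrowing")
  idraws <- attr(result, "interaction_draws")
  pick <- unique(c(1L, ceiling(length(idraws) / 2), length(idraws)))
  dens <- do.call(rbind, lapply(pick, function(i) {
    data.frame(a0 = names(idraws)[i], rr = exp(idraws[[i]]))
  }))
  p_dens <- ggplot2::ggplot(dens, ggplot2::aes(x = rr, colour = a0)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Interaction risk ratio", y = "Posterior density",
                  title = "Interaction posterior by a0")
  structure(
    list(table = tbl,
         plots = list(estimate = p_est, probability = p_prob,
                      precision = p_prec, densities = p_dens)),
    class = "pp_sweep_report"
  )
}

#' Write a sweep report to disk
#'
#' @param report A `pp_sweep_report`.
#' @param dir Output directory (created if needed).
#' @param label File-name stem.
#' @return Invisibly, the paths written.
#' @export
write_sweep_report <- function(report, dir, label = "sweep") {
  stopifnot(inherits(report, "pp_sweep_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(label, "_table.csv"))
  readr::write_csv(report$table, paths)
  for (nm in names(report$plots)) {
    p <- file.path(dir, sprintf("%s_%s.png", label, nm))
    ggplot2::ggsave(p, report$plots[[nm]], width = 6, height = 4, dpi = 120)
    paths <- c(paths, p)
  }
  invisible(paths)
}
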