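# Config-driven pipelines tying the stages together.  Anything that
# affects results lives in a YAML config (auditability); every output
# directory gets a provenance sidecar sufficient to re-run the command
# bit-identically.

#' Read and minimally validate a run configuration
#'
#' The config is a YAML file with (a subset of) the fields: `label`,
#' `seed`, `generator` (a list of [generator_config()] arguments) *or*
#' `datasets` (`historical`/`current` paths, optional `mapping`, `delim`),
#' `a0`, `grid`, `prior` ([prior_spec()] arguments), `chains`
#' ([chain_config()] arguments, seed taken from the top-level `seed`), and
#' `offset`.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    pp_stop(paste("config file not found:", path), class = "pp_io_error")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) pp_stop("config must be a YAML mapping")
  cfg
}

as_config_list <- function(config) {
  if (is.character(config) && length(config) == 1) {
    read_run_config(config)
  } else if (is.list(config)) {
    config
  } else {
    pp_stop("config must be a path or a list")
  }
}

require_seed <- function(cfg) {
  if (is.null(cfg$seed) || !is_count(cfg$seed)) {
    pp_stop("config must provide an explicit integer seed (field 'seed')")
  }
  as.integer(cfg$seed)
}

cfg_generator <- function(cfg) {
  do.call(generator_config, cfg$generator %||% list())
}

cfg_chains <- function(cfg, seed) {
  args <- cfg$chains %||% list()
  args$seed <- seed
  do.call(chain_config, args)
}

cfg_priors <- function(cfg) {
  do.call(prior_spec, cfg$prior %||% list())
}

write_provenance <- function(cfg, out_dir, command) {
  side <- list(command = command, package = "powerpriornb",
               version = as.character(packageVersion("powerpriornb")),
               config = cfg)
  yaml::write_yaml(side, file.path(out_dir, "provenance.yaml"))
}

prepare_out_dir <- function(out_dir) {
  ok <- tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.exists(out_dir)
  }, error = function(e) FALSE)
  if (!ok) {
    pp_stop(paste("cannot create output directory", out_dir),
            class = "pp_io_error")
  }
  out_dir
}

# Load the historical/current pair either from files or from the
# generator; exactly one of the two sources must be configured.
load_pair <- function(cfg, seed) {
  has_gen <- !is.null(cfg$generator)
  has_files <- !is.null(cfg$datasets)
  if (has_gen == has_files) {
    pp_stop("config must provide exactly one of 'generator' or 'datasets'")
  }
  if (has_gen) {
    simulate_pair(cfg_generator(cfg), seed)
  } else {
    ds <- cfg$datasets
    if (is.null(ds$historical) || is.null(ds$current)) {
      pp_stop("datasets config needs 'historical' and 'current' paths")
    }
    mapping <- if (!is.null(ds$mapping)) unlist(ds$mapping) else NULL
    list(
      historical = read_dataset(ds$historical, mapping = mapping,
                                delim = ds$delim %||% NULL),
      current = read_dataset(ds$current, mapping = mapping,
                             delim = ds$delim %||% NULL)
    )
  }
}

#' Simulate a historical/current pair and write dataset files
#'
#' Writes `historical.csv`, `current.csv` and a `provenance.yaml` sidecar
#' (full config, seed, package version) to `out_dir`.
#'
#' @param config Path to a YAML config or an equivalent list; must contain
#'   an explicit `seed` and a `generator` block (possibly empty for the
#'   default study conditions).
#' @param out_dir Output directory.
#' @return Invisibly, the simulated pair.
#' @export
run_simulate <- function(config, out_dir) {
  cfg <- as_config_list(config)
  seed <- require_seed(cfg)
  gcfg <- cfg_generator(cfg)
  prepare_out_dir(out_dir)
  pair <- simulate_pair(gcfg, seed)
  write_dataset(pair$historical, file.path(out_dir, "historical.csv"))
  write_dataset(pair$current, file.path(out_dir, "current.csv"))
  write_provenance(cfg, out_dir, "simulate")
  message(sprintf("run_simulate: wrote %d historical and %d current records to %s",
                  nrow(pair$historical), nrow(pair$current), out_dir))
  invisible(pair)
}

#' Fit the power-prior posterior at a configured a0 and write reports
#'
#' Produces a Bayesian panel (risk-ratio summaries per coefficient), the
#' simple-effects block, a diagnostics block, and the retained draws, all
#' as delimited text, plus a provenance sidecar.  Fails (classed
#' convergence error) if diagnostics do not pass, unless
#' `allow_nonconverged`.
#'
#' @inheritParams run_simulate
#' @param allow_nonconverged Keep going when R-hat/ESS thresholds fail?
#' @return Invisibly: list with the fit, summary, simple effects and
#'   diagnostics.
#' @export
run_fit <- function(config, out_dir, allow_nonconverged = FALSE) {
  cfg <- as_config_list(config)
  seed <- require_seed(cfg)
  prepare_out_dir(out_dir)
  pair <- load_pair(cfg, seed)
  spec <- power_prior_spec(cfg$a0 %||% 0, cfg_priors(cfg))
  cc <- cfg_chains(cfg, seed)
  fit <- sample_posterior(pair$current, pair$historical, spec = spec,
                          chain_config = cc,
                          offset = isTRUE(cfg$offset))
  summary <- summarize_draws(fit)
  effects <- simple_effects(fit)
  diag <- diagnostics(fit)
  readr::write_csv(summary, file.path(out_dir, "summary.csv"))
  readr::write_csv(effects$summary, file.path(out_dir, "simple_effects.csv"))
  export_draws(fit, file.path(out_dir, "draws.csv"))
  yaml::write_yaml(
    list(pass = diag$pass, accept_rate = as.numeric(diag$accept_rate),
         harm_probability = as.list(effects$harm_probability),
         parameters = lapply(seq_len(nrow(diag$summary)), function(i) {
           as.list(diag$summary[i, ])
         })),
    file.path(out_dir, "diagnostics.yaml")
  )
  write_provenance(cfg, out_dir, "fit")
  message(sprintf("run_fit: a0 = %g, diagnostics %s", spec$a0,
                  if (diag$pass) "pass" else "FAIL"))
  if (!diag$pass && !allow_nonconverged) {
    pp_stop("MCMC diagnostics failed (rerun with longer chains or allow_nonconverged)",
            class = "pp_convergence_error")
  }
  invisible(list(fit = fit, summary = summary, effects = effects,
                 diagnostics = diag))
}

#' Run the a0 sweep plus the frequentist comparison and write reports
#'
#' Writes the sweep table, the four sweep figures, the frequentist
#' three-panel interaction table, and a provenance sidecar.
#'
#' @inheritParams run_simulate
#' @return Invisibly: list with the sweep table, report, and frequentist
#'   panel.
#' @export
run_sweep <- function(config, out_dir) {
  cfg <- as_config_list(config)
  seed <- require_seed(cfg)
  prepare_out_dir(out_dir)
  pair <- load_pair(cfg, seed)
  grid <- as.numeric(cfg$grid %||% seq(0, 1, by = 0.1))
  sweep <- a0_sweep(pair$current, pair$historical, grid = grid,
                    chain_config = cfg_chains(cfg, seed),
                    priors = cfg_priors(cfg), offset = isTRUE(cfg$offset))
  report <- sweep_report(sweep)
  label <- cfg$label %||% "sweep"
  write_sweep_report(report, out_dir, label = label)
  panel <- three_panel_comparison(pair$historical, pair$current,
                                  offset = isTRUE(cfg$offset))
  readr::write_csv(panel, file.path(out_dir, paste0(label, "_frequentist.csv")))
  write_provenance(cfg, out_dir, "sweep")
  message(sprintf("run_sweep: %d grid values, outputs in %s",
                  nrow(sweep), out_dir))
  invisible(list(sweep = sweep, report = report, frequentist = panel))
}
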