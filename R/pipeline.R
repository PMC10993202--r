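#' Pipeline configuration
#'
#' A flat key-value list steering the end-to-end pipeline
#' (simulate -> fit -> compare -> recover -> contrast). All randomness flows
#' from the single `seed`, split deterministically per stage. Unknown keys are
#' rejected so config typos surface early.
#'
#' @param seed Root seed.
#' @param n_participants Cohort size for simulation.
#' @param model Generating / fitted model identifier.
#' @param models Model set for comparison (default all eight).
#' @param condition Condition to fit.
#' @param warmup,draws,chains,thin MCMC settings (see [dd_fit_config()]).
#' @param initial_immediate,steps,delayed_amount,delays_days,choices_per_block,runs_per_condition,conditions
#'   Staircase overrides (see [staircase_config()]).
#' @param verbose Emit progress messages to stderr.
#' @return List of class `dd_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_participants = 28L,
                            model = "exp_scaled",
                            models = dd_models()$model,
                            condition = "food",
                            warmup = 2000L, draws = 500L, chains = 4L, thin = 10L,
                            initial_immediate = 20, steps = c(10, 5, 2.5, 1),
                            delayed_amount = 40,
                            delays_days = c(2, 14, 30, 90, 180, 365),
                            choices_per_block = 5L, runs_per_condition = 2L,
                            conditions = c("food", "money"),
                            verbose = FALSE) {
  cfg <- as.list(environment())
  structure(cfg, class = "dd_pipeline_config")
}

#' Read a pipeline configuration from flat JSON
#'
#' @param path JSON file whose keys mirror [pipeline_config()] arguments.
#' @return A `dd_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

config_staircase <- function(cfg) {
  staircase_config(
    initial_immediate = cfg$initial_immediate, steps = cfg$steps,
    delayed_amount = cfg$delayed_amount, delays_days = cfg$delays_days,
    choices_per_block = cfg$choices_per_block,
    runs_per_condition = cfg$runs_per_condition, conditions = cfg$conditions
  )
}

config_fit <- function(cfg, stage) {
  dd_fit_config(warmup = cfg$warmup, draws = cfg$draws, chains = cfg$chains,
                seed = derive_seed(cfg$seed, stage), thin = cfg$thin)
}

# Deterministic per-stage seed split from the root seed.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 104729 * stage) %% 2147483646 + 1)
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

pipeline_log <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message("[discountr] ", ...)
  invisible(NULL)
}

check_out_dir <- function(path) {
  d <- dirname(path)
  if (!dir.exists(d)) {
    rlang::abort(paste0("Output directory does not exist: ", d))
  }
  path
}

#' Pipeline stages
#'
#' Each stage reads/writes the module CSV/JSON interfaces so a full analysis
#' can be scripted or driven from the command line. Every JSON artifact embeds
#' the configuration hash and the seed used.
#'
#' * `run_simulate()` writes the choice CSV and the generating-parameter
#'   sidecar CSV.
#' * `run_fit()` fits one model/condition and persists the posterior
#'   ([write_fit_csv()]).
#' * `run_compare()` fits a set of models to the same data and writes the
#'   WAIC comparison table.
#' * `run_recover()` runs a parameter-recovery simulation from a truth CSV.
#' * `run_contrast()` contrasts the population discount rate between two
#'   persisted fits.
#'
#' @param cfg A [pipeline_config()].
#' @param choices_path,truth_path,fit_path,fit_path_a,fit_path_b,out_path,out_prefix
#'   File paths of stage inputs/outputs.
#' @param parameter Parameter contrasted by `run_contrast`.
#' @return Each stage returns its primary artifact path(s) invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(cfg, choices_path, truth_path) {
  check_out_dir(choices_path)
  check_out_dir(truth_path)
  coh <- simulate_cohort(
    cfg$n_participants, cfg$model, config = config_staircase(cfg),
    seed = derive_seed(cfg$seed, 1L)
  )
  write_choice_csv(coh$trials, choices_path)
  write_truth_csv(coh$truth, truth_path)
  pipeline_log(cfg, "simulate: ", nrow(coh$trials), " trials, config hash ",
               config_hash(cfg))
  invisible(c(choices = choices_path, truth = truth_path))
}

#' @rdname pipeline
#' @export
run_fit <- function(cfg, choices_path, fit_path) {
  check_out_dir(fit_path)
  trials <- read_choice_csv(choices_path)
  fit <- fit_dd(trials, cfg$model, condition = cfg$condition,
                config = config_fit(cfg, 2L))
  flagged <- dplyr::filter(fit$rhat, .data$flagged)
  if (nrow(flagged) > 0) {
    warning(nrow(flagged), " parameter(s) with Rhat > 1.1; inspect chains.",
            call. = FALSE)
  }
  write_fit_csv(fit, fit_path)
  pipeline_log(cfg, "fit: ", cfg$model, "/", cfg$condition, ", max Rhat ",
               format(max(fit$rhat$rhat), digits = 4), ", config hash ",
               config_hash(cfg))
  invisible(fit_path)
}

#' @rdname pipeline
#' @export
run_compare <- function(cfg, choices_path, out_path) {
  check_out_dir(out_path)
  trials <- read_choice_csv(choices_path)
  fits <- lapply(seq_along(cfg$models), function(i) {
    pipeline_log(cfg, "compare: fitting ", cfg$models[i])
    fit_dd(trials, cfg$models[i], condition = cfg$condition,
           config = config_fit(cfg, 100L + i))
  })
  names(fits) <- cfg$models
  cmp <- compare_models(fits)
  readr::write_csv(tibble::as_tibble(cmp), out_path)
  invisible(out_path)
}

#' @rdname pipeline
#' @export
run_recover <- function(cfg, truth_path, out_prefix) {
  check_out_dir(out_prefix)
  truth_long <- readr::read_csv(truth_path, show_col_types = FALSE)
  truth <- truth_long |>
    dplyr::filter(.data$condition == cfg$condition) |>
    tidyr::pivot_wider(id_cols = "participant_id", names_from = "parameter",
                       values_from = "value")
  rec <- parameter_recovery(
    truth, cfg$model, config = config_staircase(cfg),
    fit_config = config_fit(cfg, 3L), condition = cfg$condition,
    seed = derive_seed(cfg$seed, 4L)
  )
  readr::write_csv(rec$pairs, paste0(out_prefix, "_pairs.csv"))
  jsonlite::write_json(
    list(stats = rec$stats, model = rec$model, seed = cfg$seed,
         config_hash = config_hash(cfg)),
    paste0(out_prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(out_prefix, ".json"))
}

#' @rdname pipeline
#' @export
run_contrast <- function(cfg, fit_path_a, fit_path_b, out_path,
                         parameter = "k") {
  check_out_dir(out_path)
  fit_a <- read_fit_csv(fit_path_a)
  fit_b <- read_fit_csv(fit_path_b)
  ct <- condition_contrast(fit_a, fit_b, parameter = parameter)
  jsonlite::write_json(
    list(
      parameter = parameter, mean = ct$mean,
      hdi_low = ct$hdi[["lower"]], hdi_high = ct$hdi[["upper"]],
      excludes_zero = ct$excludes_zero, seed = cfg$seed,
      config_hash = config_hash(cfg)
    ),
    out_path, auto_unbox = TRUE, digits = NA
  )
  invisible(out_path)
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) {
      rlang::abort(paste0("Expected --flag, got: ", args[i]))
    }
    key <- sub("^--", "", args[i])
    if (i == length(args)) rlang::abort(paste0("Missing value for --", key))
    out[[key]] <- args[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `fit`, `compare`, `recover`,
#' `contrast`. Flags: `--config <json>` (see [read_pipeline_config()]) plus
#' stage paths `--choices`, `--truth`, `--fit`, `--fit-a`, `--fit-b`,
#' `--out`; `--seed`, `--model` and `--condition` override the config file.
#' Installed alongside the package as `inst/cli/discountr.R`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status 0 invisibly; errors propagate (nonzero exit under
#'   `Rscript`).
#' @export
dd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    rlang::abort("Usage: discountr.R <simulate|fit|compare|recover|contrast> [--flags]")
  }
  cmd <- args[1]
  opts <- parse_cli_args(args[-1])
  cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
         else pipeline_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$model)) cfg$model <- opts$model
  if (!is.null(opts$condition)) cfg$condition <- opts$condition
  switch(cmd,
    simulate = run_simulate(cfg, opts$choices, opts$truth),
    fit = run_fit(cfg, opts$choices, opts$fit),
    compare = run_compare(cfg, opts$choices, opts$out),
    recover = run_recover(cfg, opts$truth, opts$out),
    contrast = run_contrast(cfg, opts[["fit-a"]], opts[["fit-b"]], opts$out),
    rlang::abort(paste0("Unknown subcommand: ", cmd))
  )
  invisible(0L)
}
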