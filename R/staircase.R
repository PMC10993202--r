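#' Staircase task configuration
#'
#' Describes the adaptive amount-adjustment intertemporal-choice task: the
#' delayed reward is fixed at 40 units, the immediate offer starts at 20 units
#' and is titrated towards the indifference point with shrinking steps (10, 5,
#' 2.5, 1) over five choices per delay block. Each run presents the six delays
#' (2 d, 2 wk, 1/3/6 months, 1 yr; months as 30 d, year as 365 d) once, in
#' random block order, and each condition is run twice, the runs alternating
#' food-money-food-money.
#'
#' @param initial_immediate Starting immediate offer (units).
#' @param steps Offer adjustments applied before trials 2..5 (units).
#' @param delayed_amount Fixed delayed reward (units).
#' @param delays_days The six block delays, in days.
#' @param choices_per_block Trials per delay block.
#' @param runs_per_condition Runs of the task per condition.
#' @param conditions Condition labels; runs alternate between them.
#' @return A list of class `staircase_config`.
#' @export
staircase_config <- function(initial_immediate = 20,
                             steps = c(10, 5, 2.5, 1),
                             delayed_amount = 40,
                             delays_days = c(2, 14, 30, 90, 180, 365),
                             choices_per_block = 5,
                             runs_per_condition = 2,
                             conditions = c("food", "money")) {
  if (length(steps) != choices_per_block - 1) {
    rlang::abort("`steps` must have length `choices_per_block - 1`.")
  }
  structure(
    list(
      initial_immediate = initial_immediate, steps = steps,
      delayed_amount = delayed_amount, delays_days = delays_days,
      choices_per_block = choices_per_block,
      blocks_per_run = length(delays_days),
      runs_per_condition = runs_per_condition,
      conditions = conditions
    ),
    class = "staircase_config"
  )
}

#' Next immediate offer in the staircase
#'
#' After the `trial_index`-th choice of a block the immediate offer moves by
#' `steps[trial_index]`: up if the delayed reward was chosen (the immediate
#' option must become more attractive), down if the immediate was chosen.
#'
#' @param current Current immediate offer (units).
#' @param choice 1 (or `"delayed"`) if the delayed reward was chosen, 0 (or
#'   `"immediate"`) otherwise.
#' @param trial_index Index of the choice just made, 1..4.
#' @param config A [staircase_config()].
#' @return The next immediate offer (units).
#' @export
#' @examples
#' next_offer(20, 1, 1) # 30
#' next_offer(20, 0, 1) # 10
next_offer <- function(current, choice, trial_index,
                       config = staircase_config()) {
  if (any(trial_index < 1) || any(trial_index > length(config$steps))) {
    rlang::abort(paste0("`trial_index` must be in 1..", length(config$steps), "."))
  }
  if (is.character(choice)) choice <- as.integer(choice == "delayed")
  step <- config$steps[trial_index]
  current + ifelse(choice == 1, step, -step)
}

#' Simulate one five-choice delay block
#'
#' Runs the staircase for a single delay: starting from the initial immediate
#' offer, each choice is drawn Bernoulli with the model's lapse-limited choice
#' probability and the next offer follows [next_offer()].
#'
#' @param delay Block delay in days.
#' @param model Generating model identifier (see [dd_models()]).
#' @param params Named list of model parameters (may include `error`).
#' @param error Lapse probability; defaults to `params$error` or 0.
#' @param config A [staircase_config()].
#' @param standardizer DRIFT standardizer (applied per block here).
#' @param responder `"stochastic"` draws each choice Bernoulli with the
#'   model's choice probability; `"thresholded"` chooses the delayed option
#'   deterministically whenever that probability is at least 0.5 (useful for
#'   staircase calibration checks).
#' @return Tibble with one row per trial: `trial`, `delay_days`,
#'   `amount_immediate`, `amount_delayed`, `choice`.
#' @export
simulate_block <- function(delay, model, params, error = NULL,
                           config = staircase_config(),
                           standardizer = standardize_z,
                           responder = c("stochastic", "thresholded")) {
  responder <- match.arg(responder)
  if (is.null(error)) error <- if (is.null(params$error)) 0 else params$error
  n <- config$choices_per_block
  offer <- config$initial_immediate
  offers <- numeric(n)
  choices <- integer(n)
  for (t in seq_len(n)) {
    offers[t] <- offer
    row <- tibble::tibble(
      amount_immediate = offer,
      amount_delayed = config$delayed_amount,
      delay_days = delay
    )
    dv <- decision_value(row, model, params, standardizer = standardizer)
    p <- choice_probability(dv, error)
    choices[t] <- if (responder == "thresholded") as.integer(p >= 0.5) else
      stats::rbinom(1L, 1L, p)
    if (t < n) offer <- next_offer(offer, choices[t], t, config)
  }
  tibble::tibble(
    trial = seq_len(n), delay_days = delay,
    amount_immediate = offers, amount_delayed = config$delayed_amount,
    choice = choices
  )
}

# Inverse-CDF truncated-normal sampler; sd = 0 degenerates to the mean
# (clamped into the support).
rtruncated_normal <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) rlang::abort("`sd` must be >= 0.")
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

param_support <- function(parameter) {
  switch(parameter,
    k = c(0, Inf),
    s = c(0, Inf),
    error = c(0, 0.2),
    scaling1 = c(0, Inf),
    scaling2 = c(0, Inf),
    scaling3 = c(0, Inf),
    c(-Inf, Inf) # regression-style weights are unbounded
  )
}

default_population <- function(model) {
  if (dd_models()$class[match(match_model(model), dd_models()$model)] == "sv") {
    list(
      mean = c(k = 0.05, s = 1, error = 0.05),
      sd = c(k = 0.02, s = 0, error = 0)
    )
  } else if (match_model(model) == "trade") {
    list(
      mean = c(scaling1 = 0.5, scaling2 = 0.5, scaling3 = 0.5, error = 0.05),
      sd = c(scaling1 = 0.1, scaling2 = 0.1, scaling3 = 0.1, error = 0)
    )
  } else {
    p <- model_parameters(model)
    list(
      mean = stats::setNames(c(rep(0.25, length(p)), 0.05), c(p, "error")),
      sd = stats::setNames(c(rep(0.1, length(p)), 0), c(p, "error"))
    )
  }
}

draw_participant_params <- function(model, pop_mean, pop_sd) {
  pars <- c(model_parameters(model), "error")
  out <- numeric(length(pars))
  names(out) <- pars
  for (p in pars) {
    if (is.na(pop_mean[p])) rlang::abort(paste0("Missing population mean for `", p, "`."))
    sup <- param_support(p)
    out[p] <- rtruncated_normal(1, pop_mean[[p]], pop_sd[[p]], sup[1], sup[2])
  }
  out
}

#' Simulate a cohort of discounters performing the staircase task
#'
#' Draws per-participant parameters from truncated-normal population
#' distributions (truncation matching each parameter's support: discount rate
#' and scalings positive, lapse in (0, 0.2], weights unbounded) and simulates
#' the full task: per condition, `runs_per_condition` runs of one randomized
#' five-choice block per delay. Runs alternate between conditions
#' (food, money, food, money by default).
#'
#' @param n_participants Number of simulated participants.
#' @param model Generating model identifier.
#' @param pop_mean,pop_sd Named numeric vectors of population means/SDs for
#'   the model's parameters plus `error`. Defaults: `k` mean 0.05 SD 0.02,
#'   `s = 1`, `error = 0.05` for SV models. Either a single set used for both
#'   conditions, or a named list with one set per condition.
#' @param config A [staircase_config()].
#' @param seed Integer seed; the dataset is reproducible given the seed.
#' @return An object of class `dd_cohort`: list with `trials` (tibble, one
#'   row per choice), `truth` (long tibble of generating parameters:
#'   `participant_id`, `condition`, `parameter`, `value`), `model`, `config`,
#'   `seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(2, "exp", seed = 1)
#' nrow(coh$trials) # 2 participants x 2 conditions x 60 trials
simulate_cohort <- function(n_participants, model = "exp_scaled",
                            pop_mean = NULL, pop_sd = NULL,
                            config = staircase_config(), seed = 1L) {
  model <- match_model(model)
  if (n_participants < 1) rlang::abort("`n_participants` must be >= 1.")
  defaults <- default_population(model)
  per_condition <- function(x, default) {
    if (is.null(x)) x <- default
    if (!is.list(x)) x <- stats::setNames(
      rep(list(x), length(config$conditions)), config$conditions
    )
    x
  }
  pop_mean <- per_condition(pop_mean, defaults$mean)
  pop_sd <- per_condition(pop_sd, defaults$sd)
  if (any(unlist(pop_sd) < 0)) rlang::abort("Population SDs must be >= 0.")

  set.seed(seed)
  run_conditions <- rep(config$conditions, config$runs_per_condition)
  trials <- vector("list", 0)
  truth <- vector("list", 0)
  for (j in seq_len(n_participants)) {
    theta <- lapply(config$conditions, function(cond) {
      draw_participant_params(model, pop_mean[[cond]], pop_sd[[cond]])
    })
    names(theta) <- config$conditions
    for (cond in config$conditions) {
      truth[[length(truth) + 1]] <- tibble::tibble(
        participant_id = j, condition = cond,
        parameter = names(theta[[cond]]), value = unname(theta[[cond]])
      )
    }
    for (r in seq_along(run_conditions)) {
      cond <- run_conditions[r]
      th <- theta[[cond]]
      block_delays <- sample(config$delays_days)
      for (b in seq_along(block_delays)) {
        params <- as.list(th[setdiff(names(th), "error")])
        blk <- simulate_block(block_delays[b], model, params,
                              error = th[["error"]], config = config)
        blk$participant_id <- j
        blk$condition <- cond
        blk$run <- r
        blk$block <- b
        trials[[length(trials) + 1]] <- blk
      }
    }
  }
  trials <- dplyr::bind_rows(trials)
  trials <- dplyr::select(
    trials, "participant_id", "condition", "run", "block", "trial",
    "delay_days", "amount_immediate", "amount_delayed", "choice"
  )
  structure(
    list(
      trials = trials, truth = dplyr::bind_rows(truth),
      model = model, config = config, seed = seed
    ),
    class = "dd_cohort"
  )
}

#' @export
print.dd_cohort <- function(x, ...) {
  cat("Simulated delay-discounting cohort\n")
  cat("  generating model:", x$model, " seed:", x$seed, "\n")
  cat("  participants:", length(unique(x$trials$participant_id)),
      " trials:", nrow(x$trials), "\n")
  invisible(x)
}

#' Empirical indifference points from titrated blocks
#'
#' For each completed five-choice block, the indifference-point estimate is
#' the immediate amount a hypothetical sixth trial would offer: the final
#' offer adjusted once more by the final (1 unit) step in the direction
#' implied by the last choice.
#'
#' @param data Tibble of trials (at least `delay_days`, `trial`,
#'   `amount_immediate`, `choice`, plus any grouping columns among
#'   `participant_id`, `condition`, `run`, `block`).
#' @param config A [staircase_config()].
#' @return Tibble with one row per block: grouping columns, `delay_days` and
#'   `indifference_point`.
#' @export
indifference_points <- function(data, config = staircase_config()) {
  keys <- intersect(c("participant_id", "condition", "run", "block"),
                    names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "delay_days")))) |>
    dplyr::group_modify(function(blk, key) {
      if (nrow(blk) != config$choices_per_block) {
        rlang::abort("Incomplete block: expected a full five-choice block.")
      }
      blk <- dplyr::arrange(blk, .data$trial)
      last <- blk[nrow(blk), ]
      step <- config$steps[length(config$steps)]
      ip <- last$amount_immediate + ifelse(last$choice == 1, step, -step)
      tibble::tibble(indifference_point = ip)
    }) |>
    dplyr::ungroup()
}

#' Quality-control filter for one-sided or inattentive responders
#'
#' Excludes participants who chose the same option in strictly more than 90%
#' of their trials (pooled across conditions), and, when reaction times are
#' recorded (`rt_s` column), participants with reaction times above 12 s on
#' more than half of their trials.
#'
#' @param data Tibble of trials with `participant_id`, `choice`, optionally
#'   `rt_s`.
#' @param max_same_prop Exclusion threshold on the proportion of same-option
#'   choices (exclusive bound).
#' @param rt_limit_s Reaction-time threshold in seconds.
#' @return List with `retained` (filtered tibble) and `exclusions` (tibble:
#'   `participant_id`, `reason`, `statistic`).
#' @export
qc_filter <- function(data, max_same_prop = 0.9, rt_limit_s = 12) {
  stats_tbl <- data |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      prop_same = max(mean(.data$choice), 1 - mean(.data$choice)),
      prop_slow = if ("rt_s" %in% names(data)) {
        mean(!is.na(.data$rt_s) & .data$rt_s > rt_limit_s)
      } else 0,
      .groups = "drop"
    )
  excl <- dplyr::bind_rows(
    stats_tbl |>
      dplyr::filter(.data$prop_same > max_same_prop) |>
      dplyr::transmute(.data$participant_id, reason = "one_sided",
                       statistic = .data$prop_same),
    stats_tbl |>
      dplyr::filter(.data$prop_slow > 0.5) |>
      dplyr::transmute(.data$participant_id, reason = "slow_rt",
                       statistic = .data$prop_slow)
  )
  list(
    retained = dplyr::filter(
      data, !.data$participant_id %in% excl$participant_id
    ),
    exclusions = excl
  )
}

#' Read and write choice data as CSV
#'
#' One row per trial: `participant_id`, `condition`, `run`, `block`, `trial`,
#' `delay_days`, `amount_immediate`, `amount_delayed`, `choice` (0 =
#' immediate, 1 = delayed), optional `rt_s`. UTF-8, header required.
#'
#' @param data Tibble of trials.
#' @param path File path.
#' @return `read_choice_csv` returns the trials tibble; `write_choice_csv`
#'   returns `path` invisibly.
#' @export
write_choice_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_choice_csv
#' @export
read_choice_csv <- function(path) {
  required <- c("participant_id", "condition", "run", "block", "trial",
                "delay_days", "amount_immediate", "amount_delayed", "choice")
  data <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("Choice CSV missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  bad <- which(!data$choice %in% c(0, 1))
  if (length(bad) > 0) {
    rlang::abort(paste0("`choice` must be 0/1; offending rows: ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  data
}

#' Write the generating-parameter sidecar CSV
#'
#' Long format: `participant_id`, `condition`, `parameter`, `value`.
#'
#' @param truth Tibble of generating parameters (e.g. `simulate_cohort()$truth`).
#' @param path File path.
#' @export
write_truth_csv <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}
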