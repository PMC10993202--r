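#' Highest density interval of posterior draws
#'
#' The shortest contiguous interval of sorted draws containing
#' `ceiling(mass * n)` samples — for unimodal posteriors, the region of
#' highest density holding the stated mass.
#'
#' @param samples Numeric vector of draws (length >= 20).
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' hdi(rnorm(1e4)) # approximately c(-1.96, 1.96)
hdi <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 20) rlang::abort("`hdi` needs at least 20 finite samples.")
  if (mass <= 0 || mass >= 1) rlang::abort("`mass` must be in (0, 1).")
  x <- sort(samples)
  m <- ceiling(mass * n)
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1])
}

#' Population-level posterior draws of one parameter
#'
#' Extracts the `Mu` draws for a free parameter, ordered by chain then draw.
#'
#' @param fit A `dd_fit`.
#' @param parameter Free parameter name (default `"k"`).
#' @return Numeric vector of draws.
#' @export
population_draws <- function(fit, parameter = "k") {
  target <- paste0("mu_", parameter)
  d <- dplyr::filter(fit$draws, .data$parameter == target)
  if (nrow(d) == 0) {
    rlang::abort(paste0("Population parameter `", target, "` not in fit."))
  }
  dplyr::arrange(d, .data$chain, .data$draw)$value
}

#' Posterior means of participant-level parameters
#'
#' @param fit A `dd_fit`.
#' @return Tibble: `participant_id`, one column per free parameter.
#' @export
participant_estimates <- function(fit) {
  fit$draws |>
    dplyr::filter(!is.na(.data$participant_id)) |>
    dplyr::group_by(.data$participant_id, .data$parameter) |>
    dplyr::summarise(estimate = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "estimate") |>
    dplyr::arrange(.data$participant_id)
}

#' Parameter-recovery simulation
#'
#' Validates the estimation pipeline: simulate a cohort from known
#' participant-level parameters, refit with the same hierarchical method, and
#' correlate the posterior-mean estimates with the generating values,
#' parameter by parameter (Pearson, two-sided).
#'
#' @param truth Wide tibble of generating participant parameters:
#'   `participant_id` plus one column per free parameter (including `error`).
#'   Typically `simulate_cohort()$truth` reshaped, or any specified values.
#' @param model Model identifier used both to generate and to fit.
#' @param config A [staircase_config()]; the simulated task uses a single
#'   condition (`condition` label below).
#' @param fit_config A [dd_fit_config()]; reduced settings are adequate for
#'   synthetic cohorts.
#' @param condition Condition label given to the simulated trials.
#' @param seed Seed for the simulation.
#' @return Object of class `dd_recovery`: `stats` (tibble: `parameter`, `r`,
#'   `p`, `n`; `r` is `NA` for zero-variance generating values), `pairs`
#'   (long tibble of true vs recovered values), `fit`, `model`.
#' @export
parameter_recovery <- function(truth, model = "exp_scaled",
                               config = staircase_config(),
                               fit_config = dd_fit_config(
                                 warmup = 2000, draws = 500, chains = 4
                               ),
                               condition = "food", seed = 1L) {
  if (nrow(truth) < 3) rlang::abort("Recovery needs >= 3 participants.")
  model <- match_model(model)
  pars <- c(model_parameters(model), "error")
  missing <- setdiff(pars, names(truth))
  if (length(missing) > 0) {
    rlang::abort(paste0("`truth` missing parameter columns: ",
                        paste(missing, collapse = ", ")))
  }
  cfg <- config
  cfg$conditions <- condition
  set.seed(seed)
  trials <- purrr::map_dfr(seq_len(nrow(truth)), function(j) {
    th <- as.list(truth[j, pars])
    purrr::map_dfr(seq_len(cfg$runs_per_condition), function(r) {
      delays <- sample(cfg$delays_days)
      purrr::imap_dfr(delays, function(d, b) {
        blk <- simulate_block(d, model, th[setdiff(pars, "error")],
                              error = th$error, config = cfg)
        dplyr::mutate(blk,
          participant_id = truth$participant_id[j],
          condition = condition, run = r, block = b
        )
      })
    })
  })
  fit <- fit_dd(trials, model, condition = condition, config = fit_config)
  est <- participant_estimates(fit)
  pairs <- truth |>
    dplyr::select(dplyr::all_of(c("participant_id", pars))) |>
    tidyr::pivot_longer(-"participant_id", names_to = "parameter",
                        values_to = "true") |>
    dplyr::inner_join(
      tidyr::pivot_longer(est, -"participant_id", names_to = "parameter",
                          values_to = "recovered"),
      by = c("participant_id", "parameter")
    )
  stats_tbl <- pairs |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      r = if (stats::sd(.data$true) == 0 || stats::sd(.data$recovered) == 0) {
        NA_real_
      } else stats::cor(.data$true, .data$recovered),
      p = if (is.na(.data$r[1]) || dplyr::n() < 3) NA_real_ else {
        stats::cor.test(.data$true, .data$recovered)$p.value
      },
      n = dplyr::n(), .groups = "drop"
    )
  structure(
    list(stats = stats_tbl, pairs = pairs, fit = fit, model = model),
    class = "dd_recovery"
  )
}

#' @export
print.dd_recovery <- function(x, ...) {
  cat("Parameter recovery (", x$model, ")\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Posterior contrast of the discount rate between conditions
#'
#' Computes the per-draw difference of the population-level parameter
#' (default the discount rate `k`) between two fits of the same model, e.g.
#' food minus money, and summarises it by its mean and 95% highest density
#' interval. The contrast is taken on population-level `Mu` draws, giving a
#' proper posterior for the difference; `excludes_zero` flags an HDI lying
#' entirely at or below / at or above zero.
#'
#' @param fit_a,fit_b `dd_fit` objects of the same model (e.g. the two
#'   conditions); the delta is `a - b` draw by draw.
#' @param parameter Free parameter to contrast (default `"k"`).
#' @param mass HDI mass.
#' @return Object of class `dd_contrast`: `delta` (draws), `mean`, `hdi`
#'   (lower/upper), `excludes_zero`, `parameter`, `conditions`.
#' @export
condition_contrast <- function(fit_a, fit_b, parameter = "k", mass = 0.95) {
  if (fit_a$model != fit_b$model) {
    rlang::abort("Fits must come from the same model.")
  }
  a <- population_draws(fit_a, parameter)
  b <- population_draws(fit_b, parameter)
  if (length(a) != length(b)) {
    rlang::abort("Draw counts differ; refit or resample to match.")
  }
  delta <- a - b
  h <- hdi(delta, mass)
  # an interval touching zero from one side counts as excluding it, but a
  # degenerate all-zero delta does not
  excl <- (h[["lower"]] >= 0 || h[["upper"]] <= 0) &&
    !(h[["lower"]] == 0 && h[["upper"]] == 0)
  structure(
    list(
      delta = delta, mean = mean(delta), hdi = h,
      excludes_zero = excl,
      parameter = parameter,
      conditions = c(fit_a$condition %||% "A", fit_b$condition %||% "B"),
      mass = mass
    ),
    class = "dd_contrast"
  )
}

#' @export
print.dd_contrast <- function(x, ...) {
  cat(sprintf(
    "Contrast of mu_%s (%s - %s): mean %.5f, %d%% HDI [%.5f, %.5f]%s\n",
    x$parameter, x$conditions[1], x$conditions[2], x$mean,
    round(100 * x$mass), x$hdi[["lower"]], x$hdi[["upper"]],
    if (x$excludes_zero) " (excludes 0)" else ""
  ))
  invisible(x)
}

#' Correlation of participant discount rates across conditions
#'
#' Pearson correlation (two-sided test) between paired posterior-mean
#' estimates, e.g. each participant's `k` for food vs money.
#'
#' @param data Tibble with one row per participant.
#' @param col_a,col_b Column names of the paired estimates.
#' @return Tibble: `r`, `p`, `n`.
#' @export
cross_condition_correlation <- function(data, col_a = "k_food",
                                        col_b = "k_money") {
  x <- data[[col_a]]
  y <- data[[col_b]]
  if (length(x) < 3 || length(y) < 3) rlang::abort("Need at least 3 pairs.")
  ct <- stats::cor.test(x, y)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
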