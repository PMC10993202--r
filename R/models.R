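#' Available choice models
#'
#' The package implements eight models of intertemporal choice: five
#' option-based subjective-value (SV) discounting models and three
#' attribute-wise heuristic models. Option-based models discount each option
#' independently and compare subjective values; heuristic models compare the
#' amount and delay attributes across options directly.
#'
#' @return A tibble with one row per model: `model` (identifier), `class`
#'   (`"sv"` or `"heuristic"`), and `parameters` (list-column of free
#'   parameter names, excluding the shared lapse `error` term).
#' @export
#' @examples
#' dd_models()
dd_models <- function() {
  tibble::tibble(
    model = c(
      "exp", "exp_scaled", "hyp", "hyp_delay_scaled", "hyp_denom_scaled",
      "itch", "drift", "trade"
    ),
    class = c(rep("sv", 5), rep("heuristic", 3)),
    parameters = list(
      "k", c("k", "s"), "k", c("k", "s"), c("k", "s"),
      c("beta_xA", "beta_xR", "beta_tA", "beta_tR"),
      c("beta_xA", "beta_xR", "beta_tA", "beta_xt"),
      c("scaling1", "scaling2", "scaling3")
    )
  )
}

match_model <- function(model) {
  m <- tolower(model)
  ids <- dd_models()$model
  if (length(m) != 1L || !m %in% ids) {
    rlang::abort(paste0(
      "Unknown model '", paste(model, collapse = ","),
      "'. Available: ", paste(ids, collapse = ", ")
    ))
  }
  m
}

model_parameters <- function(model) {
  m <- match_model(model)
  tbl <- dd_models()
  tbl$parameters[[match(m, tbl$model)]]
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort(paste0("`", name, "` must be finite and > 0."))
  }
  invisible(x)
}

#' Subjective value of a delayed reward
#'
#' Discounts an amount `A` delivered after a delay `D` (days) under one of the
#' five option-based models. Definitions:
#' \describe{
#'   \item{exp}{`A * exp(-k * D)`}
#'   \item{exp_scaled}{`A * exp(-(k * D)^s)`}
#'   \item{hyp}{`A / (1 + k * D)`}
#'   \item{hyp_delay_scaled}{`A / (1 + k * D^s)`}
#'   \item{hyp_denom_scaled}{`A / (1 + k * D)^s`}
#' }
#' With `s = 1` each scaled model reduces exactly to its unscaled counterpart,
#' and an immediate option (`D = 0`) keeps its face value under every model.
#'
#' @param amount Reward amount(s), units of the task (> 0).
#' @param delay Delay(s) in days (>= 0). Recycled against `amount`.
#' @param model One of `"exp"`, `"exp_scaled"`, `"hyp"`, `"hyp_delay_scaled"`,
#'   `"hyp_denom_scaled"`.
#' @param k Discount rate (> 0); larger `k` means steeper devaluation.
#' @param s Time-scaling exponent (> 0); ignored by the unscaled models.
#' @return Numeric vector of subjective values, `0 < SV <= amount`.
#' @export
#' @examples
#' subjective_value(40, 10, "hyp", k = 0.1) # 20
#' subjective_value(40, c(0, 30, 365), "exp_scaled", k = 0.04, s = 0.5)
subjective_value <- function(amount, delay, model, k, s = 1) {
  m <- match_model(model)
  if (!m %in% dd_models()$model[dd_models()$class == "sv"]) {
    rlang::abort("`model` must be one of the five subjective-value models.")
  }
  check_positive(k, "k")
  check_positive(s, "s")
  if (any(delay < 0)) rlang::abort("`delay` must be >= 0 days.")
  switch(m,
    exp = amount * exp(-k * delay),
    exp_scaled = amount * exp(-(k * delay)^s),
    hyp = amount / (1 + k * delay),
    hyp_delay_scaled = amount / (1 + k * delay^s),
    hyp_denom_scaled = amount / (1 + k * delay)^s
  )
}

#' Z-standardize a factor with a unit-scale fallback
#'
#' Centers and scales a numeric vector. A factor with zero spread (all values
#' equal) is only centered, i.e. maps to zero, so degenerate designs remain
#' usable in the DRIFT model.
#'
#' @param x Numeric vector.
#' @return Standardized vector of the same length.
#' @export
standardize_z <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  (x - mean(x)) / s
}

heuristic_attributes <- function(data) {
  x1 <- data$amount_immediate
  x2 <- data$amount_delayed
  t2 <- data$delay_days
  t1 <- if ("delay_immediate" %in% names(data)) data$delay_immediate else 0
  list(x1 = x1, x2 = x2, t1 = rep_len(t1, length(x2)), t2 = t2)
}

#' Attribute-wise decision values (ITCH, DRIFT, TRADE)
#'
#' Compute the decision value of choosing the delayed over the immediate
#' option by comparing amounts and delays across options. Positive values
#' favour the delayed option. `data` is one row per trial with columns
#' `amount_immediate`, `amount_delayed`, `delay_days` (and optionally
#' `delay_immediate`, default 0).
#'
#' ITCH sums four weighted comparisons: absolute and relative amount
#' differences and absolute and relative delay differences, the relative terms
#' divided by the two-option mean. DRIFT replaces the relative-delay term with
#' a weighted per-period implied growth rate `(x2/x1)^(1/(t2-t1)) - 1` and
#' passes every factor through a standardizer `z`. TRADE log-scales amounts
#' and delays, `v(x) = log(1 + scaling2*x)/scaling2` and
#' `w(t) = log(1 + scaling3*t)/scaling3`, and returns
#' `(v(x2) - v(x1)) - scaling1*(w(t2) - w(t1))`, so longer delays penalize the
#' delayed option.
#'
#' @param data Tibble/data frame of trials (see above).
#' @param beta_xA,beta_xR,beta_tA,beta_tR,beta_xt Attribute weights
#'   (dimensionless).
#' @param scaling1,scaling2,scaling3 Positive TRADE scalers: `scaling2` scales
#'   amounts, `scaling3` delays, `scaling1` the relevance of scaled delay.
#' @param standardizer Function applied to each DRIFT factor across the rows
#'   of `data`; defaults to [standardize_z()]. Use `identity` for raw factors.
#' @return Numeric vector of decision values, one per trial.
#' @name decision_value_heuristic
NULL

#' @rdname decision_value_heuristic
#' @export
decision_value_itch <- function(data, beta_xA = 0, beta_xR = 0,
                                beta_tA = 0, beta_tR = 0) {
  at <- heuristic_attributes(data)
  mean_x <- (at$x2 + at$x1) / 2
  mean_t <- (at$t2 + at$t1) / 2
  if ((beta_xR != 0 && any(mean_x == 0)) || (beta_tR != 0 && any(mean_t == 0))) {
    rlang::abort("Degenerate denominator: zero mean amount or delay with a nonzero relative weight.")
  }
  dv <- beta_xA * (at$x2 - at$x1) + beta_tA * (at$t2 - at$t1)
  if (beta_xR != 0) dv <- dv + beta_xR * (at$x2 - at$x1) / mean_x
  if (beta_tR != 0) dv <- dv + beta_tR * (at$t2 - at$t1) / mean_t
  dv
}

#' @rdname decision_value_heuristic
#' @export
decision_value_drift <- function(data, beta_xA = 0, beta_xR = 0,
                                 beta_tA = 0, beta_xt = 0,
                                 standardizer = standardize_z) {
  at <- heuristic_attributes(data)
  if (any(at$t2 <= at$t1)) {
    rlang::abort("DRIFT requires delayed > immediate delay (implied growth rate undefined).")
  }
  if (any(at$x1 <= 0)) rlang::abort("DRIFT requires immediate amounts > 0.")
  f <- drift_factors(data, standardizer)
  beta_xA * f$xA + beta_xR * f$xR + beta_tA * f$tA + beta_xt * f$xt
}

# Raw and standardized DRIFT factor columns; standardization spans the rows
# of `data`, so callers group by participant-condition before calling.
drift_factors <- function(data, standardizer = standardize_z) {
  at <- heuristic_attributes(data)
  list(
    xA = standardizer(at$x2 - at$x1),
    xR = standardizer((at$x2 - at$x1) / at$x1),
    tA = standardizer(at$t2 - at$t1),
    xt = standardizer((at$x2 / at$x1)^(1 / (at$t2 - at$t1)) - 1)
  )
}

#' @rdname decision_value_heuristic
#' @export
decision_value_trade <- function(data, scaling1 = 1, scaling2 = 1,
                                 scaling3 = 1) {
  check_positive(scaling2, "scaling2")
  check_positive(scaling3, "scaling3")
  at <- heuristic_attributes(data)
  v <- function(x) log(1 + scaling2 * x) / scaling2
  w <- function(t) log(1 + scaling3 * t) / scaling3
  (v(at$x2) - v(at$x1)) - scaling1 * (w(at$t2) - w(at$t1))
}

#' Decision value of the delayed option under any model
#'
#' Dispatches to the model's decision rule: for SV models,
#' `SV(delayed) - SV(immediate)`; for heuristic models, the attribute-wise
#' comparison. For DRIFT, factors are standardized within
#' participant-condition groups when `data` carries `participant_id` /
#' `condition` columns, matching how the hierarchical fit treats them.
#'
#' @param data Tibble of trials with `amount_immediate`, `amount_delayed`,
#'   `delay_days` (optionally `delay_immediate`, `participant_id`,
#'   `condition`).
#' @param model Model identifier (see [dd_models()]).
#' @param params Named list of the model's free parameters, e.g.
#'   `list(k = 0.05, s = 1)` or `list(beta_xA = 0.2, ...)`.
#' @param standardizer DRIFT standardizer, see [decision_value_drift()].
#' @return Numeric vector of decision values, one per row of `data`.
#' @export
#' @examples
#' trials <- tibble::tibble(
#'   amount_immediate = c(20, 30), amount_delayed = 40, delay_days = 30
#' )
#' decision_value(trials, "hyp", list(k = 0.02))
decision_value <- function(data, model, params,
                           standardizer = standardize_z) {
  m <- match_model(model)
  cls <- dd_models()$class[match(m, dd_models()$model)]
  params <- params[setdiff(names(params), "error")]
  if (cls == "sv") {
    k <- params$k
    s <- if (is.null(params$s)) 1 else params$s
    t1 <- if ("delay_immediate" %in% names(data)) data$delay_immediate else 0
    sv_del <- subjective_value(data$amount_delayed, data$delay_days, m, k, s)
    sv_imm <- subjective_value(data$amount_immediate, t1, m, k, s)
    return(sv_del - sv_imm)
  }
  if (m == "itch") {
    return(rlang::exec(decision_value_itch, data, !!!params))
  }
  if (m == "trade") {
    return(rlang::exec(decision_value_trade, data, !!!params))
  }
  # drift: standardize within participant-condition when available
  keys <- intersect(c("participant_id", "condition"), names(data))
  if (length(keys) == 0) {
    return(rlang::exec(decision_value_drift, data,
                       !!!params, standardizer = standardizer))
  }
  grp <- interaction(data[keys], drop = TRUE)
  dv <- numeric(nrow(data))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    dv[idx] <- rlang::exec(decision_value_drift, data[idx, , drop = FALSE],
                           !!!params, standardizer = standardizer)
  }
  dv
}

#' Lapse-limited logistic choice rule
#'
#' Maps a decision value to the probability of choosing the delayed option via
#' the inverse logit, compressed into `[error, 1 - error]` by a lapse term:
#' `p = (1 - 2*error) * logit^{-1}(dv) + error`. The lapse captures choice
#' inconsistency: even an arbitrarily strong preference is expressed with
#' probability at most `1 - error`.
#'
#' @param decision_value Numeric vector; for SV models this is
#'   `SV(delayed) - SV(immediate)`.
#' @param error Lapse probability in `[0, 0.2]`.
#' @return Probabilities in `[error, 1 - error]`.
#' @export
#' @examples
#' choice_probability(0, 0.1) # 0.5
#' choice_probability(log(3), 0) # 0.75
choice_probability <- function(decision_value, error = 0) {
  if (any(error < 0) || any(error > 0.2)) {
    rlang::abort("`error` must lie in [0, 0.2].")
  }
  p <- (1 - 2 * error) * stats::plogis(decision_value) + error
  # guard against last-bit float excursions outside the lapse band
  pmin(pmax(p, error), 1 - error)
}

#' Bernoulli log likelihood of observed choices
#'
#' Sums `choice * log(p) + (1 - choice) * log(1 - p)` over trials, where `p`
#' is the lapse-limited choice probability of the delayed option under the
#' given model. Finite whenever `error > 0`.
#'
#' @inheritParams decision_value
#' @param params Named list of model parameters; may include `error`
#'   (otherwise supply it via `error`).
#' @param error Lapse probability; defaults to `params$error` or 0.
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(data, model, params, error = NULL,
                           standardizer = standardize_z) {
  if (nrow(data) == 0) rlang::abort("`data` has no trials.")
  if (!"choice" %in% names(data)) rlang::abort("`data` must have a `choice` column (0/1).")
  if (is.null(error)) error <- if (is.null(params$error)) 0 else params$error
  dv <- decision_value(data, model, params, standardizer = standardizer)
  p <- choice_probability(dv, error)
  sum(data$choice * log(p) + (1 - data$choice) * log1p(-p))
}
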