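#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' Tidy posterior summaries of a hierarchical fit
#'
#' One row per free parameter and level: posterior mean, SD, 95% HDI and
#' split-Rhat. Population-level rows have `participant_id = NA`.
#'
#' @param x A `dd_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dd_fit
#' @export
tidy.dd_fit <- function(x, ...) {
  x$draws |>
    dplyr::group_by(.data$parameter, .data$participant_id) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = stats::sd(.data$value),
      hdi_low = hdi(.data$value)[["lower"]],
      hdi_high = hdi(.data$value)[["upper"]],
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::select(x$rhat, "parameter", "participant_id", "rhat"),
      by = c("parameter", "participant_id")
    )
}

#' @rdname tidy.dd_fit
#' @method glance dd_fit
#' @export
glance.dd_fit <- function(x, ...) {
  w <- waic(x)
  tibble::tibble(
    model = x$model, condition = x$condition %||% NA_character_,
    n_participants = length(x$participants), n_trials = ncol(x$loglik),
    chains = x$config$chains, draws = x$config$draws,
    max_rhat = max(x$rhat$rhat), waic = w$waic, waic_se = w$se,
    p_waic = w$p_waic
  )
}

#' @method tidy dd_waic
#' @export
tidy.dd_waic <- function(x, ...) {
  tibble::tibble(waic = x$waic, se = x$se, p_waic = x$p_waic, n_obs = x$n_obs)
}

#' @method tidy dd_comparison
#' @export
tidy.dd_comparison <- function(x, ...) tibble::as_tibble(x)

#' @method tidy dd_recovery
#' @export
tidy.dd_recovery <- function(x, ...) x$stats

#' @method glance dd_recovery
#' @export
glance.dd_recovery <- function(x, ...) {
  k_row <- dplyr::filter(x$stats, .data$parameter == "k")
  tibble::tibble(
    model = x$model, n_participants = length(unique(x$pairs$participant_id)),
    r_k = if (nrow(k_row)) k_row$r else NA_real_
  )
}

#' @method tidy dd_contrast
#' @export
tidy.dd_contrast <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter,
    contrast = paste(x$conditions, collapse = " - "),
    mean = x$mean, hdi_low = x$hdi[["lower"]], hdi_high = x$hdi[["upper"]],
    excludes_zero = x$excludes_zero
  )
}
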