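#' Posterior densities of population-level parameters
#'
#' @param object A `dd_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dd_fit
#' @export
autoplot.dd_fit <- function(object, ...) {
  pop <- dplyr::filter(object$draws, is.na(.data$participant_id))
  ggplot2::ggplot(pop, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(
      title = paste0("Population-level posteriors (", object$model,
                     if (!is.null(object$condition))
                       paste0(", ", object$condition), ")"),
      x = "parameter value", y = "draw count"
    )
}

#' WAIC comparison plot
#'
#' WAIC per model (negative-log scale, lower is better) with +/- 1 SE bars.
#'
#' @param object A `dd_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dd_comparison
#' @export
autoplot.dd_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$waic, y = .data$model)) +
    ggplot2::geom_point(colour = "red") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$waic - .data$se, xmax = .data$waic + .data$se),
      height = 0.2, colour = "red"
    ) +
    ggplot2::labs(x = "WAIC (negative-log scale)", y = NULL)
}

#' Recovery scatter: generating vs recovered parameters
#'
#' @param object A `dd_recovery`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dd_recovery
#' @export
autoplot.dd_recovery <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "generating value", y = "posterior-mean estimate")
}

#' Posterior of the condition difference with its HDI
#'
#' @param object A `dd_contrast`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dd_contrast
#' @export
autoplot.dd_contrast <- function(object, ...) {
  df <- tibble::tibble(delta = object$delta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::annotate(
      "segment", x = object$hdi[["lower"]], xend = object$hdi[["upper"]],
      y = 0, yend = 0, linewidth = 2, colour = "red"
    ) +
    ggplot2::labs(
      x = sprintf("delta mu_%s (%s - %s)", object$parameter,
                  object$conditions[1], object$conditions[2]),
      y = "draw count"
    )
}

#' Indifference points against fitted discounting curves
#'
#' Mirrors the diagnostic view of titrated indifference points: per delay,
#' the block-wise empirical indifference points (orange) overlaid with the
#' subjective-value curve of the delayed reward implied by a participant's
#' posterior-mean parameters.
#'
#' @param data Trials of a single participant-condition.
#' @param fit Optional `dd_fit` containing that participant.
#' @param participant_id Which participant to draw from `fit`.
#' @param config A [staircase_config()].
#' @return A ggplot object.
#' @export
plot_indifference_points <- function(data, fit = NULL, participant_id = NULL,
                                     config = staircase_config()) {
  ips <- indifference_points(data, config)
  p <- ggplot2::ggplot(ips, ggplot2::aes(x = .data$delay_days,
                                         y = .data$indifference_point)) +
    ggplot2::geom_point(colour = "orange", size = 2) +
    ggplot2::labs(x = "delay (days)", y = "subjective value (units)") +
    ggplot2::coord_cartesian(ylim = c(0, config$delayed_amount))
  if (!is.null(fit)) {
    est <- participant_estimates(fit)
    if (!is.null(participant_id)) {
      est <- dplyr::filter(est, .data$participant_id == !!participant_id)
    }
    if (nrow(est) != 1) rlang::abort("Select exactly one participant from `fit`.")
    grid <- tibble::tibble(delay_days = seq(0, max(config$delays_days),
                                            length.out = 200))
    grid$sv <- subjective_value(
      config$delayed_amount, grid$delay_days, fit$model,
      k = est$k, s = if ("s" %in% names(est)) est$s else 1
    )
    p <- p + ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$delay_days, y = .data$sv),
      colour = "seagreen"
    )
  }
  p
}
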