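logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Widely applicable information criterion (WAIC)
#'
#' Computed on the negative-log scale (lower is better) from the pointwise
#' posterior log likelihood: per observation `i`,
#' `lppd_i = log mean_s exp(loglik[s, i])` and the effective-parameter
#' penalty `p_i = var_s(loglik[s, i])`; `WAIC = -sum(lppd_i - p_i)` with
#' standard error `sqrt(N) * sd` of the pointwise contributions.
#'
#' @param x A `dd_fit` or a draws-by-observations matrix of pointwise log
#'   likelihoods.
#' @param ... Unused.
#' @return List of class `dd_waic`: `waic`, `se`, `p_waic`, `n_obs`, and the
#'   `pointwise` tibble (`lppd`, `p`, `waic`).
#' @export
#' @examples
#' waic(matrix(log(0.5), nrow = 3, ncol = 1))$waic # -log(0.5)
waic <- function(x, ...) UseMethod("waic")

#' @rdname waic
#' @export
waic.matrix <- function(x, ...) {
  if (any(!is.finite(x))) {
    bad <- which(apply(x, 2, function(col) any(!is.finite(col))))
    rlang::abort(paste0("Non-finite log likelihood for observation(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  s <- nrow(x)
  lppd <- apply(x, 2, logsumexp) - log(s)
  p <- apply(x, 2, stats::var)
  pointwise <- tibble::tibble(lppd = lppd, p = p, waic = -(lppd - p))
  structure(
    list(
      waic = sum(pointwise$waic),
      se = sqrt(ncol(x)) * stats::sd(pointwise$waic),
      p_waic = sum(p), n_obs = ncol(x), pointwise = pointwise
    ),
    class = "dd_waic"
  )
}

#' @rdname waic
#' @export
waic.dd_fit <- function(x, ...) waic.matrix(x$loglik)

#' @export
print.dd_waic <- function(x, ...) {
  cat(sprintf("WAIC (negative-log scale): %.2f (SE %.2f), p_waic %.2f, n = %d\n",
              x$waic, x$se, x$p_waic, x$n_obs))
  invisible(x)
}

#' Rank fitted models by WAIC
#'
#' Compares fits of different models to the identical trials and ranks them
#' ascending by WAIC. The best model is flagged significantly better than the
#' runner-up when their WAIC difference exceeds twice the standard error of
#' the paired pointwise difference.
#'
#' @param fits A named list of `dd_fit` objects (or `dd_waic` objects with
#'   matching observation sets), fitted to the same data/condition.
#' @return Tibble of class `dd_comparison`: `model`, `waic`, `se`, `p_waic`,
#'   `rank`, `delta_to_best`, `se_delta`, `significant` (best-vs-runner-up
#'   flag on the best row; other rows say whether the best beats them by more
#'   than 2 SE of the pairwise difference).
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2) rlang::abort("Need at least 2 fitted models to compare.")
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) {
      if (inherits(f, "dd_fit")) f$model else "model"
    }, character(1))
  }
  ws <- lapply(fits, function(f) if (inherits(f, "dd_waic")) f else waic(f))
  n_obs <- vapply(ws, function(w) w$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1) {
    rlang::abort("Models were fitted to different observation sets.")
  }
  tbl <- tibble::tibble(
    model = names(ws),
    waic = unname(vapply(ws, function(w) w$waic, numeric(1))),
    se = unname(vapply(ws, function(w) w$se, numeric(1))),
    p_waic = unname(vapply(ws, function(w) w$p_waic, numeric(1)))
  )
  ord <- order(tbl$waic)
  tbl <- tbl[ord, ]
  ws <- ws[ord]
  tbl$rank <- seq_len(nrow(tbl))
  best_pw <- ws[[1]]$pointwise$waic
  tbl$delta_to_best <- tbl$waic - tbl$waic[1]
  tbl$se_delta <- unname(vapply(ws, function(w) {
    d <- w$pointwise$waic - best_pw
    sqrt(length(d)) * stats::sd(d)
  }, numeric(1)))
  # best row: is the best significantly better than the runner-up?
  sig <- tbl$delta_to_best > 2 * tbl$se_delta
  sig[1] <- nrow(tbl) >= 2 &&
    tbl$delta_to_best[2] > 2 * tbl$se_delta[2]
  tbl$significant <- sig
  class(tbl) <- c("dd_comparison", class(tbl))
  tbl
}
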