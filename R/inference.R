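#' Hyperprior specification for hierarchical fitting
#'
#' Every free parameter gets an independent population-level mean (`Mu`) and
#' standard deviation (`SD`), each uniformly distributed over a fixed range;
#' participant-level parameters are normal around `Mu` with spread `SD`,
#' truncated to the parameter's support. Defaults:
#'
#' | parameter | Mu range | SD range | start (Mu, SD) | support |
#' |---|---|---|---|---|
#' | `k` | `[e^-10, e^-2]` | `[0.01, 3]` | `(e^-2.5, 1)` | `(0, Inf)` |
#' | `s` | `(0, 4]` | `[0.01, 3]` | `(1, 1)` | `(0, Inf)` |
#' | `beta_*` | `[-1, 1]` | `(0, 1]` | `(0.5, 0.5)` | unbounded |
#' | `scaling*` | `[-1, 1]` | `(0, 1]` | `(0.5, 0.5)` | `(0, Inf)` |
#' | `error` | `(0, 0.2]` | `(0, 0.2]` | `(0.1, 0.1)` | `(0, 0.2)` |
#'
#' @return Tibble with columns `parameter`, `mu_lower`, `mu_upper`,
#'   `sd_lower`, `sd_upper`, `mu_start`, `sd_start`, `support_lower`,
#'   `support_upper`.
#' @export
dd_priors <- function() {
  weight <- function(p) tibble::tibble(
    parameter = p, mu_lower = -1, mu_upper = 1, sd_lower = 0, sd_upper = 1,
    mu_start = 0.5, sd_start = 0.5, support_lower = -Inf, support_upper = Inf
  )
  scaler <- function(p) dplyr::mutate(weight(p), support_lower = 0)
  dplyr::bind_rows(
    tibble::tibble(
      parameter = "k", mu_lower = exp(-10), mu_upper = exp(-2),
      sd_lower = 0.01, sd_upper = 3, mu_start = exp(-2.5), sd_start = 1,
      support_lower = 0, support_upper = Inf
    ),
    tibble::tibble(
      parameter = "s", mu_lower = 0, mu_upper = 4,
      sd_lower = 0.01, sd_upper = 3, mu_start = 1, sd_start = 1,
      support_lower = 0, support_upper = Inf
    ),
    weight(c("beta_xA", "beta_xR", "beta_tA", "beta_tR", "beta_xt")),
    scaler(c("scaling1", "scaling2", "scaling3")),
    tibble::tibble(
      parameter = "error", mu_lower = 0, mu_upper = 0.2,
      sd_lower = 0, sd_upper = 0.2, mu_start = 0.1, sd_start = 0.1,
      support_lower = 0, support_upper = 0.2
    )
  )
}

#' MCMC sampling configuration
#'
#' Full-scale defaults follow the documented analysis settings: 60,000
#' warm-up iterations and 1,500 retained draws. For routine testing and
#' examples a reduced configuration (e.g. `warmup = 2000, draws = 500`) is
#' adequate on clean synthetic cohorts. Warm-up is split between sampler
#' adaptation and burn-in.
#'
#' @param warmup Total warm-up iterations (adaptation + burn-in).
#' @param draws Retained posterior draws per chain.
#' @param chains Number of chains (>= 2 required for Rhat).
#' @param seed Integer seed; chain RNGs are derived from it deterministically.
#' @param adapt Adaptation iterations; default half of `warmup`, capped at
#'   2000.
#' @param thin Keep every `thin`-th post-warm-up iteration (default 10). The
#'   slice sampler moves one scalar at a time, so a raw iteration carries
#'   much less information than a gradient-based one; thinning makes the
#'   retained draws comparably informative. `draws` always counts retained
#'   draws.
#' @return List of class `dd_fit_config`.
#' @export
dd_fit_config <- function(warmup = 60000, draws = 1500, chains = 4,
                          seed = 1L, adapt = NULL, thin = 10L) {
  if (warmup < 2 || draws < 1 || chains < 1 || thin < 1) {
    rlang::abort("`warmup`, `draws`, `chains`, `thin` must be positive (warmup >= 2).")
  }
  if (is.null(adapt)) adapt <- min(2000, floor(warmup / 2))
  adapt <- min(adapt, warmup - 1)
  structure(
    list(warmup = warmup, draws = draws, chains = chains,
         seed = as.integer(seed), adapt = adapt, burnin = warmup - adapt,
         thin = as.integer(thin)),
    class = "dd_fit_config"
  )
}

# Truncation interval for the raw (standard-normal) deviate of a
# non-centered participant-level parameter, so that the transformed
# parameter mu + sd * raw stays inside (lower, upper).
raw_trunc_suffix <- function(p, lower, upper) {
  if (is.infinite(lower) && is.infinite(upper)) return("")
  bound <- function(b) {
    if (is.infinite(b)) "" else
      sprintf("(%s - mu_%s)/sd_%s", format(b, digits = 17), p, p)
  }
  paste0(" T(", bound(lower), ",", bound(upper), ")")
}

trunc_suffix <- function(lower, upper) {
  if (is.infinite(lower) && is.infinite(upper)) return("")
  lo <- if (is.infinite(lower)) "" else format(lower, digits = 17)
  hi <- if (is.infinite(upper)) "" else format(upper, digits = 17)
  paste0(" T(", lo, ",", hi, ")")
}

# The discount rate drives every choice directly and is strongly informed
# per participant: it mixes best centered. The modulators (s, lapse,
# attribute weights, scalings) are weakly informed and funnel when the
# population SD collapses: they mix best non-centered. The posterior is
# identical either way.
centered_parameters <- "k"

# JAGS expression for the decision value of trial i, as a function of the
# data vectors (x1, x2, D, t1, z* factors) and participant-level parameters.
dv_expression <- function(model) {
  sv <- function(expr_a, expr_d) paste0(
    gsub("A", "x2[i]", gsub("D", "D[i]", expr_d)), " - ",
    gsub("A", "x1[i]", gsub("D", "t1[i]", expr_a))
  )
  switch(model,
    exp = sv("A*exp(-k[pid[i]]*D)", "A*exp(-k[pid[i]]*D)"),
    exp_scaled = sv("A*exp(-pow(k[pid[i]]*D, s[pid[i]]))",
                    "A*exp(-pow(k[pid[i]]*D, s[pid[i]]))"),
    hyp = sv("A/(1 + k[pid[i]]*D)", "A/(1 + k[pid[i]]*D)"),
    hyp_delay_scaled = sv("A/(1 + k[pid[i]]*pow(D, s[pid[i]]))",
                          "A/(1 + k[pid[i]]*pow(D, s[pid[i]]))"),
    hyp_denom_scaled = sv("A/pow(1 + k[pid[i]]*D, s[pid[i]])",
                          "A/pow(1 + k[pid[i]]*D, s[pid[i]])"),
    itch = paste0(
      "beta_xA[pid[i]]*(x2[i]-x1[i]) + ",
      "beta_xR[pid[i]]*(x2[i]-x1[i])/((x2[i]+x1[i])/2) + ",
      "beta_tA[pid[i]]*(D[i]-t1[i]) + ",
      "beta_tR[pid[i]]*(D[i]-t1[i])/((D[i]+t1[i])/2)"
    ),
    drift = paste0(
      "beta_xA[pid[i]]*z_xA[i] + beta_xR[pid[i]]*z_xR[i] + ",
      "beta_tA[pid[i]]*z_tA[i] + beta_xt[pid[i]]*z_xt[i]"
    ),
    trade = paste0(
      "(log(1 + scaling2[pid[i]]*x2[i]) - log(1 + scaling2[pid[i]]*x1[i]))",
      "/scaling2[pid[i]] - scaling1[pid[i]]*",
      "(log(1 + scaling3[pid[i]]*D[i]) - log(1 + scaling3[pid[i]]*t1[i]))",
      "/scaling3[pid[i]]"
    )
  )
}

jags_model_string <- function(model, priors = dd_priors()) {
  model <- match_model(model)
  pars <- c(model_parameters(model), "error")
  pr <- priors[match(pars, priors$parameter), ]
  if (anyNA(pr$parameter)) rlang::abort("Priors missing for some parameters.")
  pop_lines <- character(0)
  part_lines <- character(0)
  for (r in seq_len(nrow(pr))) {
    p <- pr$parameter[r]
    pop_lines <- c(pop_lines,
      sprintf("  mu_%s ~ dunif(%.17g, %.17g)", p, pr$mu_lower[r], pr$mu_upper[r]),
      sprintf("  sd_%s ~ dunif(%.17g, %.17g)", p, pr$sd_lower[r], pr$sd_upper[r])
    )
    if (p %in% centered_parameters) {
      part_lines <- c(part_lines, sprintf(
        "    %s[j] ~ dnorm(mu_%s, pow(sd_%s, -2))%s",
        p, p, p, trunc_suffix(pr$support_lower[r], pr$support_upper[r])
      ))
    } else {
      # non-centered: participant value = mu + sd * raw, raw standard
      # normal truncated so the value respects the parameter's support
      part_lines <- c(part_lines, sprintf(
        "    %s_raw[j] ~ dnorm(0, 1)%s\n    %s[j] <- mu_%s + sd_%s * %s_raw[j]",
        p, raw_trunc_suffix(p, pr$support_lower[r], pr$support_upper[r]),
        p, p, p, p
      ))
    }
  }
  paste0(
    "model {\n",
    paste(pop_lines, collapse = "\n"), "\n",
    "  for (j in 1:J) {\n",
    paste(part_lines, collapse = "\n"), "\n",
    "  }\n",
    "  for (i in 1:N) {\n",
    "    dv[i] <- ", dv_expression(model), "\n",
    "    prob[i] <- (1 - 2*error[pid[i]]) * ilogit(dv[i]) + error[pid[i]]\n",
    "    y[i] ~ dbern(prob[i])\n",
    "    loglik[i] <- logdensity.bern(y[i], prob[i])\n",
    "  }\n",
    "}\n"
  )
}

#' Build the hierarchical choice model for one condition
#'
#' Assembles the model description (hierarchy, priors, likelihood) and the
#' data needed to sample it: population mean and SD per free parameter with
#' uniform hyperpriors, independent truncated-normal participant-level
#' parameters, and a Bernoulli likelihood through the lapse-limited logistic
#' choice rule. For DRIFT the four factors are standardized within each
#' participant's trials before entering the sampler.
#'
#' @param data Tibble of trials (choice CSV schema, see [read_choice_csv()]).
#' @param model Model identifier (see [dd_models()]).
#' @param condition Condition label to fit (`NULL` uses all rows, e.g. for
#'   single-condition data).
#' @param priors A [dd_priors()] tibble.
#' @return List of class `dd_model_spec`: `model_string` (JAGS), `data_list`,
#'   `participants` (id mapping), `parameters` (free parameter names),
#'   `n_population` / `n_participant_level` (free-parameter counts), `model`,
#'   `condition`, and the trial `data` in sampler order.
#' @export
build_model <- function(data, model = "exp_scaled", condition = NULL,
                        priors = dd_priors()) {
  model <- match_model(model)
  if (!is.null(condition)) {
    if (!condition %in% data$condition) {
      rlang::abort(paste0("Condition '", condition, "' absent from data."))
    }
    data <- dplyr::filter(data, .data$condition == !!condition)
  }
  if (nrow(data) == 0) rlang::abort("No trials to fit.")
  if (!"participant_id" %in% names(data)) data$participant_id <- 1L
  participants <- sort(unique(data$participant_id))
  pid <- match(data$participant_id, participants)
  t1 <- if ("delay_immediate" %in% names(data)) data$delay_immediate else
    rep(0, nrow(data))
  data_list <- list(
    J = length(participants), N = nrow(data), pid = pid,
    x1 = data$amount_immediate, x2 = data$amount_delayed,
    D = data$delay_days, t1 = t1, y = data$choice
  )
  if (model == "drift") {
    # the sampler sees only the standardized factors
    data_list[c("x1", "x2", "D", "t1")] <- NULL
    for (j in seq_along(participants)) {
      idx <- which(pid == j)
      f <- drift_factors(data[idx, , drop = FALSE])
      for (nm in names(f)) {
        key <- paste0("z_", nm)
        if (is.null(data_list[[key]])) data_list[[key]] <- numeric(nrow(data))
        data_list[[key]][idx] <- f[[nm]]
      }
    }
  }
  pars <- c(model_parameters(model), "error")
  structure(
    list(
      model_string = jags_model_string(model, priors),
      data_list = data_list, participants = participants,
      parameters = pars,
      n_population = 2L * length(pars),
      n_participant_level = length(participants) * length(pars),
      model = model, condition = condition, priors = priors, data = data
    ),
    class = "dd_model_spec"
  )
}

chain_inits <- function(spec, config) {
  pr <- spec$priors[match(spec$parameters, spec$priors$parameter), ]
  set.seed(config$seed)
  chain_seeds <- sample.int(2147483646L, config$chains)
  lapply(seq_len(config$chains), function(ch) {
    set.seed(chain_seeds[ch])
    init <- list()
    for (r in seq_len(nrow(pr))) {
      p <- pr$parameter[r]
      # Table-specified starting point, jittered per chain within the
      # hyperprior range and the parameter support.
      width <- min(pr$mu_upper[r] - pr$mu_lower[r], 1)
      mu0 <- pr$mu_start[r] + stats::runif(1, -0.05, 0.05) * width
      mu0 <- min(max(mu0, pr$mu_lower[r] + 1e-9 * (1 + abs(pr$mu_lower[r]))),
                 pr$mu_upper[r] - 1e-9)
      sd0 <- min(max(pr$sd_start[r], pr$sd_lower[r] + 1e-6), pr$sd_upper[r])
      init[[paste0("mu_", p)]] <- mu0
      init[[paste0("sd_", p)]] <- sd0
      if (p %in% centered_parameters) {
        start <- min(max(pr$mu_start[r], pr$support_lower[r] + 1e-6),
                     pr$support_upper[r] - 1e-6)
        init[[p]] <- rep(start, spec$data_list$J)
      } else {
        # raw deviates start at zero: participant values start on mu
        init[[paste0(p, "_raw")]] <- rep(0, spec$data_list$J)
      }
    }
    init$.RNG.name <- "base::Mersenne-Twister"
    init$.RNG.seed <- chain_seeds[ch]
    init
  })
}

#' Sample the hierarchical model
#'
#' Runs MCMC (adaptive Gibbs/slice sampling via JAGS) with the configured
#' warm-up and retained draws, monitoring every population- and
#' participant-level parameter and the pointwise log likelihood of every
#' trial. Chain starting points come from the prior table's starting column,
#' jittered per chain; runs are reproducible given `config$seed`.
#'
#' @param spec A [build_model()] specification.
#' @param config A [dd_fit_config()].
#' @return Object of class `dd_fit`: `draws` (long tibble: `chain`, `draw`,
#'   `parameter`, `participant_id` — `NA` for population-level — and
#'   `value`), `loglik` (matrix, total draws x trials, trial order matching
#'   `$data`), `rhat` (tibble), `model`, `condition`, `config`,
#'   `participants`, `parameters`, `data`.
#' @export
fit_model <- function(spec, config = dd_fit_config()) {
  if (!inherits(spec, "dd_model_spec")) rlang::abort("`spec` must come from build_model().")
  monitors <- c(
    paste0("mu_", spec$parameters), paste0("sd_", spec$parameters),
    spec$parameters, "loglik"
  )
  jm <- rjags::jags.model(
    textConnection(spec$model_string), data = spec$data_list,
    inits = chain_inits(spec, config), n.chains = config$chains,
    n.adapt = config$adapt, quiet = TRUE
  )
  if (config$burnin > 0) stats::update(jm, config$burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors,
                              n.iter = config$draws * config$thin,
                              thin = config$thin, progress.bar = "none")
  as_dd_fit(samp, spec, config)
}

as_dd_fit <- function(samp, spec, config) {
  mats <- lapply(samp, as.matrix)
  cols <- colnames(mats[[1]])
  ll_cols <- grepl("^loglik\\[", cols)
  loglik <- do.call(rbind, lapply(mats, function(m) m[, ll_cols, drop = FALSE]))
  ll_idx <- as.integer(sub("^loglik\\[(\\d+)\\]$", "\\1", cols[ll_cols]))
  loglik <- loglik[, order(ll_idx), drop = FALSE]
  dimnames(loglik) <- NULL
  if (any(!is.finite(loglik))) {
    rlang::abort("Non-finite pointwise log likelihood in posterior draws.")
  }

  par_cols <- cols[!ll_cols]
  base <- sub("\\[\\d+\\]$", "", par_cols)
  idx <- suppressWarnings(as.integer(sub("^.*\\[(\\d+)\\]$", "\\1", par_cols)))
  participant <- ifelse(is.na(idx), NA, spec$participants[idx])
  draws <- purrr::imap_dfr(mats, function(m, ch) {
    tibble::tibble(
      chain = as.integer(ch),
      draw = rep(seq_len(nrow(m)), times = length(par_cols)),
      parameter = rep(base, each = nrow(m)),
      participant_id = rep(participant, each = nrow(m)),
      value = as.vector(m[, par_cols, drop = FALSE])
    )
  })

  fit <- structure(
    list(
      draws = draws, loglik = loglik, model = spec$model,
      condition = spec$condition, config = config,
      participants = spec$participants, parameters = spec$parameters,
      data = spec$data, rhat = NULL
    ),
    class = "dd_fit"
  )
  fit$rhat <- rhat(fit)
  fit
}

#' Fit a hierarchical discounting model to choice data
#'
#' Convenience wrapper: [build_model()] then [fit_model()]. Fits one condition
#' at a time, mirroring how the sampler is informed about behaviour in a
#' single condition.
#'
#' @inheritParams build_model
#' @param config A [dd_fit_config()].
#' @return A `dd_fit` (see [fit_model()]).
#' @export
#' @examples
#' \donttest{
#' coh <- simulate_cohort(4, "exp", seed = 2)
#' fit <- fit_dd(coh$trials, "exp", condition = "food",
#'               config = dd_fit_config(warmup = 400, draws = 100, chains = 2))
#' glance(fit)
#' }
fit_dd <- function(data, model = "exp_scaled", condition = NULL,
                   priors = dd_priors(), config = dd_fit_config()) {
  fit_model(build_model(data, model, condition, priors), config)
}

#' @export
print.dd_fit <- function(x, ...) {
  cat("Hierarchical delay-discounting fit\n")
  cat("  model:", x$model,
      if (!is.null(x$condition)) paste0(" condition: ", x$condition), "\n")
  cat("  participants:", length(x$participants),
      " trials:", ncol(x$loglik), "\n")
  cat("  chains:", x$config$chains, " draws/chain:", x$config$draws,
      " warmup:", x$config$warmup, "\n")
  cat("  max Rhat:", format(max(x$rhat$rhat), digits = 4), "\n")
  invisible(x)
}

#' Rank-normalized split-Rhat convergence diagnostic
#'
#' Chains are split in half, draws are rank-normalized across all half-chains
#' (normal quantiles of fractional ranks), and the classic potential
#' scale-reduction factor is computed on the normalized draws. Values above
#' 1.1 indicate disagreement between chains. A parameter whose draws are all
#' identical has no between/within variance to compare and is reported as 1.
#'
#' @param x A `dd_fit`, or a draws matrix (iterations x chains).
#' @param ... Unused.
#' @return For a matrix, a scalar. For a `dd_fit`, a tibble with `parameter`,
#'   `participant_id`, `rhat` and `flagged` (`rhat > 1.1`).
#' @export
rhat <- function(x, ...) UseMethod("rhat")

#' @rdname rhat
#' @export
rhat.matrix <- function(x, ...) {
  if (ncol(x) < 2) rlang::abort("Rhat needs at least 2 chains.")
  n_half <- floor(nrow(x) / 2)
  if (n_half < 2) rlang::abort("Too few draws per chain to split.")
  halves <- cbind(x[seq_len(n_half), , drop = FALSE],
                  x[nrow(x) - n_half + seq_len(n_half), , drop = FALSE])
  if (max(halves) == min(halves)) return(1)
  z <- stats::qnorm((rank(halves) - 3 / 8) / (length(halves) + 1 / 4))
  z <- matrix(z, nrow = n_half)
  n <- nrow(z)
  w <- mean(apply(z, 2, stats::var))
  b <- n * stats::var(colMeans(z))
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' @rdname rhat
#' @export
rhat.dd_fit <- function(x, ...) {
  if (x$config$chains < 2) rlang::abort("Rhat needs at least 2 chains.")
  per_par <- x$draws |>
    dplyr::group_by(.data$parameter, .data$participant_id) |>
    dplyr::summarise(
      rhat = rhat.matrix(matrix(.data$value[order(.data$chain, .data$draw)],
                                ncol = x$config$chains)),
      .groups = "drop"
    )
  dplyr::mutate(per_par, flagged = .data$rhat > 1.1)
}

#' Persist and reload posterior samples
#'
#' Writes the parameter draws as long-format CSV (`chain`, `draw`,
#' `parameter`, `participant_id` with `POP` for population level, `value`),
#' the pointwise log likelihood as a companion `*_loglik.csv` (`chain`,
#' `draw`, `trial`, `value`), and a JSON metadata sidecar (`*_meta.json`)
#' recording model, condition, configuration and participant ids.
#'
#' @param fit A `dd_fit`.
#' @param path Path of the main CSV; companions derive from it.
#' @return `write_fit_csv` returns `path` invisibly; `read_fit_csv` returns a
#'   `dd_fit` (without the original trial data).
#' @export
write_fit_csv <- function(fit, path) {
  stem <- sub("\\.csv$", "", path)
  draws <- dplyr::mutate(
    fit$draws,
    participant_id = ifelse(is.na(.data$participant_id), "POP",
                            as.character(.data$participant_id))
  )
  readr::write_csv(draws, path)
  s <- nrow(fit$loglik)
  ll <- tibble::tibble(
    chain = rep(rep(seq_len(fit$config$chains), each = fit$config$draws),
                times = ncol(fit$loglik)),
    draw = rep(rep(seq_len(fit$config$draws), fit$config$chains),
               times = ncol(fit$loglik)),
    trial = rep(seq_len(ncol(fit$loglik)), each = s),
    value = as.vector(fit$loglik)
  )
  readr::write_csv(ll, paste0(stem, "_loglik.csv"))
  jsonlite::write_json(
    list(
      model = fit$model, condition = fit$condition,
      config = unclass(fit$config), participants = fit$participants,
      parameters = fit$parameters
    ),
    paste0(stem, "_meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_fit_csv
#' @export
read_fit_csv <- function(path) {
  stem <- sub("\\.csv$", "", path)
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  draws <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(participant_id = "c"))
  draws$participant_id <- suppressWarnings(
    ifelse(draws$participant_id == "POP", NA, draws$participant_id)
  )
  if (all(is.na(suppressWarnings(as.numeric(stats::na.omit(draws$participant_id)))) == FALSE)) {
    draws$participant_id <- as.numeric(draws$participant_id)
  }
  ll <- readr::read_csv(paste0(stem, "_loglik.csv"), show_col_types = FALSE)
  ll <- dplyr::arrange(ll, .data$trial, .data$chain, .data$draw)
  loglik <- matrix(ll$value, ncol = max(ll$trial))
  config <- do.call(dd_fit_config, meta$config[
    c("warmup", "draws", "chains", "seed", "adapt", "thin")
  ])
  fit <- structure(
    list(
      draws = draws, loglik = loglik, model = meta$model,
      condition = meta$condition, config = config,
      participants = meta$participants, parameters = meta$parameters,
      data = NULL, rhat = NULL
    ),
    class = "dd_fit"
  )
  fit$rhat <- rhat(fit)
  fit
}
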