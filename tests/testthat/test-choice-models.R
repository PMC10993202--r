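sv_models <- c("exp", "exp_scaled", "hyp", "hyp_delay_scaled",
               "hyp_denom_scaled")

test_that("subjective value matches closed forms and the zero-delay identity", {
  for (m in sv_models) {
    expect_equal(subjective_value(40, 0, m, k = 0.3, s = 0.7), 40,
                 info = m)
  }
  expect_equal(subjective_value(40, 10, "hyp", k = 0.1), 20)
  expect_equal(subjective_value(40, 100, "exp_scaled", k = 0.04, s = 0.5),
               40 * exp(-2), tolerance = 1e-12)
  expect_equal(subjective_value(40, 10, "hyp_denom_scaled", k = 0.1, s = 2),
               10)
  expect_error(subjective_value(40, 10, "hyp", k = -1), "k")
  expect_error(subjective_value(40, 10, "exp_scaled", k = 0.1, s = 0), "s")
})

test_that("SV decreases in delay and in k, and stays within (0, A]", {
  delays <- c(0, 1, 2, 7, 14, 30, 90, 180, 365)
  ks <- c(0.001, 0.01, 0.05, 0.2, 1)
  for (m in sv_models) {
    for (k in ks) {
      for (s in c(0.5, 1, 2)) {
        sv <- subjective_value(40, delays, m, k, s)
        # strict decrease wherever the value is still representable; the
        # steepest exponential settings underflow to 0 at long delays
        rep_ok <- sv > 1e-290
        expect_true(all(diff(sv[rep_ok]) < 0), info = paste(m, k, s))
        expect_true(all(sv >= 0 & sv <= 40), info = paste(m, k, s))
        expect_gt(sv[1], 0)
      }
    }
    for (d in delays[-1]) {
      sv_k <- subjective_value(40, d, m, ks, s = 0.8)
      expect_true(all(diff(sv_k) < 0), info = paste(m, d))
    }
  }
})

test_that("scaled models with s = 1 reduce to their unscaled counterparts", {
  grid <- expand.grid(
    delay = c(0, 1, 5, 14, 30, 90, 180, 365),
    k = exp(seq(log(1e-4), log(1), length.out = 25))
  )
  pairs <- list(
    c("exp_scaled", "exp"),
    c("hyp_delay_scaled", "hyp"),
    c("hyp_denom_scaled", "hyp")
  )
  for (pr in pairs) {
    scaled <- subjective_value(40, grid$delay, pr[1], grid$k, s = 1)
    plain <- subjective_value(40, grid$delay, pr[2], grid$k)
    expect_equal(scaled, plain, tolerance = 1e-14, info = pr[1])
  }
})

test_that("ITCH decision value follows the four weighted comparisons", {
  tr <- trial_row(20, 40, 14)
  expect_equal(decision_value_itch(tr), 0)
  expect_equal(decision_value_itch(tr, beta_xA = 1), 20)
  expect_equal(decision_value_itch(tr, beta_xR = 1), 20 / 30)
  expect_equal(decision_value_itch(tr, beta_tA = 1), 14)
  expect_equal(decision_value_itch(tr, beta_tR = 1), 14 / 7)
  mixed <- decision_value_itch(tr, beta_xA = 0.1, beta_xR = -0.5,
                               beta_tA = 0.02, beta_tR = -0.3)
  expect_equal(mixed, 0.1 * 20 - 0.5 * 20 / 30 + 0.02 * 14 - 0.3 * 2)
  expect_error(
    decision_value_itch(trial_row(20, 40, 0), beta_tR = 1),
    "[Dd]egenerate"
  )
})

test_that("DRIFT uses the implied per-period growth rate and standardized factors", {
  tr <- trial_row(20, 40, 14)
  expect_equal(decision_value_drift(tr), 0)
  expect_equal(
    decision_value_drift(tr, beta_xt = 1, standardizer = identity),
    2^(1 / 14) - 1
  )
  expect_equal(
    decision_value_drift(tr, beta_xA = 1, standardizer = identity), 20
  )
  # zero-variance factor standardizes to zero
  same_gap <- trial_row(c(10, 20, 30), c(30, 40, 50), c(2, 14, 30))
  expect_equal(
    decision_value_drift(same_gap, beta_xA = 1),
    rep(0, 3)
  )
  expect_error(decision_value_drift(trial_row(20, 40, 0), beta_xt = 1),
               "delay")
})

test_that("DRIFT standardization happens within participant-condition groups", {
  d <- dplyr::bind_rows(
    dplyr::mutate(trial_row(c(10, 20), 40, c(2, 14)), participant_id = 1),
    dplyr::mutate(trial_row(c(5, 35), 40, c(30, 90)), participant_id = 2)
  )
  dv <- decision_value(d, "drift", list(beta_xA = 1))
  by_hand <- c(standardize_z(c(30, 20)), standardize_z(c(35, 5)))
  expect_equal(dv, by_hand)
})

test_that("TRADE log-scales amounts and delays with the stated sign", {
  same <- trial_row(40, 40, 14, t1 = 14)
  expect_equal(decision_value_trade(same), 0)
  near_identity <- decision_value_trade(
    trial_row(20, 40, 14), scaling1 = 1, scaling2 = 1e-9, scaling3 = 1
  )
  expect_equal(near_identity, 20 - log(15), tolerance = 1e-6)
  expect_equal(
    decision_value_trade(trial_row(20, 40, 200), scaling1 = 0, scaling2 = 1),
    log(41) - log(21)
  )
  # longer delay penalizes the delayed option
  dv <- decision_value_trade(trial_row(20, 40, c(2, 365)))
  expect_lt(dv[2], dv[1])
  expect_error(decision_value_trade(trial_row(20, 40, 14), scaling2 = -1),
               "scaling2")
})

test_that("choice rule is a lapse-limited inverse logit", {
  expect_equal(choice_probability(0, 0), 0.5)
  expect_equal(choice_probability(log(3), 0), 0.75)
  expect_equal(choice_probability(700, 0.1), 0.9)
  expect_equal(choice_probability(-700, 0.1), 0.1)
  expect_error(choice_probability(0, 0.3), "error")

  set.seed(11)
  dv <- stats::rcauchy(1e4) * 100 # heavy tails, exercises saturation
  for (e in c(0, 0.05, 0.2)) {
    p <- choice_probability(dv, e)
    expect_true(all(p >= e & p <= 1 - e))
    # lapse symmetry
    expect_equal(p + choice_probability(-dv, e), rep(1, length(dv)),
                 tolerance = 1e-12)
  }
})

test_that("log likelihood equals the log of the product of trial probabilities", {
  one <- dplyr::mutate(trial_row(40, 40, 14), choice = 1)
  expect_equal(log_likelihood(one, "itch", list()), log(0.5))

  # additivity over identical trials
  five <- dplyr::bind_rows(replicate(5, one, simplify = FALSE))
  expect_equal(log_likelihood(five, "itch", list()), 5 * log(0.5))

  # hand-set decision values via itch with beta_xA = 1: dv = x2 - x1
  d <- trial_row(c(39, 35, 20, 10, 42), 40, c(2, 14, 30, 90, 180))
  d$choice <- c(1, 0, 1, 1, 0)
  params <- list(beta_xA = 1, error = 0.1)
  p <- choice_probability(d$amount_delayed - d$amount_immediate, 0.1)
  oracle <- log(prod(ifelse(d$choice == 1, p, 1 - p)))
  expect_equal(log_likelihood(d, "itch", params), oracle)

  expect_error(log_likelihood(d[0, ], "itch", params), "trials")
})

test_that("unknown models are rejected everywhere", {
  expect_error(subjective_value(40, 1, "quadratic", 0.1), "Unknown model")
  expect_error(decision_value(trial_row(20, 40, 14), "nope", list()),
               "Unknown model")
})
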