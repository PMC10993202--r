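test_that("next_offer applies the shrinking titration steps", {
  expect_equal(next_offer(20, 1, 1), 30)
  expect_equal(next_offer(20, 0, 1), 10)
  expect_equal(next_offer(37.5, 1, 4), 38.5)
  expect_equal(next_offer(30, "immediate", 2), 25)
  expect_error(next_offer(20, 1, 5), "trial_index")
  expect_error(next_offer(20, 1, 0), "trial_index")
})

test_that("all 32 choice paths stay on the titration grid and match the oracle", {
  paths <- expand.grid(rep(list(0:1), 5))
  finals <- numeric(nrow(paths))
  for (i in seq_len(nrow(paths))) {
    ch <- as.integer(paths[i, ])
    oracle <- staircase_path_oracle(ch)
    offer <- 20
    for (t in 1:4) {
      expect_equal(offer, oracle[t])
      offer <- next_offer(offer, ch[t], t)
    }
    expect_equal(offer, oracle[5])
    finals[i] <- offer
    expect_true(all(oracle >= 1.5 & oracle <= 38.5))
    expect_true(all(oracle * 2 == round(oracle * 2))) # 0.5-unit grid
  }
  expect_equal(max(finals), 38.5)
  expect_equal(min(finals), 1.5)
})

test_that("thresholded responders hit the deterministic staircase limits", {
  # negligible discounting: delayed always preferred
  blk <- simulate_block(365, "exp", list(k = 1e-9), error = 0,
                        responder = "thresholded")
  expect_equal(blk$amount_immediate, c(20, 30, 35, 37.5, 38.5))
  expect_equal(blk$choice, rep(1L, 5))
  # extreme discounting: immediate always preferred
  blk2 <- simulate_block(2, "exp", list(k = 100), error = 0,
                         responder = "thresholded")
  expect_equal(blk2$amount_immediate, c(20, 10, 5, 2.5, 1.5))
  expect_equal(blk2$choice, rep(0L, 5))
  # config invariants
  set.seed(3)
  any_blk <- simulate_block(30, "hyp", list(k = 0.05), error = 0.1)
  expect_equal(nrow(any_blk), 5)
  expect_true(all(any_blk$amount_delayed == 40))
})

test_that("simulated cohorts keep the task bookkeeping", {
  coh <- local_cohort(3, "exp", seed = 42)
  trials <- coh$trials
  expect_equal(nrow(trials), 3 * 2 * 60)
  counts <- dplyr::count(trials, participant_id, run)
  expect_true(all(counts$n == 30))
  # six distinct delays per run, each in exactly one block
  per_run <- trials |>
    dplyr::distinct(participant_id, run, block, delay_days) |>
    dplyr::count(participant_id, run)
  expect_true(all(per_run$n == 6))
  delay_sets <- trials |>
    dplyr::group_by(participant_id, run) |>
    dplyr::summarise(ok = setequal(unique(delay_days),
                                   c(2, 14, 30, 90, 180, 365)),
                     .groups = "drop")
  expect_true(all(delay_sets$ok))
  # runs alternate food-money-food-money
  run_cond <- dplyr::distinct(trials, run, condition)
  expect_equal(run_cond$condition[order(run_cond$run)],
               c("food", "money", "food", "money"))
  expect_true(all(trials$amount_delayed == 40))
  first_trials <- dplyr::filter(trials, trial == 1)
  expect_true(all(first_trials$amount_immediate == 20))
  # offers never leave the reachable titration set
  expect_true(all(trials$amount_immediate >= 1.5 &
                  trials$amount_immediate <= 38.5))
})

test_that("cohorts are reproducible and degenerate SDs pin the parameters", {
  a <- simulate_cohort(2, "hyp", seed = 7)
  b <- simulate_cohort(2, "hyp", seed = 7)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth, b$truth)

  mean_set <- c(k = 0.04, error = 0.08)
  one <- simulate_cohort(1, "exp", pop_mean = mean_set,
                         pop_sd = c(k = 0, error = 0), seed = 9)
  expect_equal(
    dplyr::arrange(one$truth, condition, parameter)$value,
    rep(c(0.08, 0.04), 2) # error, k per condition
  )
  expect_error(
    simulate_cohort(2, "exp", pop_sd = c(k = -1, error = 0)), "SD"
  )
})

test_that("indifference points are the hypothetical sixth offer", {
  mk_block <- function(choices) {
    tibble::tibble(
      participant_id = 1, condition = "food", run = 1, block = 1,
      trial = 1:5, delay_days = 30,
      amount_immediate = staircase_path_oracle(choices),
      amount_delayed = 40, choice = choices
    )
  }
  expect_equal(
    indifference_points(mk_block(rep(1L, 5)))$indifference_point, 39.5
  )
  expect_equal(
    indifference_points(mk_block(rep(0L, 5)))$indifference_point, 0.5
  )
  alternating <- mk_block(c(1L, 0L, 1L, 0L, 1L))
  expect_equal(alternating$amount_immediate, c(20, 30, 25, 27.5, 26.5))
  expect_equal(indifference_points(alternating)$indifference_point, 27.5)
  expect_error(indifference_points(mk_block(rep(1L, 5))[1:3, ]),
               "Incomplete block")
})

test_that("titration converges to the generative subjective value", {
  # thresholded responder, no lapses: the estimate lands within the final
  # step (1 unit) of the true SV at every delay
  k <- 0.035
  for (d in c(2, 14, 30, 90, 180, 365)) {
    blk <- simulate_block(d, "exp", list(k = k), error = 0,
                          responder = "thresholded")
    blk$participant_id <- 1
    ip <- indifference_points(blk)$indifference_point
    truth <- subjective_value(40, d, "exp", k)
    expect_lte(abs(ip - truth), 1)
  }
})

test_that("qc filter excludes one-sided and slow responders at the stated bounds", {
  mk_participant <- function(id, n_delayed, n = 120, rt = NULL) {
    out <- tibble::tibble(
      participant_id = id,
      choice = c(rep(1L, n_delayed), rep(0L, n - n_delayed))
    )
    if (!is.null(rt)) out$rt_s <- rt
    out
  }
  d <- dplyr::bind_rows(
    mk_participant(1, 110), # 91.7% same -> excluded
    mk_participant(2, 108), # exactly 90% -> retained
    mk_participant(3, 60) # 50/50 -> retained
  )
  res <- qc_filter(d)
  expect_equal(res$exclusions$participant_id, 1)
  expect_equal(res$exclusions$reason, "one_sided")
  expect_setequal(unique(res$retained$participant_id), c(2, 3))

  # one-sided in the immediate direction is excluded too
  res2 <- qc_filter(mk_participant(9, 5))
  expect_equal(res2$exclusions$participant_id, 9)

  slow <- mk_participant(4, 60, rt = c(rep(13, 61), rep(2, 59)))
  fine <- mk_participant(5, 60, rt = c(rep(13, 60), rep(2, 60)))
  res3 <- qc_filter(dplyr::bind_rows(slow, fine))
  expect_equal(res3$exclusions$participant_id, 4)
  expect_equal(res3$exclusions$reason, "slow_rt")
})

test_that("choice CSVs round-trip and schema violations are reported", {
  coh <- local_cohort(3, "exp", seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_choice_csv(coh$trials, path)
  back <- read_choice_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(coh$trials))

  broken <- dplyr::rename(coh$trials, amt = amount_immediate)
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(broken, path2)
  expect_error(read_choice_csv(path2), "amount_immediate")

  bad_choice <- dplyr::mutate(coh$trials,
                              choice = replace(choice, 3, 2L))
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad_choice, path3)
  expect_error(read_choice_csv(path3), "rows: 3")
})
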