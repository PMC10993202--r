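# Shared builders for small in-code fixtures.

# One-row trial table for decision-value checks.
trial_row <- function(x1, x2, t2, t1 = 0) {
  tibble::tibble(
    amount_immediate = x1, amount_delayed = x2,
    delay_days = t2, delay_immediate = t1
  )
}

# Reduced MCMC settings for unit tests (not the acceptance settings).
tiny_fit_config <- function(seed = 1L, chains = 2L) {
  dd_fit_config(warmup = 600, draws = 200, chains = chains, seed = seed,
                thin = 2)
}

# Deterministic staircase path: apply every choice in `choices` (0/1) and
# return the offers seen on trials 1..5. Independent re-implementation of the
# titration arithmetic used as the oracle for next_offer().
staircase_path_oracle <- function(choices,
                                  start = 20, steps = c(10, 5, 2.5, 1)) {
  offers <- numeric(length(choices))
  offers[1] <- start
  for (t in seq_len(length(choices) - 1)) {
    offers[t + 1] <- offers[t] + ifelse(choices[t] == 1, steps[t], -steps[t])
  }
  offers
}

# Cohort cache so expensive fits are shared across tests in a file.
local_cohort <- local({
  cache <- new.env()
  function(n, model = "exp", seed = 42, ...) {
    key <- paste(n, model, seed, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_cohort(n, model, seed = seed, ...)
    }
    cache[[key]]
  }
})
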