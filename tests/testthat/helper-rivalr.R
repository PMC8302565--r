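# small parameter sets and hand-built fixtures used across test files

small_params <- function(...) {
  rivalry_params(n_subjects = 3, n_repetitions = 1, trial_length_s = 60, ...)
}

# a single-trial phase table with explicit durations, alternating percepts
make_trial <- function(durations, first = "SIM", subject = 1, delta_i_db = 2,
                       repetition = 1, censored_last = FALSE) {
  k <- length(durations)
  percepts <- rep(c(first, setdiff(c("SIM", "AM"), first)), length.out = k)
  tibble::tibble(
    subject = subject, delta_i_db = delta_i_db, repetition = repetition,
    percept = percepts,
    onset_s = cumsum(c(0, durations[-k])),
    duration_s = durations,
    censored = c(rep(FALSE, k - 1), censored_last)
  )
}

# gamma durations as a phase table for the distribution/scaling tests
gamma_phase_table <- function(n, shape, mean, delta_i_db, subject = 1) {
  make_trial(stats::rgamma(n, shape = shape, scale = mean / shape),
             delta_i_db = delta_i_db, subject = subject)
}
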