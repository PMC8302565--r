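test_that("phases are maximal single-key runs; both-key and no-key samples report nothing", {
  tr <- tibble::tibble(
    left_key = c(rep(1L, 1000), rep(0L, 1000)),
    right_key = c(rep(0L, 1000), rep(1L, 1000))
  )
  ph <- extract_phases(tr, sample_rate_hz = 100)
  expect_equal(ph$percept, c("SIM", "AM"))
  expect_equal(ph$duration_s, c(10, 10))
  expect_equal(ph$onset_s, c(0, 10))

  both <- tibble::tibble(left_key = rep(1L, 500), right_key = rep(1L, 500))
  expect_equal(nrow(extract_phases(both, 100)), 0)

  bad <- tibble::tibble(left_key = c(0L, 2L), right_key = c(0L, 0L))
  expect_error(extract_phases(bad, 100), "binary")
})

test_that("short unreported gaps are merged within a phase, long ones split it", {
  key <- function(spans) {
    # spans: list of c(value, n_samples)
    unlist(lapply(spans, function(s) rep(s[1], s[2])))
  }
  l <- key(list(c(1, 300), c(0, 20), c(1, 300), c(0, 80), c(1, 100)))
  tr <- tibble::tibble(left_key = as.integer(l), right_key = 0L)
  ph <- extract_phases(tr, 100, merge_tol_s = 0.5)
  # 0.2 s gap merged (duration spans it), 0.8 s gap splits
  expect_equal(nrow(ph), 2)
  expect_equal(ph$duration_s[1], 6.2)
  expect_equal(ph$duration_s[2], 1.0)
  # reported + unreported time partitions the trace
  expect_equal(sum(ph$duration_s) + 0.8, nrow(tr) / 100)
})

test_that("exclusion flags non-alternating trials and out-of-bounds means", {
  lone <- make_trial(180, censored_last = TRUE)
  flags <- trial_exclusions(lone)
  expect_true(flags$excluded)
  expect_equal(flags$reason, "no_alternation")

  fast <- make_trial(rep(3, 20)) # both percepts average 3 s
  expect_equal(trial_exclusions(fast)$reason, "mean_below_floor")

  slow <- make_trial(c(160, 10, 170), subject = 2)
  expect_equal(trial_exclusions(slow)$reason, "mean_above_ceiling")

  ok <- make_trial(c(10, 20, 12, 18), subject = 3)
  expect_false(trial_exclusions(ok)$excluded)

  expect_error(trial_exclusions(ok, min_mean_s = 150, max_mean_s = 4), "smaller")
})

test_that("apply_exclusion partitions trials, is idempotent and counts per condition", {
  ph <- dplyr::bind_rows(
    make_trial(c(10, 20, 12, 18), subject = 1, delta_i_db = 2),
    make_trial(180, subject = 2, delta_i_db = 2, censored_last = TRUE),
    make_trial(rep(2, 30), subject = 3, delta_i_db = 6),
    make_trial(c(15, 25, 20), subject = 4, delta_i_db = 6)
  )
  kept <- apply_exclusion(ph)
  rep <- exclusion_report(kept)
  expect_equal(rep$n_total, 4)
  expect_equal(rep$n_excluded, 2)
  expect_equal(sort(unique(kept$subject)), c(1, 4))
  per <- rep$per_condition
  expect_equal(per$n_excluded[per$delta_i_db == 2], 1)
  expect_equal(per$n_excluded[per$delta_i_db == 6], 1)
  # idempotent: re-applying to the kept set excludes nothing
  again <- apply_exclusion(kept)
  expect_equal(exclusion_report(again)$n_excluded, 0)
  expect_equal(as.data.frame(again), as.data.frame(kept), ignore_attr = TRUE)
})

test_that("the across-percept interpretation never excludes more than per-percept", {
  p <- small_params()
  ph <- generate_dataset(p, seed = 17)
  n_per <- exclusion_report(apply_exclusion(ph, scheme = "per_percept"))$n_excluded
  n_across <- exclusion_report(apply_exclusion(ph, scheme = "across_percept"))$n_excluded
  expect_lte(n_across, n_per)
})

test_that("trial summaries follow the stated arithmetic", {
  ph <- make_trial(c(10, 20, 30))
  ts <- trial_summary(ph)
  expect_equal(ts$mean_dur_sim, 20)
  expect_equal(ts$mean_dur_am, 20)
  expect_equal(ts$prop_sim, 2 / 3)
  expect_equal(ts$prop_sim + ts$prop_am, 1)
  expect_equal(ts$alternation_rate, 2 / 60 * 60) # 2 switches in a minute
  expect_equal(ts$n_phases, 3L)

  single <- make_trial(30)
  expect_equal(trial_summary(single)$alternation_rate, 0)
  expect_error(trial_summary(make_trial(10)[0, ]), "zero phases")
})

test_that("summaries are invariant to a uniform time shift of onsets", {
  ph <- make_trial(c(12, 18, 9, 21))
  shifted <- dplyr::mutate(ph, onset_s = onset_s + 37)
  expect_equal(trial_summary(ph), trial_summary(shifted))
})

test_that("censored phases are excluded from means but kept in proportions", {
  ph <- make_trial(c(10, 20, 40), censored_last = TRUE)
  ts <- trial_summary(ph)
  expect_equal(ts$mean_dur_sim, 10) # the 40 s censored SIM phase is dropped
  expect_equal(ts$prop_sim, 50 / 70) # but its time still counts
  ts_all <- trial_summary(ph, drop_censored = FALSE)
  expect_equal(ts_all$mean_dur_sim, 25)
})

test_that("rebalancing fills every cell to the target from its own support", {
  ts <- dplyr::bind_rows(
    trial_summary(make_trial(c(10, 20, 12, 18), subject = 1, delta_i_db = 2)),
    trial_summary(make_trial(c(30, 8, 26), subject = 2, delta_i_db = 2)),
    trial_summary(make_trial(c(14, 16, 15), subject = 1, delta_i_db = 4))
  )
  rb <- rebalance(ts, target_n = 45, seed = 3)
  cells <- dplyr::count(rb, delta_i_db, percept)
  expect_true(all(cells$n == 45))
  # no invented values: resampled rows live in the observed support
  obs <- rb[rb$source == "observed", ]
  res <- rb[rb$source == "resampled", ]
  for (cell in split(res, interaction(res$delta_i_db, res$percept))) {
    if (nrow(cell) == 0) next
    src <- obs[obs$delta_i_db == cell$delta_i_db[1] &
                 obs$percept == cell$percept[1], ]
    expect_true(all(cell$mean_dur_s %in% src$mean_dur_s))
  }
  # cells at or above the target are returned unchanged
  at_target <- rebalance(ts, target_n = 1, seed = 3)
  expect_true(all(at_target$source == "observed"))
  # single-value cell: target copies of that value
  one <- trial_summary(make_trial(c(10, 20), subject = 1, delta_i_db = 1))
  rb1 <- rebalance(one, target_n = 45, seed = 1)
  expect_equal(sum(rb1$mean_dur_s[rb1$percept == "SIM"] == 10), 45)
})

test_that("rebalancing with a fixed seed is reproducible and empty cells error", {
  ts <- trial_summary(make_trial(c(10, 20, 12), subject = 1, delta_i_db = 2))
  expect_identical(rebalance(ts, 45, seed = 5), rebalance(ts, 45, seed = 5))
  lop <- make_trial(c(100, 2, 90), subject = 1, delta_i_db = 2)
  only_sim <- lop[lop$percept == "SIM", ]
  expect_error(rebalance(trial_summary(only_sim), 45), "cell")
})

test_that("subject means pool durations across repetitions, not trial means", {
  ph <- dplyr::bind_rows(
    make_trial(c(10, 5, 20), subject = 1, delta_i_db = 2, repetition = 1),
    make_trial(c(30, 5), subject = 1, delta_i_db = 2, repetition = 2)
  )
  sm <- subject_condition_means(ph)
  expect_equal(sm$mean_duration_s[sm$percept == "SIM"], 20) # (10+20+30)/3
  # idempotence: identical trials give the trial mean
  ph2 <- dplyr::bind_rows(
    make_trial(c(10, 5, 20), subject = 1, delta_i_db = 2, repetition = 1),
    make_trial(c(10, 5, 20), subject = 1, delta_i_db = 2, repetition = 2)
  )
  sm2 <- subject_condition_means(ph2)
  expect_equal(sm2$mean_duration_s[sm2$percept == "SIM"], 15)

  # a one-percept cell yields a missing-value row with a warning
  lone <- make_trial(c(12, 14), subject = 2, delta_i_db = 4)
  lone <- lone[lone$percept == "SIM", ]
  expect_warning(sm3 <- subject_condition_means(dplyr::bind_rows(ph, lone)),
                 "missing")
  expect_true(any(is.na(sm3$mean_duration_s)))
})
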