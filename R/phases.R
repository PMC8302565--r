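# trial identity columns present in a phase table (any subset may be absent
# when working with a single trial)
trial_keys <- function(df) {
  intersect(c("subject", "delta_i_db", "repetition"), names(df))
}

assert_phase_table <- function(df) {
  need <- c("percept", "onset_s", "duration_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("phase table is missing column(s): ",
                 paste(miss, collapse = ", "), "."))
  }
  if (!all(df$percept %in% c("SIM", "AM"))) {
    abort("`percept` must be \"SIM\" or \"AM\".")
  }
  invisible(df)
}

#' Parse a keypress trace into perceptual phases
#'
#' A phase is a maximal run of samples during which exactly one key is
#' held; samples with no key or both keys held are unreported time and
#' belong to no phase. The left key reports SIM, the right key AM.
#' Consecutive same-percept runs separated only by unreported time
#' shorter than `merge_tol_s` are merged into one phase (keypress
#' re-grips should not split a phase); the merged duration spans the
#' gap. A phase still held at the end of the trace is flagged censored.
#'
#' @param trace Tibble with binary `left_key`, `right_key` columns and
#'   either a `time_s` column or an explicit `sample_rate_hz`.
#' @param sample_rate_hz Sampling rate; inferred from `time_s` if absent.
#' @param merge_tol_s Maximal unreported gap (seconds) absorbed inside
#'   a phase.
#' @return Tibble with `percept`, `onset_s`, `duration_s`, `censored`.
#' @examples
#' tr <- tibble::tibble(
#'   left_key = rep(c(1L, 0L), each = 1000),
#'   right_key = rep(c(0L, 1L), each = 1000)
#' )
#' extract_phases(tr, sample_rate_hz = 100)
#' @export
extract_phases <- function(trace, sample_rate_hz = NULL, merge_tol_s = 0.5) {
  if (!all(c("left_key", "right_key") %in% names(trace))) {
    abort("`trace` needs `left_key` and `right_key` columns.")
  }
  l <- trace$left_key
  r <- trace$right_key
  if (length(l) != length(r)) abort("key channels differ in length.")
  if (!all(l %in% c(0, 1)) || !all(r %in% c(0, 1))) {
    abort("malformed trace: key channels must be binary (0/1).")
  }
  if (is.null(sample_rate_hz)) {
    if (!"time_s" %in% names(trace) || nrow(trace) < 2) {
      abort("supply `sample_rate_hz` or a `time_s` column.")
    }
    sample_rate_hz <- 1 / median(diff(trace$time_s))
  }
  if (sample_rate_hz <= 0) abort("`sample_rate_hz` must be positive.")

  state <- ifelse(l == 1 & r == 0, "SIM", ifelse(r == 1 & l == 0, "AM", "NONE"))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ph <- which(runs$values != "NONE")
  if (!length(ph)) {
    return(tibble(percept = character(), onset_s = numeric(),
                  duration_s = numeric(), censored = logical()))
  }
  lab <- runs$values[ph]
  s_idx <- starts[ph]
  e_idx <- ends[ph]

  # merge same-label phases separated by a short unreported gap
  out_lab <- lab[1]; out_s <- s_idx[1]; out_e <- e_idx[1]
  if (length(ph) > 1) {
    for (i in 2:length(ph)) {
      j <- length(out_lab)
      gap_s <- (s_idx[i] - out_e[j] - 1) / sample_rate_hz
      if (lab[i] == out_lab[j] && gap_s < merge_tol_s) {
        out_e[j] <- e_idx[i]
      } else {
        out_lab <- c(out_lab, lab[i])
        out_s <- c(out_s, s_idx[i])
        out_e <- c(out_e, e_idx[i])
      }
    }
  }
  tibble(
    percept = out_lab,
    onset_s = (out_s - 1) / sample_rate_hz,
    duration_s = (out_e - out_s + 1) / sample_rate_hz,
    censored = out_e == length(state) & seq_along(out_lab) == length(out_lab)
  )
}

#' Shortest reportable alternation span implied by the stimulus timing
#'
#' The exclusion floor for mean phase durations comes from the stimulus
#' itself: a percept reported for fewer pulse cycles than a minimal
#' alternation pattern (five pulse + gap cycles, H-L-H-L-H-) cannot be a
#' genuine dominance phase. With 400 ms pulses each followed by a
#' 400 ms silent interval this span is 4 s, the default `min_mean_s` of
#' [apply_exclusion()].
#'
#' @param n_pulses Number of pulse + gap cycles in the minimal pattern.
#' @param pulse_s Pulse duration in seconds.
#' @param gap_s Silent interval after each pulse in seconds.
#' @return The span in seconds.
#' @examples
#' stimulus_span() # 4
#' @export
stimulus_span <- function(n_pulses = 5, pulse_s = 0.4, gap_s = 0.4) {
  n_pulses * (pulse_s + gap_s)
}

#' Flag trials whose mean percept durations are implausible
#'
#' Computes per-trial mean durations and applies the exclusion rule: a
#' trial is excluded when a percept type was never reported (perception
#' did not alternate), or when a mean duration falls below `min_mean_s`
#' (shorter than the minimal alternation span of the stimulus, see
#' [stimulus_span()]) or above `max_mean_s` (taken to indicate
#' non-alternating perception). Under the default `"per_percept"`
#' scheme each percept type's mean is tested separately and either
#' failing excludes the trial; under `"across_percept"` the mean over
#' all phases is tested. Censored final phases are included in these
#' means: a trial dominated by a single 180 s phase must be caught by
#' the 150 s ceiling even though its true duration is unknown.
#'
#' @param phases Long phase table (see [generate_dataset()]).
#' @param min_mean_s,max_mean_s Exclusion bounds in seconds.
#' @param scheme `"per_percept"` or `"across_percept"`.
#' @return One row per trial: the trial keys, per-percept counts and
#'   means, `excluded`, `reason`.
#' @export
trial_exclusions <- function(phases, min_mean_s = 4, max_mean_s = 150,
                             scheme = c("per_percept", "across_percept")) {
  scheme <- match.arg(scheme)
  if (min_mean_s >= max_mean_s) {
    abort("`min_mean_s` must be smaller than `max_mean_s`.")
  }
  assert_phase_table(phases)
  keys <- trial_keys(phases)
  tab <- phases |>
    group_by(across(all_of(keys))) |>
    summarise(
      n_sim = sum(percept == "SIM"),
      n_am = sum(percept == "AM"),
      mean_sim = mean(duration_s[percept == "SIM"]),
      mean_am = mean(duration_s[percept == "AM"]),
      mean_all = mean(duration_s),
      .groups = "drop"
    )
  tab |>
    mutate(
      reason = dplyr::case_when(
        n_sim == 0 | n_am == 0 ~ "no_alternation",
        scheme == "per_percept" &
          pmin(mean_sim, mean_am) < min_mean_s ~ "mean_below_floor",
        scheme == "per_percept" &
          pmax(mean_sim, mean_am) > max_mean_s ~ "mean_above_ceiling",
        scheme == "across_percept" & mean_all < min_mean_s ~ "mean_below_floor",
        scheme == "across_percept" & mean_all > max_mean_s ~ "mean_above_ceiling",
        TRUE ~ NA_character_
      ),
      excluded = !is.na(reason)
    )
}

#' Apply the trial-exclusion rule and keep the remaining phases
#'
#' Filters the phase table to trials passing [trial_exclusions()] and
#' attaches an exclusion report (totals, per-condition excluded counts,
#' thresholds) as attribute `"exclusion_report"`, retrievable with
#' [exclusion_report()]. Kept phases are returned unchanged.
#'
#' @inheritParams trial_exclusions
#' @return The kept phases (tibble) with attributes
#'   `"exclusions"` (the per-trial flag table) and `"exclusion_report"`.
#' @examples
#' ph <- generate_dataset(rivalry_params(n_subjects = 2,
#'                                       n_repetitions = 1,
#'                                       trial_length_s = 60))
#' kept <- apply_exclusion(ph)
#' exclusion_report(kept)$n_excluded
#' @export
apply_exclusion <- function(phases, min_mean_s = 4, max_mean_s = 150,
                            scheme = c("per_percept", "across_percept")) {
  scheme <- match.arg(scheme)
  flags <- trial_exclusions(phases, min_mean_s, max_mean_s, scheme)
  keys <- trial_keys(phases)
  kept_ids <- flags[!flags$excluded, keys, drop = FALSE]
  kept <- if (length(keys)) {
    dplyr::semi_join(phases, kept_ids, by = keys)
  } else if (any(flags$excluded)) phases[0, ] else phases
  per_condition <- if ("delta_i_db" %in% names(flags)) {
    flags |>
      group_by(delta_i_db) |>
      summarise(n_trials = dplyr::n(), n_excluded = sum(excluded),
                .groups = "drop")
  } else {
    tibble(delta_i_db = NA_real_, n_trials = nrow(flags),
           n_excluded = sum(flags$excluded))
  }
  attr(kept, "exclusions") <- flags
  attr(kept, "exclusion_report") <- list(
    n_total = nrow(flags),
    n_excluded = sum(flags$excluded),
    per_condition = per_condition,
    min_mean_s = min_mean_s,
    max_mean_s = max_mean_s,
    scheme = scheme
  )
  kept
}

#' @rdname apply_exclusion
#' @param kept The tibble returned by [apply_exclusion()].
#' @export
exclusion_report <- function(kept) {
  rep <- attr(kept, "exclusion_report")
  if (is.null(rep)) abort("no exclusion report attached; run apply_exclusion() first.")
  rep
}

#' Per-trial summary statistics
#'
#' For every trial: mean dominance duration per percept, proportion of
#' reported time per percept, alternation rate and phase count.
#' Censored final phases are dropped from duration means by default
#' (their true duration is unknown) but always count towards reported
#' time, proportions and the phase count. The alternation rate is
#' (number of phases - 1) per minute of reported time; proportions use
#' reported time as denominator so `prop_sim + prop_am = 1` exactly.
#'
#' @param phases Long phase table.
#' @param drop_censored Drop censored phases from duration means.
#' @return One row per trial with `mean_dur_sim`, `mean_dur_am`,
#'   `prop_sim`, `prop_am`, `alternation_rate` (switches/min),
#'   `n_phases`, `reported_s`.
#' @examples
#' ph <- tibble::tibble(percept = c("SIM", "AM", "SIM"),
#'                      onset_s = c(0, 10, 30),
#'                      duration_s = c(10, 20, 30), censored = FALSE)
#' trial_summary(ph)
#' @export
trial_summary <- function(phases, drop_censored = TRUE) {
  assert_phase_table(phases)
  if (nrow(phases) == 0) abort("undefined summary: trial has zero phases.")
  if (!"censored" %in% names(phases)) phases$censored <- FALSE
  keys <- trial_keys(phases)
  phases |>
    group_by(across(all_of(keys))) |>
    summarise(
      mean_dur_sim = mean(duration_s[percept == "SIM" &
                                       (!censored | !drop_censored)]),
      mean_dur_am = mean(duration_s[percept == "AM" &
                                      (!censored | !drop_censored)]),
      reported_s = sum(duration_s),
      prop_sim = sum(duration_s[percept == "SIM"]) / reported_s,
      prop_am = sum(duration_s[percept == "AM"]) / reported_s,
      n_phases = dplyr::n(),
      alternation_rate = 60 * (dplyr::n() - 1) / reported_s,
      .groups = "drop"
    )
}

#' Rebalance condition cells by resampling per-trial mean durations
#'
#' After exclusion the number of trials differs across conditions. To
#' balance the design, per-trial mean durations are resampled with
#' replacement within each (condition, percept) cell until every cell
#' holds `target_n` observations (45 by default: 15 subjects x 3
#' repetitions). Original rows are flagged `"observed"`, added rows
#' `"resampled"`; the procedure never invents values outside a cell's
#' support.
#'
#' @param summaries Output of [trial_summary()] on the kept trials.
#' @param target_n Target observations per (condition, percept) cell.
#' @param seed Optional seed making the resampling reproducible.
#' @return Long tibble with `delta_i_db`, `percept`, `subject`,
#'   `repetition`, `mean_dur_s`, `source`.
#' @export
rebalance <- function(summaries, target_n = 45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!"delta_i_db" %in% names(summaries)) {
    abort("`summaries` must carry a `delta_i_db` column.")
  }
  long <- summaries |>
    tidyr::pivot_longer(c(mean_dur_sim, mean_dur_am),
                        names_to = "percept", values_to = "mean_dur_s") |>
    mutate(percept = ifelse(percept == "mean_dur_sim", "SIM", "AM")) |>
    dplyr::filter(!is.na(mean_dur_s)) |>
    mutate(source = "observed")
  keep_cols <- intersect(
    c("delta_i_db", "percept", "subject", "repetition", "mean_dur_s", "source"),
    names(long)
  )
  long <- long[keep_cols]
  cells <- split(long, interaction(long$delta_i_db, long$percept, drop = FALSE))
  conditions <- unique(long$delta_i_db)
  full <- expand.grid(delta_i_db = conditions, percept = c("SIM", "AM"))
  out <- purrr::map_dfr(seq_len(nrow(full)), function(i) {
    cell <- long[long$delta_i_db == full$delta_i_db[i] &
                   long$percept == full$percept[i], ]
    if (nrow(cell) == 0) {
      abort(paste0("cannot rebalance: no retained trials in cell delta_i_db = ",
                   full$delta_i_db[i], ", percept = ", full$percept[i], "."))
    }
    if (nrow(cell) >= target_n) return(cell)
    extra <- cell[sample.int(nrow(cell), target_n - nrow(cell), replace = TRUE), ]
    extra$source <- "resampled"
    dplyr::bind_rows(cell, extra)
  })
  as_tibble(out)
}

#' Subject-level mean durations and proportions per condition
#'
#' For each subject x condition x percept, the mean dominance duration
#' pooled over all phase durations across repetitions (not a mean of
#' per-trial means) and the proportion of reported time, ready for the
#' condition curves and the within-subject ANOVA. Cells where a subject
#' reported one percept but not the other are emitted as missing-value
#' rows with a warning.
#'
#' @param phases Long phase table (typically after [apply_exclusion()]).
#' @param drop_censored Drop censored phases from duration means.
#' @return Tibble keyed (`subject`, `delta_i_db`, `percept`) with
#'   `mean_duration_s`, `prop`, `n_phases`.
#' @export
subject_condition_means <- function(phases, drop_censored = TRUE) {
  assert_phase_table(phases)
  if (!all(c("subject", "delta_i_db") %in% names(phases))) {
    abort("`phases` must carry `subject` and `delta_i_db` columns.")
  }
  if (!"censored" %in% names(phases)) phases$censored <- FALSE
  totals <- phases |>
    group_by(subject, delta_i_db) |>
    summarise(total_s = sum(duration_s), .groups = "drop")
  out <- phases |>
    group_by(subject, delta_i_db, percept) |>
    summarise(
      mean_duration_s = mean(duration_s[!censored | !drop_censored]),
      reported_s = sum(duration_s),
      n_phases = sum(!censored | !drop_censored),
      .groups = "drop"
    ) |>
    dplyr::left_join(totals, by = c("subject", "delta_i_db")) |>
    mutate(prop = reported_s / total_s) |>
    dplyr::select(subject, delta_i_db, percept, mean_duration_s, prop, n_phases) |>
    tidyr::complete(tidyr::nesting(subject, delta_i_db),
                    percept = c("SIM", "AM"))
  if (anyNA(out$mean_duration_s)) {
    warn(paste0(sum(is.na(out$mean_duration_s)),
                " subject x condition cell(s) lack one percept; ",
                "missing-value rows emitted."))
  }
  dplyr::arrange(out, subject, delta_i_db, dplyr::desc(percept))
}
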