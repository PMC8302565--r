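parse_transition <- function(transition, lag) {
  parts <- strsplit(gsub("\\s", "", transition), "->", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% c("SIM", "AM"))) {
    abort("`transition` must look like \"SIM->AM\".")
  }
  if (!lag %in% c(1, 2)) abort("`lag` must be 1 or 2.")
  if (lag == 1 && parts[1] == parts[2]) {
    abort("lag-1 pairs connect different percepts (e.g. \"SIM->AM\").")
  }
  if (lag == 2 && parts[1] != parts[2]) {
    abort("lag-2 pairs connect the same percept (e.g. \"SIM->SIM\").")
  }
  parts
}

#' Lagged pairs of phase durations
#'
#' Enumerates, per trial, the (duration, next duration) pairs for one
#' transition type. Lag 1 pairs a phase with the immediately following
#' phase of the other percept (transitions SIM->AM and AM->SIM); lag 2
#' pairs a phase with the next phase of the same percept (SIM->SIM,
#' AM->AM). Pairs involving a censored phase are excluded. For lag 1
#' the SIM->AM and AM->SIM pair sets are disjoint and together cover
#' all adjacent pairs.
#'
#' @param phases Long phase table; each trial's phases must strictly
#'   alternate.
#' @param lag 1 or 2.
#' @param transition Transition label, e.g. `"SIM->AM"`.
#' @param use_norm Pair the `norm_duration` column instead of raw
#'   durations (requires [normalize_durations()] output).
#' @return Tibble with the trial keys and `first_dur`, `second_dur`.
#' @examples
#' ph <- tibble::tibble(percept = c("SIM", "AM", "SIM", "AM"),
#'                      onset_s = c(0, 10, 25, 40),
#'                      duration_s = c(10, 15, 15, 20), censored = FALSE)
#' lagged_pairs(ph, lag = 1, transition = "SIM->AM")
#' @export
lagged_pairs <- function(phases, lag, transition, use_norm = FALSE) {
  from <- parse_transition(transition, lag)[1]
  assert_phase_table(phases)
  if (!"censored" %in% names(phases)) phases$censored <- FALSE
  if (use_norm && !"norm_duration" %in% names(phases)) {
    abort("`use_norm = TRUE` needs a `norm_duration` column.")
  }
  keys <- trial_keys(phases)
  val <- if (use_norm) "norm_duration" else "duration_s"
  phases |>
    group_by(across(all_of(keys))) |>
    dplyr::arrange(onset_s, .by_group = TRUE) |>
    dplyr::group_modify(function(tr, key) {
      k <- nrow(tr)
      if (k > 1 && any(tr$percept[-1] == tr$percept[-k])) {
        abort("malformed sequence: phases must strictly alternate within a trial.")
      }
      i <- which(tr$percept == from)
      i <- i[i + lag <= k]
      i <- i[!tr$censored[i] & !tr$censored[i + lag]]
      tibble(first_dur = tr[[val]][i], second_dur = tr[[val]][i + lag])
    }) |>
    ungroup()
}

#' Pooled lagged correlation of phase durations
#'
#' The first of two complementary methods: durations are normalized to
#' the mean of their percept type within each trial (removing
#' inter-subject and inter-trial differences that would otherwise
#' induce spurious correlation), the lagged pairs of all trials are
#' pooled, and the Pearson correlation coefficient is computed over the
#' pooled scatter with a two-sided t-based p-value.
#'
#' @inheritParams lagged_pairs
#' @param p_method `"t"` for the usual t-based p-value, or
#'   `"permutation"` for a two-sided permutation p (pairings shuffled).
#' @param n_perm Permutations when `p_method = "permutation"`.
#' @return One-row tibble: `method`, `lag`, `transition`, `corr`,
#'   `p_value`, `n_pairs`.
#' @export
pooled_corr <- function(phases, lag, transition, p_method = c("t", "permutation"),
                        n_perm = 2000) {
  p_method <- match.arg(p_method)
  parse_transition(transition, lag)
  norm <- normalize_durations(phases, "per_trial_percept",
                              drop_censored = TRUE)
  pairs <- lagged_pairs(norm, lag, transition, use_norm = TRUE)
  if (nrow(pairs) < 3) abort("need at least 3 pooled pairs.")
  if (sd(pairs$first_dur) == 0 || sd(pairs$second_dur) == 0) {
    abort("undefined correlation: a pooled margin has zero variance.")
  }
  r <- cor(pairs$first_dur, pairs$second_dur)
  n <- nrow(pairs)
  p <- if (p_method == "t") {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  } else {
    null_r <- vapply(seq_len(n_perm), function(i) {
      cor(pairs$first_dur, sample(pairs$second_dur))
    }, numeric(1))
    (1 + sum(abs(null_r) >= abs(r))) / (n_perm + 1)
  }
  tibble(method = "pooled", lag = lag, transition = transition,
         corr = r, p_value = p, n_pairs = n)
}

#' Single-trial lagged correlation distribution
#'
#' The second method: the Pearson correlation is computed on raw
#' (un-normalized) durations within each trial having at least
#' `min_pairs` pairs, each trial is treated as one sample of the
#' correlation, and a two-sided one-sample t-test asks whether the mean
#' of the distribution differs from zero.
#'
#' @inheritParams lagged_pairs
#' @param min_pairs Minimal pairs per trial for a defined correlation.
#' @return One-row tibble: `method`, `lag`, `transition`, `m` (mean
#'   correlation), `std`, `statistic` (t), `p_value`, `n_trials`,
#'   `n_skipped`, `degenerate` (zero spread across trials).
#' @export
single_trial_corr <- function(phases, lag, transition, min_pairs = 3) {
  parse_transition(transition, lag)
  if (min_pairs < 3) abort("`min_pairs` must be at least 3.")
  keys <- trial_keys(phases)
  pairs <- lagged_pairs(phases, lag, transition)
  per_trial <- pairs |>
    group_by(across(all_of(keys))) |>
    summarise(
      n_pairs = dplyr::n(),
      r = if (dplyr::n() >= min_pairs &&
              sd(first_dur) > 0 && sd(second_dur) > 0) {
        cor(first_dur, second_dur)
      } else NA_real_,
      .groups = "drop"
    )
  rs <- per_trial$r[!is.na(per_trial$r)]
  n_skipped <- sum(is.na(per_trial$r))
  if (length(rs) < 2) {
    abort("insufficient data: fewer than 2 trials admit a correlation.")
  }
  if (sd(rs) == 0) {
    return(tibble(method = "single_trial", lag = lag, transition = transition,
                  m = mean(rs), std = 0, statistic = NA_real_,
                  p_value = NA_real_, n_trials = length(rs),
                  n_skipped = n_skipped, degenerate = TRUE))
  }
  tt <- t.test(rs, mu = 0)
  tibble(method = "single_trial", lag = lag, transition = transition,
         m = mean(rs), std = sd(rs), statistic = unname(tt$statistic),
         p_value = tt$p.value, n_trials = length(rs),
         n_skipped = n_skipped, degenerate = FALSE)
}

#' All lag-1/lag-2 correlations by both methods
#'
#' Convenience wrapper running [pooled_corr()] and
#' [single_trial_corr()] for the four transition types (lag 1:
#' SIM->AM, AM->SIM; lag 2: SIM->SIM, AM->AM).
#'
#' @inheritParams single_trial_corr
#' @return Tibble, one row per method x transition.
#' @export
lag_correlation_table <- function(phases, min_pairs = 3) {
  specs <- tibble(
    lag = c(1, 1, 2, 2),
    transition = c("SIM->AM", "AM->SIM", "SIM->SIM", "AM->AM")
  )
  pooled <- purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    pooled_corr(phases, specs$lag[i], specs$transition[i])
  })
  single <- purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    single_trial_corr(phases, specs$lag[i], specs$transition[i], min_pairs)
  })
  dplyr::bind_rows(pooled, single)
}
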