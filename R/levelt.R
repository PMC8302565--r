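#' Condition curves of mean dominance and proportion
#'
#' Averages subject-level values per condition and percept, with
#' standard errors across subjects, producing the Levelt-proposition-II
#' surfaces: mean dominance duration and dominance proportion as a
#' function of the intensity difference. Under proposition II the mean
#' dominance of the percept favoured by the manipulation grows with the
#' stimulus difference while the other percept's shrinks.
#'
#' @param subject_means Output of [subject_condition_means()].
#' @return A tibble of class `rivalry_curves`, one row per condition x
#'   percept: `n_subjects`, `mean_duration_s`, `se_duration`,
#'   `mean_prop`, `se_prop`. Missing subject cells are dropped with a
#'   warning; error-bar convention is SEM across subjects.
#' @examples
#' ph <- generate_dataset(rivalry_params(n_subjects = 4,
#'                                       n_repetitions = 1,
#'                                       trial_length_s = 120))
#' condition_curves(subject_condition_means(ph))
#' @export
condition_curves <- function(subject_means) {
  need <- c("subject", "delta_i_db", "percept", "mean_duration_s", "prop")
  miss <- setdiff(need, names(subject_means))
  if (length(miss)) {
    abort(paste0("`subject_means` is missing column(s): ",
                 paste(miss, collapse = ", "), "."))
  }
  drop <- !complete.cases(subject_means[c("mean_duration_s", "prop")])
  if (any(drop)) {
    warn(paste0(sum(drop), " missing subject cell(s) dropped from the curves."))
    subject_means <- subject_means[!drop, ]
  }
  curves <- subject_means |>
    group_by(delta_i_db, percept) |>
    summarise(
      n_subjects = dplyr::n_distinct(subject),
      se_duration = sd_over_sqrt_n(mean_duration_s),
      mean_duration_s = mean(mean_duration_s),
      se_prop = sd_over_sqrt_n(prop),
      mean_prop = mean(prop),
      .groups = "drop"
    ) |>
    dplyr::select(delta_i_db, percept, n_subjects,
                  mean_duration_s, se_duration, mean_prop, se_prop)
  if (any(curves$n_subjects < 2)) {
    abort("insufficient data: every condition needs at least 2 subjects.")
  }
  class(curves) <- c("rivalry_curves", class(curves))
  curves
}

# SEM helper; NA-free input expected
sd_over_sqrt_n <- function(x) sd(x) / sqrt(length(x))

#' Mean alternation rate per condition
#'
#' The alternation rate (switches per minute) peaks at equidominance
#' and falls off on either side. Each subject's rate per condition
#' pools switches and reported time over repetitions; the curve is the
#' mean across subjects with its SEM.
#'
#' @param phases Long phase table (after exclusion).
#' @return Tibble per condition: `n_subjects`, `mean_rate`, `se_rate`
#'   (switches per minute).
#' @export
alternation_rate_curve <- function(phases) {
  assert_phase_table(phases)
  if (!all(c("subject", "delta_i_db") %in% names(phases))) {
    abort("`phases` must carry `subject` and `delta_i_db` columns.")
  }
  rates <- phases |>
    group_by(subject, delta_i_db, repetition) |>
    summarise(switches = dplyr::n() - 1, reported_s = sum(duration_s),
              .groups = "drop") |>
    group_by(subject, delta_i_db) |>
    summarise(rate = 60 * sum(switches) / sum(reported_s), .groups = "drop")
  curve <- rates |>
    group_by(delta_i_db) |>
    summarise(
      n_subjects = dplyr::n(),
      mean_rate = mean(rate),
      se_rate = sd_over_sqrt_n(rate),
      .groups = "drop"
    )
  if (any(curve$n_subjects < 2)) {
    abort("insufficient data: every condition needs at least 2 subjects.")
  }
  curve
}

#' Estimate the equidominance point
#'
#' The equidominance point is the intensity difference at which both
#' percepts dominate equal fractions of time (SIM proportion = 0.5).
#' It is located on the SIM-proportion condition curve: an exact
#' attainment is returned as such, otherwise the crossing is linearly
#' interpolated in dB between the bracketing tested levels. With
#' several crossings the one nearest the alternation-rate maximum is
#' chosen (rates supplied via `rate_curve`), since the rate peaks at
#' equidominance. A curve that never crosses 0.5 yields a boundary
#' flag, never an extrapolation.
#'
#' @param curves A [condition_curves()] result (or any tibble with
#'   `delta_i_db`, `percept`, `mean_prop`).
#' @param rate_curve Optional [alternation_rate_curve()] result used to
#'   disambiguate multiple crossings.
#' @return One-row tibble: `delta_star_db`, `bracket_lo`, `bracket_hi`,
#'   `attained` (exactly 0.5 at a tested level), `boundary` (`NA`, or
#'   `"above"`/`"below"` when the curve never crosses 0.5).
#' @examples
#' cv <- tibble::tibble(delta_i_db = c(0.5, 1, 2, 4, 6),
#'                      percept = "SIM",
#'                      mean_prop = c(.7, .6, .55, .45, .3))
#' estimate_equidominance(cv)
#' @export
estimate_equidominance <- function(curves, rate_curve = NULL) {
  sim <- curves[curves$percept == "SIM", ]
  sim <- sim[order(sim$delta_i_db), ]
  d <- sim$delta_i_db
  p <- sim$mean_prop
  if (length(d) < 2) abort("need at least two conditions.")

  hit <- which(abs(p - 0.5) < 1e-12)
  cands <- tibble(delta_star_db = numeric(), bracket_lo = numeric(),
                  bracket_hi = numeric(), attained = logical())
  if (length(hit)) {
    cands <- dplyr::bind_rows(cands, tibble(
      delta_star_db = d[hit], bracket_lo = d[hit], bracket_hi = d[hit],
      attained = TRUE
    ))
  }
  cross <- which((p[-length(p)] - 0.5) * (p[-1] - 0.5) < 0)
  if (length(cross)) {
    lo <- d[cross]; hi <- d[cross + 1]
    star <- lo + (0.5 - p[cross]) * (hi - lo) / (p[cross + 1] - p[cross])
    cands <- dplyr::bind_rows(cands, tibble(
      delta_star_db = star, bracket_lo = lo, bracket_hi = hi, attained = FALSE
    ))
  }
  if (nrow(cands) == 0) {
    return(tibble(
      delta_star_db = NA_real_, bracket_lo = NA_real_, bracket_hi = NA_real_,
      attained = FALSE,
      boundary = if (all(p > 0.5)) "above" else "below"
    ))
  }
  pick <- 1L
  if (nrow(cands) > 1 && !is.null(rate_curve)) {
    peak <- rate_curve$delta_i_db[which.max(rate_curve$mean_rate)]
    pick <- which.min(abs(cands$delta_star_db - peak))
  }
  dplyr::bind_cols(cands[pick, ], tibble(boundary = NA_character_))
}
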