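#' Parameters for the synthetic rivalry experiment generator
#'
#' Bundles and validates every knob of the synthetic experiment:
#' session layout (subjects, intensity-difference levels, repetitions,
#' trial length), the marginal family and moments of phase durations,
#' the serial-dependence targets, between-subject heterogeneity and
#' keypress timing.
#'
#' Defaults emulate the study conditions of a vibrotactile rivalry
#' session: 15 subjects, five intensity differences
#' (0.5, 1, 2, 4, 6 dB), three repetitions of 3-minute trials, gamma
#' phase-duration marginals with coefficient of variation 0.6, SIM mean
#' duration decreasing and AM mean increasing in dB (log-linear,
#' crossing at 16 s near 2.5 dB, so that equidominance falls between
#' the 2 and 4 dB conditions), a small positive lag-1 and small
#' negative lag-2 duration correlation (+0.15 / -0.15).
#'
#' Serial dependence is induced by a Gaussian copula over a latent
#' stationary AR(2) process whose lag-1/lag-2 autocorrelations equal
#' the targets; the monotone quantile transform to the gamma or
#' log-normal marginal attenuates these slightly, so the targets are
#' approximate (see the methods vignette).
#'
#' @param n_subjects Number of subjects.
#' @param delta_i_db Intensity-difference levels (dB), the control
#'   parameter of the experiment.
#' @param n_repetitions Repetitions of each level per subject; each
#'   repetition is one block of `length(delta_i_db)` trials.
#' @param trial_length_s Trial length in seconds.
#' @param marginal Phase-duration marginal family, `"gamma"` or
#'   `"lognormal"`.
#' @param mean_sim_fn,mean_am_fn Functions mapping dB to the mean
#'   dominance duration (seconds) of the SIM / AM percept. Must be
#'   strictly positive over `delta_i_db`.
#' @param cv Target coefficient of variation of phase durations.
#' @param lag1_corr,lag2_corr Target lag-1 / lag-2 duration
#'   correlations, each in (-1, 1); the pair must be admissible for a
#'   stationary AR(2).
#' @param subject_sd Between-subject heterogeneity: SD of a log-normal
#'   multiplicative subject effect on mean durations (log scale; 0.3
#'   gives roughly +/-35% typical spread).
#' @param jitter_sd SD (seconds) of the truncated-Gaussian keypress
#'   reaction-time jitter applied at phase boundaries when rendering
#'   traces.
#' @param sample_rate_hz Keypress sampling rate for rendered traces.
#' @param seed Default root seed used by [generate_dataset()].
#'
#' @return An object of class `rivalry_params` (a named list).
#' @examples
#' p <- rivalry_params(n_subjects = 2, trial_length_s = 60)
#' p$mean_sim_fn(2)
#' @export
rivalry_params <- function(n_subjects = 15,
                           delta_i_db = c(0.5, 1, 2, 4, 6),
                           n_repetitions = 3,
                           trial_length_s = 180,
                           marginal = c("gamma", "lognormal"),
                           mean_sim_fn = function(d) 16 * exp(-0.12 * (d - 2.5)),
                           mean_am_fn = function(d) 16 * exp(0.12 * (d - 2.5)),
                           cv = 0.6,
                           lag1_corr = 0.15,
                           lag2_corr = -0.15,
                           subject_sd = 0.3,
                           jitter_sd = 0.1,
                           sample_rate_hz = 100,
                           seed = 1L) {
  marginal <- match.arg(marginal)
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be a positive integer.")
  }
  if (trial_length_s <= 0) abort("`trial_length_s` must be positive.")
  if (cv <= 0) abort("`cv` must be positive.")
  if (abs(lag1_corr) >= 1 || abs(lag2_corr) >= 1) {
    abort("`lag1_corr` and `lag2_corr` must lie strictly inside (-1, 1).")
  }
  if (subject_sd < 0) abort("`subject_sd` must be non-negative.")
  if (jitter_sd < 0) abort("`jitter_sd` must be non-negative.")
  mus <- c(vapply(delta_i_db, mean_sim_fn, numeric(1)),
           vapply(delta_i_db, mean_am_fn, numeric(1)))
  if (any(!is.finite(mus)) || any(mus <= 0)) {
    abort("mean functions must be strictly positive over `delta_i_db`.")
  }
  latent_ar2_coefs(lag1_corr, lag2_corr) # admissibility check, errors if not
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      delta_i_db = as.numeric(delta_i_db),
      n_repetitions = as.integer(n_repetitions),
      trial_length_s = trial_length_s,
      marginal = marginal,
      mean_sim_fn = mean_sim_fn,
      mean_am_fn = mean_am_fn,
      cv = cv,
      lag1_corr = lag1_corr,
      lag2_corr = lag2_corr,
      subject_sd = subject_sd,
      jitter_sd = jitter_sd,
      sample_rate_hz = sample_rate_hz,
      seed = as.integer(seed)
    ),
    class = "rivalry_params"
  )
}

#' AR(2) coefficients for a target autocorrelation pair
#'
#' Solves the Yule-Walker equations for the AR(2) coefficients that
#' produce the given lag-1 and lag-2 autocorrelations, and checks the
#' stationarity triangle. Used by the generator's latent Gaussian
#' process; exported because the admissibility check is part of the
#' parameter contract.
#'
#' @param rho1,rho2 Target lag-1 / lag-2 autocorrelations.
#' @return A list with `phi1`, `phi2` and `innovation_sd` (the
#'   innovation SD giving unit marginal variance).
#' @examples
#' latent_ar2_coefs(0.15, -0.15)
#' @export
latent_ar2_coefs <- function(rho1, rho2) {
  if (abs(rho1) >= 1 || abs(rho2) >= 1) {
    abort("autocorrelations must lie strictly inside (-1, 1).")
  }
  phi1 <- rho1 * (1 - rho2) / (1 - rho1^2)
  phi2 <- (rho2 - rho1^2) / (1 - rho1^2)
  viol <- c(
    if (phi1 + phi2 >= 1) "phi1 + phi2 >= 1",
    if (phi2 - phi1 >= 1) "phi2 - phi1 >= 1",
    if (abs(phi2) >= 1) "|phi2| >= 1"
  )
  if (length(viol)) {
    abort(paste0(
      "autocorrelation pair (", rho1, ", ", rho2,
      ") is not admissible for a stationary AR(2): ",
      paste(viol, collapse = ", "), "."
    ))
  }
  s2 <- (1 + phi2) * ((1 - phi2)^2 - phi1^2) / (1 - phi2)
  list(phi1 = phi1, phi2 = phi2, innovation_sd = sqrt(s2))
}

# stationary AR(2) sample with unit marginal variance
simulate_ar2 <- function(n, rho1, rho2) {
  co <- latent_ar2_coefs(rho1, rho2)
  z <- numeric(n)
  z[1] <- rnorm(1)
  if (n >= 2) z[2] <- rho1 * z[1] + sqrt(1 - rho1^2) * rnorm(1)
  if (n >= 3) {
    eps <- rnorm(n - 2, sd = co$innovation_sd)
    for (t in 3:n) z[t] <- co$phi1 * z[t - 1] + co$phi2 * z[t - 2] + eps[t - 2]
  }
  z
}

# quantile transform of N(0,1) values to a positive marginal with
# given mean and coefficient of variation
marginal_quantile <- function(z, mean, cv, family) {
  if (cv < 1e-8) return(rep(mean, length(z))) # variance floor: degenerate
  u <- pnorm(z)
  if (family == "gamma") {
    shape <- 1 / cv^2
    qgamma(u, shape = shape, scale = mean * cv^2)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    qlnorm(u, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
}

#' Latin-square session design
#'
#' Builds the trial order for each subject: `n_repetitions` blocks, each
#' block presenting every intensity-difference level exactly once, with
#' block orders taken as rows of randomized Latin squares so condition
#' order is counterbalanced within and across subjects. A small pool of
#' distinct randomized squares is generated and subjects are assigned to
#' grids cyclically.
#'
#' @param n_subjects Number of subjects.
#' @param delta_i_db Condition levels (dB).
#' @param n_repetitions Blocks per subject (each level once per block).
#' @param seed Integer seed; the design is deterministic given the seed.
#' @param n_grids Number of distinct randomized Latin squares in the pool.
#' @return A tibble with columns `subject`, `repetition` (block),
#'   `position` (order within block), `delta_i_db`, `grid`.
#' @examples
#' d <- build_design(2, seed = 1)
#' table(d$subject, d$delta_i_db)
#' @export
build_design <- function(n_subjects,
                         delta_i_db = c(0.5, 1, 2, 4, 6),
                         n_repetitions = 3,
                         seed = 1L,
                         n_grids = 9L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 1) {
    abort("`n_subjects` must be a positive integer.")
  }
  m <- length(delta_i_db)
  if (n_repetitions > m) {
    abort("`n_repetitions` cannot exceed the number of levels (rows of a Latin square).")
  }
  set.seed(seed)
  grids <- replicate(n_grids, random_latin_square(m), simplify = FALSE)
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    g <- ((s - 1) %% n_grids) + 1
    rows <- sample.int(m, n_repetitions) # distinct rows of the subject's grid
    purrr::map_dfr(seq_len(n_repetitions), function(r) {
      tibble(
        subject = s,
        repetition = r,
        position = seq_len(m),
        delta_i_db = delta_i_db[grids[[g]][rows[r], ]],
        grid = g
      )
    })
  })
}

# randomized Latin square: cyclic base with rows/columns/symbols permuted
random_latin_square <- function(m) {
  base <- outer(seq_len(m), seq_len(m), function(i, j) ((i + j - 2) %% m) + 1)
  base <- base[sample.int(m), sample.int(m)]
  sym <- sample.int(m)
  matrix(sym[base], m, m)
}

#' Sample one trial's sequence of perceptual phases
#'
#' Draws a strictly alternating SIM/AM phase sequence for one trial.
#' The first percept is a fair coin flip; durations are quantile
#' transforms of a latent stationary Gaussian AR(2) (Gaussian copula),
#' so each duration has the target marginal (gamma or log-normal with
#' mean `mean_*_fn(delta_i_db) * subject_effect` and coefficient of
#' variation `cv`) while successive durations carry approximately the
#' target lag-1/lag-2 correlations. The final phase is truncated at the
#' trial end and flagged censored.
#'
#' Uses the current RNG state; seed upstream (or use
#' [generate_dataset()] which manages per-trial substreams).
#'
#' @param params A [rivalry_params()] object.
#' @param delta_i_db Condition level (dB) for this trial.
#' @param subject_effect Multiplicative subject effect on mean durations.
#' @param trial_length_s Trial length; defaults to the value in `params`.
#' @return A tibble with columns `percept`, `onset_s`, `duration_s`,
#'   `censored`.
#' @examples
#' set.seed(1)
#' sample_phase_sequence(rivalry_params(), delta_i_db = 2)
#' @export
sample_phase_sequence <- function(params, delta_i_db, subject_effect = 1,
                                  trial_length_s = params$trial_length_s) {
  stopifnot(inherits(params, "rivalry_params"))
  if (subject_effect <= 0) abort("`subject_effect` must be positive.")
  mu_sim <- params$mean_sim_fn(delta_i_db) * subject_effect
  mu_am <- params$mean_am_fn(delta_i_db) * subject_effect
  first_sim <- runif(1) < 0.5

  mu_min <- min(mu_sim, mu_am)
  n <- max(20L, ceiling(3 * trial_length_s / mu_min))
  repeat {
    z <- simulate_ar2(n, params$lag1_corr, params$lag2_corr)
    is_sim <- (seq_len(n) %% 2L == 1L) == first_sim
    dur <- ifelse(is_sim,
      marginal_quantile(z, mu_sim, params$cv, params$marginal),
      marginal_quantile(z, mu_am, params$cv, params$marginal)
    )
    if (sum(dur) >= trial_length_s) break
    n <- n * 2L
  }
  onset <- cumsum(c(0, dur[-n]))
  keep <- onset < trial_length_s
  dur <- dur[keep]
  onset <- onset[keep]
  is_sim <- is_sim[keep]
  k <- length(dur)
  cens <- logical(k)
  if (onset[k] + dur[k] > trial_length_s) {
    dur[k] <- trial_length_s - onset[k]
    cens[k] <- TRUE
  }
  tibble(
    percept = ifelse(is_sim, "SIM", "AM"),
    onset_s = onset,
    duration_s = dur,
    censored = cens
  )
}

#' Generate a full synthetic rivalry dataset
#'
#' Runs the whole synthetic experiment: a Latin-square design via
#' [build_design()], one multiplicative log-normal effect per subject
#' (mean 1 on the natural scale), and one phase sequence per
#' (subject, condition, repetition) trial via [sample_phase_sequence()].
#' A single root seed is expanded into per-subject and per-trial
#' substreams, so the output is fully reproducible and any subject's
#' trials can be regenerated independently.
#'
#' @param params A [rivalry_params()] object.
#' @param seed Root seed; defaults to `params$seed`.
#' @return A long tibble of phases with columns `subject`,
#'   `delta_i_db`, `repetition`, `percept`, `onset_s`, `duration_s`,
#'   `censored`, carrying the design and subject effects as attributes
#'   `"design"` and `"subject_effects"`.
#' @examples
#' small <- rivalry_params(n_subjects = 2, n_repetitions = 1,
#'                         trial_length_s = 60)
#' phases <- generate_dataset(small, seed = 7)
#' dplyr::count(phases, subject, delta_i_db)
#' @export
generate_dataset <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "rivalry_params"))
  set.seed(seed)
  design_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, params$n_subjects)
  design <- build_design(
    params$n_subjects, params$delta_i_db, params$n_repetitions,
    seed = design_seed
  )
  effects <- numeric(params$n_subjects)
  phases <- purrr::map_dfr(seq_len(params$n_subjects), function(s) {
    set.seed(subject_seeds[s])
    # mean-1 multiplicative subject effect
    effects[s] <<- exp(rnorm(1, sd = params$subject_sd) - params$subject_sd^2 / 2)
    slots <- design[design$subject == s, ]
    trial_seeds <- sample.int(.Machine$integer.max - 1L, nrow(slots))
    purrr::map_dfr(seq_len(nrow(slots)), function(i) {
      set.seed(trial_seeds[i])
      ph <- sample_phase_sequence(params, slots$delta_i_db[i], effects[s])
      dplyr::bind_cols(
        tibble(
          subject = s,
          delta_i_db = slots$delta_i_db[i],
          repetition = slots$repetition[i]
        )[rep(1, nrow(ph)), ],
        ph
      )
    })
  })
  attr(phases, "design") <- design
  attr(phases, "subject_effects") <-
    tibble(subject = seq_len(params$n_subjects), effect = effects)
  attr(phases, "params") <- params
  phases
}

#' Render a phase sequence as a sampled keypress trace
#'
#' Turns one trial's phases into the two binary key channels an
#' observer would produce: SIM maps to the left key, AM to the right
#' key. Each internal phase boundary is perturbed by truncated Gaussian
#' reaction-time jitter (never enough to reorder boundaries), and the
#' release/press pair at a switch leaves a short no-key gap; at most
#' one key is held per sample. With `jitter_sd = 0` the rendering is
#' exact up to the sampling grid and [extract_phases()] recovers every
#' duration to within one sample period.
#'
#' @param phases Tibble with `percept`, `onset_s`, `duration_s`
#'   (one trial, ordered, non-overlapping).
#' @param sample_rate_hz Sampling rate of the trace.
#' @param jitter_sd Boundary jitter SD in seconds.
#' @param trial_length_s Trace length; defaults to the end of the last
#'   phase.
#' @return A tibble with columns `time_s`, `left_key`, `right_key`.
#' @examples
#' ph <- tibble::tibble(percept = c("SIM", "AM"), onset_s = c(0, 10),
#'                      duration_s = c(10, 10), censored = FALSE)
#' tr <- render_trace(ph, sample_rate_hz = 100)
#' nrow(tr)
#' @export
render_trace <- function(phases, sample_rate_hz = 100, jitter_sd = 0,
                         trial_length_s = NULL) {
  if (sample_rate_hz <= 0) abort("`sample_rate_hz` must be positive.")
  phases <- dplyr::arrange(phases, onset_s)
  k <- nrow(phases)
  if (k == 0) abort("`phases` is empty.")
  ends <- phases$onset_s + phases$duration_s
  if (k > 1 && any(phases$onset_s[-1] < ends[-k] - 1e-9)) {
    abort("phases overlap; they must be ordered and non-overlapping.")
  }
  trial_length_s <- trial_length_s %||% ends[k]

  press <- phases$onset_s
  release <- ends
  if (jitter_sd > 0 && k > 1) {
    for (i in seq_len(k - 1)) {
      b <- ends[i]
      # truncate so the jittered switch stays inside both neighbours
      lim <- 0.45 * min(phases$duration_s[i], phases$duration_s[i + 1])
      e <- sort(pmax(pmin(rnorm(2, sd = jitter_sd), lim, 3 * jitter_sd),
                     -lim, -3 * jitter_sd))
      release[i] <- b + e[1]
      press[i + 1] <- b + e[2]
    }
  }
  n <- round(trial_length_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  left <- integer(n)
  right <- integer(n)
  for (i in seq_len(k)) {
    held <- t >= press[i] - 1e-9 & t < release[i] - 1e-9
    if (phases$percept[i] == "SIM") left[held] <- 1L else right[held] <- 1L
  }
  tibble(time_s = t, left_key = left, right_key = right)
}
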