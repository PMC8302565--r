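#' Normalize phase durations by their group mean
#'
#' Dominance durations vary widely across subjects and conditions while
#' the distribution shape stays put, so samples are pooled after
#' dividing each duration by the mean of its group. Two schemes are
#' offered: per subject x condition x percept (the default, used for
#' pooled histograms and the scaling analysis) and per trial x percept
#' (used for the pooled correlation analysis, where trial-level
#' normalization avoids spurious correlation from inter-trial
#' differences). Each group's normalized mean is exactly 1.
#'
#' @param phases Long phase table.
#' @param scheme `"per_subject_condition_percept"` or
#'   `"per_trial_percept"`.
#' @param drop_first Drop the first phase of every trial.
#' @param drop_censored Drop censored phases (default; their duration
#'   is unknown).
#' @return The input rows retained, with a `norm_duration` column.
#' @examples
#' ph <- tibble::tibble(subject = 1, delta_i_db = 2, repetition = 1,
#'                      percept = c("SIM", "AM", "SIM"),
#'                      onset_s = c(0, 10, 30),
#'                      duration_s = c(10, 20, 30), censored = FALSE)
#' normalize_durations(ph)$norm_duration
#' @export
normalize_durations <- function(phases,
                                scheme = c("per_subject_condition_percept",
                                           "per_trial_percept"),
                                drop_first = FALSE,
                                drop_censored = TRUE) {
  scheme <- match.arg(scheme)
  assert_phase_table(phases)
  if (!"censored" %in% names(phases)) phases$censored <- FALSE
  keys <- trial_keys(phases)
  if (drop_first) {
    phases <- phases |>
      group_by(across(all_of(keys))) |>
      dplyr::arrange(onset_s, .by_group = TRUE) |>
      dplyr::slice(-1) |>
      ungroup()
  }
  if (drop_censored) phases <- phases[!phases$censored, ]
  grp <- switch(scheme,
    per_subject_condition_percept = intersect(
      c("subject", "delta_i_db", "percept"), names(phases)
    ),
    per_trial_percept = c(keys, "percept")
  )
  out <- phases |>
    group_by(across(all_of(grp))) |>
    mutate(norm_duration = duration_s / mean(duration_s)) |>
    ungroup()
  if (any(!is.finite(out$norm_duration))) {
    abort("degenerate group: a normalization group has zero mean duration.")
  }
  out
}

#' Fit a gamma or log-normal distribution to durations
#'
#' Two-parameter maximum-likelihood fit (gamma shape/rate; log-normal
#' meanlog/sdlog, no location shift) via [fitdistrplus::fitdist()].
#'
#' @param x Positive numeric sample (durations, possibly normalized).
#' @param family `"gamma"` or `"lognormal"`.
#' @return Object of class `duration_fit`: a list with `family`,
#'   `estimate` (named parameter vector), `sd` (standard errors),
#'   `loglik`, `n` and the sample `x`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' set.seed(1)
#' fit_duration_dist(rgamma(500, shape = 4), "gamma")
#' @export
fit_duration_dist <- function(x, family = c("gamma", "lognormal")) {
  family <- match.arg(family)
  x <- as.numeric(x)
  if (length(x) < 5) abort("insufficient sample: need at least 5 durations.")
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("durations must be positive and finite.")
  }
  if (sd(x) == 0) {
    abort("degenerate sample: constant durations admit no maximum-likelihood fit.")
  }
  distname <- if (family == "gamma") "gamma" else "lnorm"
  fit <- tryCatch(
    fitdistrplus::fitdist(x, distname, method = "mle"),
    error = function(e) abort(paste0("degenerate sample: ", conditionMessage(e)))
  )
  structure(
    list(family = family, estimate = fit$estimate, sd = fit$sd,
         loglik = fit$loglik, n = length(x), x = x),
    class = "duration_fit"
  )
}

#' @export
print.duration_fit <- function(x, ...) {
  cat("Duration distribution fit (", x$family, "), n = ", x$n, "\n", sep = "")
  print(round(x$estimate, 4))
  cat("log-likelihood:", round(x$loglik, 2), "\n")
  invisible(x)
}

# cumulative distribution function of a fitted family
fit_cdf <- function(fit) {
  est <- fit$estimate
  if (fit$family == "gamma") {
    function(q) pgamma(q, shape = est[["shape"]], rate = est[["rate"]])
  } else {
    function(q) plnorm(q, meanlog = est[["meanlog"]], sdlog = est[["sdlog"]])
  }
}

fit_pdf <- function(fit) {
  est <- fit$estimate
  if (fit$family == "gamma") {
    function(q) stats::dgamma(q, shape = est[["shape"]], rate = est[["rate"]])
  } else {
    function(q) stats::dlnorm(q, meanlog = est[["meanlog"]], sdlog = est[["sdlog"]])
  }
}

#' One-sample Kolmogorov-Smirnov goodness of fit
#'
#' Tests the sample against the fitted distribution with the one-sample
#' KS statistic and its asymptotic p-value. A significant result
#' (p < .05) rejects the family. The parameters having been estimated
#' from the same sample makes the plain KS p conservative (the
#' Lilliefors bias); the uncorrected p is reported deliberately, with
#' this caveat documented.
#'
#' @param x Sample to test (defaults to the sample the fit was made on).
#' @param fit A [fit_duration_dist()] result.
#' @return One-row tibble: `family`, `statistic` (D), `p_value`, `n`.
#' @examples
#' set.seed(1)
#' s <- rgamma(200, shape = 3)
#' ks_gof(s, fit_duration_dist(s, "gamma"))
#' @export
ks_gof <- function(x = fit$x, fit) {
  stopifnot(inherits(fit, "duration_fit"))
  x <- as.numeric(x)
  if (length(x) < 5) abort("insufficient sample: need at least 5 durations.")
  kt <- suppressWarnings(ks.test(x, fit_cdf(fit))) # ties at the sampling grid
  tibble(family = fit$family, statistic = unname(kt$statistic),
         p_value = kt$p.value, n = length(x))
}

#' Central and normalized moments of a duration sample
#'
#' Sample mean, second and third central moments (1/n definitions),
#' coefficient of variation `cv = sqrt(mu2)/mu1`, skewness
#' `gamma1 = mu3/mu2^(3/2)` and their ratio `gamma1/cv`. These are the
#' quantities whose constancy across conditions expresses the scaling
#' property (central moments proportional to powers of the mean). For
#' a gamma population `gamma1/cv = 2` for every shape; for a
#' log-normal, `gamma1 = cv^3 + 3*cv`.
#'
#' @param x Numeric sample, at least 3 values.
#' @return One-row tibble: `mu1`, `mu2`, `mu3`, `cv`, `gamma1`,
#'   `gamma1_over_cv`, `n`. A zero-variance sample yields `cv = 0` and
#'   undefined (`NA`) skewness.
#' @examples
#' moment_summary(c(1, 2, 3))
#' @export
moment_summary <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) abort("need at least 3 values.")
  mu1 <- mean(x)
  mu2 <- mean((x - mu1)^2)
  mu3 <- mean((x - mu1)^3)
  if (mu2 == 0) {
    return(tibble(mu1 = mu1, mu2 = 0, mu3 = 0, cv = 0,
                  gamma1 = NA_real_, gamma1_over_cv = NA_real_, n = n))
  }
  cv <- sqrt(mu2) / mu1
  gamma1 <- mu3 / mu2^1.5
  tibble(mu1 = mu1, mu2 = mu2, mu3 = mu3, cv = cv, gamma1 = gamma1,
         gamma1_over_cv = gamma1 / cv, n = n)
}

#' Assess the scaling property across conditions
#'
#' Normalizes durations (per subject x condition x percept), pools them
#' per condition, and summarizes each condition's coefficient of
#' variation and skewness-to-cv ratio with percentile bootstrap
#' confidence intervals. The scaling property holds when these
#' normalized moments are constant across conditions; constancy is
#' quantified by the maximal pairwise difference with its bootstrap
#' interval (an interval covering 0 is consistent with scaling).
#' Conditions with fewer than `min_phases` phases are dropped with a
#' warning, as higher moments are unreliable there.
#'
#' @param phases Long phase table (after exclusion).
#' @param conditions Conditions (dB) to assess; intermediate conditions
#'   by default since extreme ones have few phases.
#' @param n_boot Bootstrap replicates.
#' @param min_phases Minimal pooled phases per condition.
#' @param conf_level Confidence level of the percentile intervals.
#' @return Object of class `scaling_assessment`: list with
#'   `by_condition` (cv and gamma1/cv with CIs per condition) and
#'   `constancy` (max pairwise difference of each measure with CI).
#' @export
scaling_assessment <- function(phases, conditions = c(1, 2, 4),
                               n_boot = 1000, min_phases = 20,
                               conf_level = 0.95) {
  norm <- normalize_durations(phases, "per_subject_condition_percept")
  norm <- norm[norm$delta_i_db %in% conditions, ]
  samples <- split(norm$norm_duration, norm$delta_i_db)
  small <- vapply(samples, length, integer(1)) < min_phases
  if (any(small)) {
    warn(paste0("condition(s) ", paste(names(samples)[small], collapse = ", "),
                " dropped: fewer than ", min_phases, " phases."))
    samples <- samples[!small]
  }
  if (length(samples) < 2) {
    abort("need at least 2 conditions with enough phases.")
  }
  alpha <- (1 - conf_level) / 2
  probs <- c(alpha, 1 - alpha)

  stat <- function(x) {
    ms <- moment_summary(x)
    c(cv = ms$cv, g1cv = ms$gamma1_over_cv)
  }
  obs <- vapply(samples, stat, numeric(2))
  boots <- lapply(samples, function(x) {
    vapply(seq_len(n_boot), function(i) {
      stat(x[sample.int(length(x), replace = TRUE)])
    }, numeric(2))
  })
  by_condition <- purrr::map_dfr(seq_along(samples), function(i) {
    ci_cv <- quantile(boots[[i]]["cv", ], probs, names = FALSE)
    ci_g <- quantile(boots[[i]]["g1cv", ], probs, names = FALSE)
    tibble(
      delta_i_db = as.numeric(names(samples)[i]),
      n = length(samples[[i]]),
      cv = obs["cv", i], cv_lo = ci_cv[1], cv_hi = ci_cv[2],
      gamma1_over_cv = obs["g1cv", i], g1cv_lo = ci_g[1], g1cv_hi = ci_g[2]
    )
  })
  # signed pairwise differences with bootstrap CIs; the pair with the
  # largest absolute observed difference is the constancy summary
  conds <- names(samples)
  pair_idx <- utils::combn(seq_along(samples), 2)
  constancy <- purrr::map_dfr(
    c(cv = "cv", gamma1_over_cv = "g1cv"),
    function(row) {
      tab <- purrr::map_dfr(seq_len(ncol(pair_idx)), function(p) {
        i <- pair_idx[1, p]; j <- pair_idx[2, p]
        d_boot <- boots[[i]][row, ] - boots[[j]][row, ]
        ci <- quantile(d_boot, probs, names = FALSE)
        tibble(
          cond_a = as.numeric(conds[i]), cond_b = as.numeric(conds[j]),
          diff = obs[row, i] - obs[row, j], lo = ci[1], hi = ci[2]
        )
      })
      tab$is_max <- abs(tab$diff) == max(abs(tab$diff))
      tab
    },
    .id = "measure"
  )
  structure(
    list(by_condition = by_condition, constancy = constancy,
         n_boot = n_boot, conf_level = conf_level),
    class = "scaling_assessment"
  )
}

#' @export
print.scaling_assessment <- function(x, ...) {
  cat("Scaling-property assessment (", x$n_boot, " bootstrap replicates)\n",
      sep = "")
  print(x$by_condition)
  cat("\nConstancy (max pairwise difference):\n")
  print(x$constancy)
  invisible(x)
}
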