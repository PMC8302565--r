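#' Convert partial eta-squared to Cohen's f (and back)
#'
#' `f = sqrt(eta_p2 / (1 - eta_p2))`; e.g. a partial eta-squared of .5
#' corresponds to f = 1.
#'
#' @param eta_p2 Partial eta-squared values in \[0, 1).
#' @return Cohen's f.
#' @examples
#' eta2_to_f(c(0.25, 0.09, 0.37))
#' @export
eta2_to_f <- function(eta_p2) {
  if (any(!is.finite(eta_p2)) || any(eta_p2 < 0)) {
    abort("`eta_p2` must lie in [0, 1).")
  }
  if (any(eta_p2 >= 1)) abort("Cohen's f diverges as eta_p2 approaches 1.")
  sqrt(eta_p2 / (1 - eta_p2))
}

#' @rdname eta2_to_f
#' @param f Cohen's f values (non-negative).
#' @export
f_to_eta2 <- function(f) {
  if (any(!is.finite(f)) || any(f < 0)) abort("`f` must be non-negative.")
  f^2 / (1 + f^2)
}

check_power_spec <- function(m, alpha, epsilon, rho) {
  if (m < 2) abort("`m` must be at least 2 within levels.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (abs(rho) >= 1) abort("`rho` must lie strictly inside (-1, 1).")
  if (epsilon < 1 / (m - 1) - 1e-12 || epsilon > 1) {
    abort("`epsilon` must lie in [1/(m-1), 1].")
  }
}

#' Power of a within-subjects ANOVA F test
#'
#' Noncentral-F power for the main effect of an m-level within factor,
#' following the G*Power repeated-measures convention: numerator df
#' `(m-1) * epsilon`, denominator df `(N-1)(m-1) * epsilon`, and
#' noncentrality `lambda = f^2 * N * m * epsilon / (1 - rho)`, where
#' `rho` is the correlation among repeated measures and `epsilon` the
#' nonsphericity correction. Note the sign convention for `rho`
#' matters: a negative correlation makes `1 - rho > 1` and shrinks the
#' noncentrality; both signs are accepted and left to the caller.
#'
#' @param n_subjects Number of subjects N.
#' @param m Number of within-factor levels.
#' @param f Cohen's effect size f (alternatively supply `eta_p2`).
#' @param eta_p2 Partial eta-squared, converted via [eta2_to_f()].
#' @param alpha Significance level.
#' @param epsilon Nonsphericity correction in \[1/(m-1), 1\].
#' @param rho Correlation among repeated measures, in (-1, 1).
#' @return The power, a number in (0, 1).
#' @examples
#' anova_power(14, m = 5, eta_p2 = 0.09, rho = 0.43)
#' @export
anova_power <- function(n_subjects, m, f = NULL, eta_p2 = NULL, alpha = 0.05,
                        epsilon = 1, rho = 0) {
  if (is.null(f)) {
    if (is.null(eta_p2)) abort("supply `f` or `eta_p2`.")
    f <- eta2_to_f(eta_p2)
  }
  check_power_spec(m, alpha, epsilon, rho)
  if (any(n_subjects < 2)) abort("`n_subjects` must be at least 2.")
  df1 <- (m - 1) * epsilon
  df2 <- (n_subjects - 1) * (m - 1) * epsilon
  lambda <- f^2 * n_subjects * m * epsilon / (1 - rho)
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Smallest sample size reaching a target power
#'
#' Integer search (bisection over N in \[3, 1e6\]; [anova_power()] is
#' monotone non-decreasing in N) for the smallest number of subjects at
#' which the within-subjects ANOVA F test attains the target power.
#'
#' @inheritParams anova_power
#' @param power Target power in (0, 1).
#' @return The smallest admissible N (at least 3).
#' @examples
#' required_sample_size(m = 5, eta_p2 = 0.09, power = 0.85, rho = 0.43)
#' @export
required_sample_size <- function(m, f = NULL, eta_p2 = NULL, alpha = 0.05,
                                 power = 0.85, epsilon = 1, rho = 0) {
  if (is.null(f)) {
    if (is.null(eta_p2)) abort("supply `f` or `eta_p2`.")
    f <- eta2_to_f(eta_p2)
  }
  if (power <= 0 || power >= 1) abort("`power` must lie in (0, 1).")
  if (f <= 0) abort("target power is unreachable with a zero effect size.")
  check_power_spec(m, alpha, epsilon, rho)
  pw <- function(n) anova_power(n, m, f = f, alpha = alpha,
                                epsilon = epsilon, rho = rho)
  lo <- 3L
  if (pw(lo) >= power) return(lo)
  hi <- 8L
  while (pw(hi) < power) {
    hi <- hi * 4L
    if (hi > 1e6) abort("target power is unreachable below N = 1e6.")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= power) hi <- mid else lo <- mid
  }
  hi
}
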