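#' Tidy a within-subject ANOVA
#'
#' @param x A [rm_anova()] result.
#' @param ... Unused.
#' @return A plain tibble, one row per effect.
#' @export
tidy.rivalry_anova <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "rivalry_anova")
  out
}

#' @rdname tidy.rivalry_anova
#' @export
glance.rivalry_anova <- function(x, ...) {
  tibble(
    n_subjects = attr(x, "n_subjects"),
    dv = attr(x, "dv"),
    within = paste(attr(x, "within"), collapse = ":"),
    n_effects = nrow(x),
    any_sphericity_violation = any(x$mauchly_p < 0.05, na.rm = TRUE)
  )
}

#' Tidy a fitted duration distribution
#'
#' @param x A [fit_duration_dist()] result.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std_error`.
#' @export
tidy.duration_fit <- function(x, ...) {
  tibble(term = names(x$estimate),
         estimate = unname(x$estimate),
         std_error = unname(x$sd))
}

#' @rdname tidy.duration_fit
#' @export
glance.duration_fit <- function(x, ...) {
  tibble(family = x$family, logLik = x$loglik,
         AIC = 2 * length(x$estimate) - 2 * x$loglik, nobs = x$n)
}

#' Tidy a scaling-property assessment
#'
#' @param x A [scaling_assessment()] result.
#' @param ... Unused.
#' @return The per-condition table of normalized moments with CIs.
#' @export
tidy.scaling_assessment <- function(x, ...) {
  x$by_condition
}

#' @rdname tidy.scaling_assessment
#' @export
glance.scaling_assessment <- function(x, ...) {
  mx <- x$constancy[x$constancy$is_max, ]
  mx <- mx[!duplicated(mx$measure), ]
  tibble(
    measure = mx$measure,
    max_pairwise_diff = mx$diff,
    lo = mx$lo, hi = mx$hi,
    consistent_with_scaling = mx$lo <= 0 & mx$hi >= 0
  )
}
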