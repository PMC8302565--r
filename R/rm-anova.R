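# orthonormal contrasts spanning the space orthogonal to the intercept
orthonormal_contrasts <- function(m) {
  h <- stats::contr.helmert(m)
  h %*% diag(1 / sqrt(colSums(h^2)), ncol(h), ncol(h))
}

# Mauchly's W, its chi-square approximation and the Greenhouse-Geisser
# epsilon from contrast-space scores Z (n x k). `nd` is the covariance df.
mauchly_from_scores <- function(Z, on_degenerate = c("na", "error")) {
  on_degenerate <- match.arg(on_degenerate)
  n <- nrow(Z)
  k <- ncol(Z)
  nd <- n - 1
  if (k == 1) {
    return(list(w = 1, chisq = NA_real_, df = NA_real_, p = NA_real_,
                epsilon = 1))
  }
  S <- cov(Z)
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  degenerate <- nd < k || max(lam) <= 0 || min(lam) < max(lam) * 1e-12
  if (degenerate) {
    if (on_degenerate == "error") {
      abort("degenerate covariance: the within-subject covariance is rank deficient.")
    }
    warn("rank-deficient within-subject covariance; Mauchly test unavailable.")
    eps <- if (max(lam) > 0) sum(lam)^2 / (k * sum(lam^2)) else 1
    return(list(w = NA_real_, chisq = NA_real_, df = NA_real_, p = NA_real_,
                epsilon = eps))
  }
  w <- prod(lam / mean(lam))
  res <- mauchly_pvalue(w, k, nd)
  c(list(w = w), res, list(epsilon = sum(lam)^2 / (k * sum(lam^2))))
}

# chi-square approximation with the second-order Box correction term
# (the convention of stats::mauchly.test and car)
mauchly_pvalue <- function(w, k, nd) {
  dfc <- k * (k + 1) / 2 - 1
  rho <- 1 - (2 * k^2 + k + 2) / (6 * k * nd)
  w2 <- (k + 2) * (k - 1) * (k - 2) * (2 * k^3 + 6 * k^2 + 3 * k + 2) /
    (288 * (nd * k * rho)^2)
  z <- -nd * rho * log(w)
  pr1 <- pchisq(z, dfc, lower.tail = FALSE)
  pr2 <- pchisq(z, dfc + 4, lower.tail = FALSE)
  list(chisq = z, df = dfc, p = pr1 + w2 * (pr2 - pr1))
}

#' Mauchly sphericity test and Greenhouse-Geisser epsilon
#'
#' Tests sphericity of the within-subject covariance of an m-level
#' repeated factor (Mauchly's W with its chi-square approximation) and
#' computes the Greenhouse-Geisser epsilon from the eigenvalues of the
#' orthonormalized covariance. With m = 2 sphericity is trivially
#' satisfied and epsilon is exactly 1; in general epsilon lies in
#' \[1/(m-1), 1\].
#'
#' @param x Either an n x m matrix/data frame of subject scores (one
#'   row per subject, one column per level), or an m x m covariance
#'   matrix with `n` supplied.
#' @param n Number of subjects when `x` is a covariance matrix.
#' @return One-row tibble: `m`, `mauchly_w`, `chisq`, `df`, `p_value`,
#'   `gg_epsilon`.
#' @examples
#' set.seed(1)
#' mauchly_epsilon(matrix(rnorm(60), 20, 3))
#' @export
mauchly_epsilon <- function(x, n = NULL) {
  x <- as.matrix(x)
  if (is.null(n)) {
    # subject-score matrix
    n <- nrow(x)
    m <- ncol(x)
    if (m < 2) abort("need at least 2 levels.")
    if (n < m) abort("degenerate covariance: need at least m subjects for a full-rank estimate.")
    Z <- x %*% orthonormal_contrasts(m)
    res <- mauchly_from_scores(Z, on_degenerate = "error")
  } else {
    m <- ncol(x)
    if (m < 2) abort("need at least 2 levels.")
    if (!isTRUE(all.equal(x, t(x)))) abort("`x` must be a covariance matrix when `n` is given.")
    C <- orthonormal_contrasts(m)
    S <- t(C) %*% x %*% C
    k <- m - 1
    lam <- pmax(eigen(S, symmetric = TRUE, only.values = TRUE)$values, 0)
    if ((n - 1) < k || max(lam) <= 0 ||
        (k > 1 && min(lam) < max(lam) * 1e-12)) {
      abort("degenerate covariance: the within-subject covariance is rank deficient.")
    }
    if (k == 1) {
      res <- list(w = 1, chisq = NA_real_, df = NA_real_, p = NA_real_,
                  epsilon = 1)
    } else {
      w <- prod(lam / mean(lam))
      res <- c(list(w = w), mauchly_pvalue(w, k, n - 1),
               list(epsilon = sum(lam)^2 / (k * sum(lam^2))))
    }
  }
  tibble(m = m, mauchly_w = res$w, chisq = res$chisq, df = res$df,
         p_value = res$p, gg_epsilon = res$epsilon)
}

#' Within-subject (repeated measures) ANOVA
#'
#' Standard univariate within-subject decomposition for one or two
#' repeated factors on a complete balanced design: each effect is
#' tested against its subject-by-effect interaction error term. For
#' every effect the table reports F, the uncorrected p, partial and
#' generalized eta-squared, Mauchly's sphericity test and the
#' Greenhouse-Geisser epsilon with the GG-corrected p (computed always;
#' the convention of quoting the corrected p only when Mauchly reaches
#' significance is applied by [anova_report()]).
#'
#' Effect sizes: `eta_p2 = SS_effect / (SS_effect + SS_error_effect)`;
#' `ges = SS_effect / (SS_effect + SS_subject + sum of all error SS)`.
#'
#' @param data Long tibble, one row per subject x cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of one or two within-factor columns.
#' @param subject Name of the subject-identifier column.
#' @return Tibble of class `rivalry_anova`, one row per effect:
#'   `effect`, `df_num`, `df_den`, `statistic`, `p_value`, `ges`,
#'   `eta_p2`, `mauchly_w`, `mauchly_p`, `gg_epsilon`, `p_gg`.
#' @examples
#' set.seed(1)
#' d <- expand.grid(subject = 1:8, cond = letters[1:3])
#' d$y <- rnorm(nrow(d)) + as.integer(d$cond)
#' rm_anova(d, dv = "y", within = "cond")
#' @export
rm_anova <- function(data, dv, within, subject = "subject") {
  if (!length(within) %in% 1:2) abort("`within` must name one or two factors.")
  cols <- c(subject, within, dv)
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    abort(paste0("`data` is missing column(s): ", paste(miss, collapse = ", "), "."))
  }
  df <- as_tibble(data[cols])
  names(df) <- c(".subject", paste0(".f", seq_along(within)), ".dv")
  if (anyNA(df$.dv)) abort("missing cell: the dependent variable contains NA.")
  df$.subject <- factor(df$.subject)
  n <- nlevels(df$.subject)
  if (n < 3) abort("need at least 3 subjects.")

  fac <- lapply(seq_along(within), function(i) factor(df[[paste0(".f", i)]]))
  lev <- lapply(fac, levels)
  sizes <- vapply(fac, nlevels, integer(1))
  # cell index with the last factor varying fastest (matches kron order)
  cell <- if (length(fac) == 1) {
    as.integer(fac[[1]])
  } else {
    (as.integer(fac[[1]]) - 1L) * sizes[2] + as.integer(fac[[2]])
  }
  n_cells <- prod(sizes)
  counts <- table(df$.subject, factor(cell, levels = seq_len(n_cells)))
  if (any(counts != 1)) {
    abort(paste0(
      "missing cell: every subject must contribute exactly one value per ",
      "cell (found counts ", min(counts), "..", max(counts),
      "); aggregate replicates first."
    ))
  }
  Y <- matrix(NA_real_, n, n_cells)
  Y[cbind(as.integer(df$.subject), cell)] <- df$.dv

  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  ss_subj <- n_cells * sum((subj_means - grand)^2)
  ss_total <- sum((Y - grand)^2)

  one_effect <- function(M, name, df_num) {
    # M: n x levels matrix of subject-by-level means averaged over the
    # other factor; `mult` converts mean-squares back to raw SS scale
    mult <- n_cells / ncol(M)
    lmeans <- colMeans(M)
    ss_e <- n * mult * sum((lmeans - grand)^2)
    resid <- M - outer(rowMeans(M), rep(1, ncol(M))) -
      outer(rep(1, n), lmeans) + grand
    ss_err <- mult * sum(resid^2)
    df_den <- (n - 1) * df_num
    list(name = name, ss = ss_e, ss_err = ss_err,
         df_num = df_num, df_den = df_den,
         Z = M %*% orthonormal_contrasts(ncol(M)))
  }

  effects <- list()
  if (length(fac) == 1) {
    effects[[1]] <- one_effect(Y, within[1], sizes[1] - 1)
  } else {
    a <- sizes[1]; b <- sizes[2]
    # subject x A means (average over B), columns ordered by A level
    YA <- t(apply(Y, 1, function(y) tapply(y, rep(seq_len(a), each = b), mean)))
    YB <- t(apply(Y, 1, function(y) tapply(y, rep(seq_len(b), times = a), mean)))
    effects[[1]] <- one_effect(YA, within[1], a - 1)
    effects[[2]] <- one_effect(YB, within[2], b - 1)
    # interaction: remaining within-subject variation
    cm <- colMeans(Y)
    am <- rep(colMeans(YA), each = b)
    bm <- rep(colMeans(YB), times = a)
    ss_ab <- n * sum((cm - am - bm + grand)^2)
    ss_known <- ss_subj + effects[[1]]$ss + effects[[1]]$ss_err +
      effects[[2]]$ss + effects[[2]]$ss_err + ss_ab
    ss_ab_err <- max(ss_total - ss_known, 0)
    effects[[3]] <- list(
      name = paste0(within[1], ":", within[2]),
      ss = ss_ab, ss_err = ss_ab_err,
      df_num = (a - 1) * (b - 1), df_den = (n - 1) * (a - 1) * (b - 1),
      Z = Y %*% kronecker(orthonormal_contrasts(a), orthonormal_contrasts(b))
    )
  }

  ss_err_all <- sum(vapply(effects, function(e) e$ss_err, numeric(1)))
  rows <- purrr::map_dfr(effects, function(e) {
    ms_e <- e$ss / e$df_num
    ms_err <- e$ss_err / e$df_den
    f <- if (e$ss <= 1e-300) 0 else if (ms_err == 0) Inf else ms_e / ms_err
    p <- pf(f, e$df_num, e$df_den, lower.tail = FALSE)
    sph <- mauchly_from_scores(e$Z, on_degenerate = "na")
    tibble(
      effect = e$name,
      df_num = e$df_num,
      df_den = e$df_den,
      statistic = f,
      p_value = p,
      ges = if (e$ss + ss_subj + ss_err_all == 0) NA_real_ else
        e$ss / (e$ss + ss_subj + ss_err_all),
      eta_p2 = if (e$ss + e$ss_err == 0) NA_real_ else e$ss / (e$ss + e$ss_err),
      mauchly_w = sph$w,
      mauchly_p = sph$p,
      gg_epsilon = sph$epsilon,
      p_gg = pf(f, e$df_num * sph$epsilon, e$df_den * sph$epsilon,
                lower.tail = FALSE)
    )
  })
  attr(rows, "n_subjects") <- n
  attr(rows, "dv") <- dv
  attr(rows, "within") <- within
  attr(rows, "ss") <- list(
    subject = ss_subj, total = ss_total,
    effects = setNames(lapply(effects, function(e) c(effect = e$ss, error = e$ss_err)),
                       vapply(effects, function(e) e$name, character(1)))
  )
  class(rows) <- c("rivalry_anova", class(rows))
  rows
}

#' Effect sizes of a fitted within-subject ANOVA
#'
#' Extracts partial eta-squared (effect SS over effect-plus-own-error
#' SS) and generalized eta-squared (effect SS over effect SS plus all
#' error SS including between-subject variance) for every effect.
#'
#' @param fit A [rm_anova()] result.
#' @return Tibble with `effect`, `ges`, `eta_p2`.
#' @export
effect_sizes <- function(fit) {
  stopifnot(inherits(fit, "rivalry_anova"))
  if (all(is.na(fit$ges))) abort("undefined effect size: total sum of squares is zero.")
  tibble(effect = fit$effect, ges = fit$ges, eta_p2 = fit$eta_p2)
}

#' Reported p-values under the sphericity-correction convention
#'
#' Adds a `p_reported` column following the common reporting rule:
#' quote the Greenhouse-Geisser corrected p when the Mauchly test
#' reaches significance, otherwise the uncorrected p.
#'
#' @param fit A [rm_anova()] result.
#' @param alpha Significance level for the Mauchly test.
#' @return The input with an extra `p_reported` column.
#' @export
anova_report <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "rivalry_anova"))
  fit$p_reported <- ifelse(
    !is.na(fit$mauchly_p) & fit$mauchly_p < alpha, fit$p_gg, fit$p_value
  )
  fit
}

#' Pairwise paired t-tests with Bonferroni correction
#'
#' Two-sided paired t-test for every pair of levels of a within factor,
#' with p-values multiplied by the number of pairs and capped at 1.
#'
#' @param data Long tibble, one row per subject x level.
#' @param dv Dependent-variable column name.
#' @param within Factor column name.
#' @param subject Subject-identifier column name.
#' @return Tibble of class `rivalry_pairwise`: `level1`, `level2`,
#'   `estimate` (mean difference), `statistic`, `df`, `p_value`,
#'   `p_bonf`, `degenerate` (zero within-pair variance with unequal
#'   means). See [pairwise_matrix()] for the lower-triangular layout.
#' @export
pairwise_bonferroni <- function(data, dv, within, subject = "subject") {
  cols <- c(subject, within, dv)
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    abort(paste0("`data` is missing column(s): ", paste(miss, collapse = ", "), "."))
  }
  df <- as_tibble(data[cols])
  names(df) <- c(".subject", ".f", ".dv")
  wide <- df |>
    tidyr::pivot_wider(names_from = ".f", values_from = ".dv") |>
    dplyr::select(-".subject")
  if (anyNA(wide)) abort("missing cell: every subject needs a value at every level.")
  if (nrow(wide) < 3) abort("need at least 3 subjects per pair.")
  levs <- names(wide)
  pairs <- utils::combn(levs, 2)
  n_pairs <- ncol(pairs)
  out <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    x <- wide[[pairs[1, i]]]
    y <- wide[[pairs[2, i]]]
    d <- x - y
    if (sd(d) == 0) {
      equal <- mean(d) == 0
      tibble(level1 = pairs[1, i], level2 = pairs[2, i],
             estimate = mean(d),
             statistic = if (equal) 0 else Inf * sign(mean(d)),
             df = length(d) - 1,
             p_value = if (equal) 1 else 0,
             degenerate = !equal)
    } else {
      tt <- t.test(x, y, paired = TRUE)
      tibble(level1 = pairs[1, i], level2 = pairs[2, i],
             estimate = unname(tt$estimate),
             statistic = unname(tt$statistic),
             df = unname(tt$parameter),
             p_value = tt$p.value,
             degenerate = FALSE)
    }
  })
  out$p_bonf <- pmin(1, out$p_value * n_pairs)
  attr(out, "n_pairs") <- n_pairs
  class(out) <- c("rivalry_pairwise", class(out))
  out
}

#' Lower-triangular matrix of Bonferroni-corrected p-values
#'
#' @param pw A [pairwise_bonferroni()] result.
#' @return A square matrix with corrected p-values below the diagonal.
#' @export
pairwise_matrix <- function(pw) {
  stopifnot(inherits(pw, "rivalry_pairwise"))
  levs <- unique(c(pw$level1, pw$level2))
  m <- matrix(NA_real_, length(levs), length(levs),
              dimnames = list(levs, levs))
  for (i in seq_len(nrow(pw))) {
    m[pw$level2[i], pw$level1[i]] <- pw$p_bonf[i]
  }
  m
}
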