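proj <- function(X) X %*% solve(crossprod(X)) %*% t(X)

test_that("the SS decomposition matches direct projection matrices on a tiny design", {
  set.seed(14)
  d <- expand.grid(subject = factor(1:3), A = factor(1:3))
  d$y <- rnorm(9)
  fit <- rm_anova(d, "y", "A")
  X1 <- matrix(1, 9, 1)
  XS <- model.matrix(~ 0 + subject, d)
  XA <- model.matrix(~ 0 + A, d)
  ss_A <- sum(((proj(XA) - proj(X1)) %*% d$y)^2)
  resid <- (diag(9) - proj(XS) - proj(XA) + proj(X1)) %*% d$y
  ss_err <- sum(resid^2)
  expect_equal(fit$statistic, (ss_A / 2) / (ss_err / 4), tolerance = 1e-10)
  expect_equal(fit$df_num, 2)
  expect_equal(fit$df_den, 4)
})

test_that("with two levels F equals the squared paired t with identical p", {
  set.seed(3)
  d <- data.frame(subject = rep(1:12, 2), A = rep(c("a", "b"), each = 12),
                  y = rnorm(24))
  fit <- rm_anova(d, "y", "A")
  tt <- t.test(d$y[d$A == "a"], d$y[d$A == "b"], paired = TRUE)
  expect_equal(fit$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(fit$gg_epsilon, 1) # two levels: sphericity trivially holds
})

test_that("the two-way decomposition agrees with aov and car on F, Mauchly and GG", {
  skip_if_not_installed("car")
  set.seed(42)
  d <- expand.grid(subject = factor(1:10), A = factor(1:4), B = factor(1:3))
  d$y <- rnorm(nrow(d)) + as.integer(d$A) * 0.5 +
    as.integer(d$A) * as.integer(d$B) * 0.1
  fit <- rm_anova(d, "y", c("A", "B"))

  av <- summary(aov(y ~ A * B + Error(subject / (A * B)), data = d))
  f_aov <- c(av[["Error: subject:A"]][[1]]["A", "F value"],
             av[["Error: subject:B"]][[1]]["B", "F value"],
             av[["Error: subject:A:B"]][[1]]["A:B", "F value"])
  expect_equal(fit$statistic, unname(f_aov), tolerance = 1e-10)

  wide <- tidyr::pivot_wider(d, names_from = c(A, B), values_from = y)
  idata <- data.frame(A = factor(rep(1:4, times = 3)),
                      B = factor(rep(1:3, each = 4)))
  ca <- car::Anova(lm(as.matrix(wide[, -1]) ~ 1), idata = idata,
                   idesign = ~ A * B, type = 3)
  s <- suppressWarnings(summary(ca, multivariate = FALSE))
  expect_equal(unname(fit$mauchly_w), unname(s$sphericity.tests[, 1]),
               tolerance = 1e-8)
  expect_equal(unname(fit$mauchly_p), unname(s$sphericity.tests[, 2]),
               tolerance = 5e-3)
  expect_equal(unname(fit$gg_epsilon), unname(s$pval.adjustments[, "GG eps"]),
               tolerance = 1e-8)
  expect_equal(unname(fit$p_gg), unname(s$pval.adjustments[, "Pr(>F[GG])"]),
               tolerance = 1e-8)
})

test_that("a constant response yields zero F everywhere and subject permutation changes nothing", {
  d <- expand.grid(subject = 1:6, A = 1:4)
  d$y <- 5
  fit <- suppressWarnings(rm_anova(d, "y", "A"))
  expect_equal(fit$statistic, 0)

  set.seed(8)
  d$y <- rnorm(nrow(d))
  f1 <- rm_anova(d, "y", "A")
  relabel <- c(3, 1, 6, 2, 5, 4)
  d2 <- dplyr::mutate(d, subject = relabel[subject])
  f2 <- rm_anova(d2, "y", "A")
  expect_equal(as.data.frame(f1), as.data.frame(f2), tolerance = 1e-12)
})

test_that("missing or duplicated cells are refused", {
  d <- expand.grid(subject = 1:5, A = 1:3)
  d$y <- rnorm(15)
  expect_error(rm_anova(d[-3, ], "y", "A"), "cell")
  expect_error(rm_anova(rbind(d, d[1, ]), "y", "A"), "cell")
  expect_error(rm_anova(d[d$subject < 3, ], "y", "A"), "3 subjects")
})

test_that("p_gg is never anti-conservative and the GG-quoting rule is applied", {
  set.seed(5)
  for (i in 1:10) {
    d <- expand.grid(subject = 1:8, A = 1:4)
    d$y <- rnorm(32) + rep(rnorm(8), 4) * c(2, 1, 0.2, 0.1)[d$A] +
      c(0, 0.5, 1, 1.5)[d$A]
    fit <- rm_anova(d, "y", "A")
    # shrinking both dfs raises the upper-tail p whenever F >= 1 (the
    # regime the correction exists for; below 1 it can move either way)
    if (fit$statistic >= 1) expect_gte(fit$p_gg, fit$p_value)
    rep <- anova_report(fit)
    expected <- if (!is.na(fit$mauchly_p) && fit$mauchly_p < .05) fit$p_gg else fit$p_value
    expect_equal(rep$p_reported, expected)
  }
})

test_that("type-I error of the within-subject F is calibrated at the 5% level", {
  set.seed(99)
  rej <- vapply(1:1000, function(i) {
    d <- expand.grid(subject = 1:10, A = 1:5)
    d$y <- rnorm(50)
    rm_anova(d, "y", "A")$p_value < 0.05
  }, logical(1))
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gte(mean(rej), band[1])
  expect_lte(mean(rej), band[2])
})

test_that("Mauchly machinery honours its closed-form boundaries", {
  set.seed(6)
  # m = 2: epsilon exactly 1
  expect_equal(mauchly_epsilon(matrix(rnorm(40), 20, 2))$gg_epsilon, 1)
  # spherical population: epsilon near 1 at large n
  big <- matrix(rnorm(4000), 1000, 4)
  expect_gt(mauchly_epsilon(big)$gg_epsilon, 0.97)
  # rank-one structure: epsilon at its 1/(m-1) floor
  u <- rnorm(200)
  Y <- cbind(u, -u, u, -u) + matrix(rnorm(800, sd = 1e-4), 200, 4)
  expect_lt(mauchly_epsilon(Y)$gg_epsilon, 1 / 3 + 0.01)
  # too few subjects for a full-rank covariance
  expect_error(mauchly_epsilon(matrix(rnorm(12), 3, 4)), "degenerate")
  # the covariance-matrix entry point agrees with base R's Mauchly test
  X <- matrix(rnorm(100), 20, 5)
  mine <- mauchly_epsilon(X)
  base <- mauchly.test(lm(X ~ 1), X = ~1)
  expect_equal(mine$mauchly_w, unname(base$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, base$p.value, tolerance = 1e-3)
  from_cov <- mauchly_epsilon(cov(X), n = 20)
  expect_equal(from_cov$mauchly_w, mine$mauchly_w, tolerance = 1e-12)
  expect_equal(from_cov$gg_epsilon, mine$gg_epsilon, tolerance = 1e-12)
})

test_that("effect sizes follow their sums-of-squares definitions", {
  # no subject variance: ges equals eta_p2
  d <- expand.grid(subject = 1:4, A = 1:3)
  d$y <- c(1, 1, 1, 1, 2, 2, 2, 2, 4, 4, 4, 4) + rep(c(.1, -.1, .2, -.2), 3)
  d$y <- d$y - ave(d$y, d$subject) + mean(d$y) # remove subject variance
  fit <- rm_anova(d, "y", "A")
  es <- effect_sizes(fit)
  expect_equal(es$ges, es$eta_p2, tolerance = 1e-10)
  # SS_effect = SS_error gives eta_p2 = 1/2
  ss <- attr(fit, "ss")$effects$A
  eta_manual <- ss["effect"] / (ss["effect"] + ss["error"])
  expect_equal(unname(eta_manual), fit$eta_p2, tolerance = 1e-12)
})

test_that("pairwise paired t tests count comparisons and cap corrected p at 1", {
  set.seed(12)
  d <- expand.grid(subject = 1:8, A = letters[1:5])
  d$y <- rnorm(40) + (d$A == "e") * 3
  pw <- pairwise_bonferroni(d, "y", "A")
  expect_equal(nrow(pw), 10) # choose(5, 2)
  expect_equal(pw$p_bonf, pmin(1, pw$p_value * 10))
  expect_true(all(pw$p_bonf <= 1))
  m <- pairwise_matrix(pw)
  expect_true(all(is.na(m[upper.tri(m, diag = TRUE)])))
  expect_equal(m["b", "a"], pw$p_bonf[pw$level1 == "a" & pw$level2 == "b"])

  # identical columns: corrected p is exactly 1
  d2 <- expand.grid(subject = 1:6, A = c("a", "b"))
  d2$y <- rep(rnorm(6), 2)
  pw2 <- pairwise_bonferroni(d2, "y", "A")
  expect_equal(pw2$p_value, 1)
  expect_false(pw2$degenerate)
})

test_that("familywise error of the Bonferroni battery stays at or below alpha", {
  set.seed(77)
  fwer <- vapply(1:600, function(i) {
    d <- expand.grid(subject = 1:8, A = letters[1:5])
    d$y <- rnorm(40)
    any(pairwise_bonferroni(d, "y", "A")$p_bonf < 0.05)
  }, logical(1))
  # binomial upper band around alpha = .05
  expect_lte(mean(fwer), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 600))
})

test_that("effect-size conversion and its inverse are exact", {
  expect_equal(eta2_to_f(0.5), 1)
  expect_equal(f_to_eta2(eta2_to_f(0.37)), 0.37, tolerance = 1e-12)
  expect_error(eta2_to_f(1), "diverges")
  expect_error(eta2_to_f(-0.1), "0, 1")
})

test_that("power rises with N and the sample-size search is tight at its floor", {
  grid <- 3:40
  pw <- vapply(grid, function(n) anova_power(n, m = 5, f = 0.4, rho = 0.3),
               numeric(1))
  expect_true(all(diff(pw) >= -1e-12))
  # enormous effects hit the smallest admissible N
  expect_equal(required_sample_size(m = 5, f = 50), 3L)
  expect_error(required_sample_size(m = 5, f = 0), "unreachable")
  # minimality: one subject fewer misses the target
  n <- required_sample_size(m = 5, eta_p2 = 0.09, power = 0.85, rho = 0.43)
  expect_gte(anova_power(n, m = 5, eta_p2 = 0.09, rho = 0.43), 0.85)
  expect_lt(anova_power(n - 1, m = 5, eta_p2 = 0.09, rho = 0.43), 0.85)
})
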