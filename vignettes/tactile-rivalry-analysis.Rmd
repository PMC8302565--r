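---
title: "Analysing tactile perceptual rivalry with rivalr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing tactile perceptual rivalry with rivalr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivalr)
library(dplyr)
```

## The experiment this package analyses

In a tactile rivalry session, antiphase trains of 400 ms vibrotactile
pulses (each followed by a 400 ms silent gap) are delivered to the two
index fingers. With an intensity difference ΔI (in dB) between the
high- and low-amplitude pulses, perception alternates between two
mutually exclusive interpretations: one simultaneous vibration pattern
on both hands (SIM) or pulses jumping between hands (apparent
movement, AM). Observers hold the left arrow key while SIM dominates
and the right arrow key while AM dominates; keys are sampled at
100 Hz. A session comprises 3-minute trials at five intensity
differences (0.5, 1, 2, 4, 6 dB), each repeated three times, ordered
by rows of randomized 5 × 5 Latin squares so condition order is
counterbalanced within and across the 15 subjects.

The quantities of interest are the *dominance phases* — maximal
stretches of time with one percept reported — and three families of
statistics over them: Levelt-proposition-II condition curves, the
shape of the phase-duration distribution, and the serial correlation
of successive durations.

## From keypresses to phases

`extract_phases()` defines a phase as a maximal run of samples where
exactly one key is held. No-key and both-key samples are unreported
time and belong to no phase. Two same-percept runs separated only by
unreported time shorter than `merge_tol_s` are merged, gap included in
the duration: brief key releases are re-grips, not perceptual
switches. The default tolerance of 0.5 s is shorter than one stimulus
cycle (0.8 s), so a genuine switch-and-return can never be folded into
one phase. A phase still held at the end of the trace is flagged
*censored*: its true duration is unknown.

Censored phases are excluded from duration means by default
(`drop_censored = TRUE` throughout) but always count toward reported
time, proportions and the phase count — a trial dominated by a single
uninterrupted percept must still show up as such.

### Trial exclusion

A trial is excluded when a percept type was never reported (perception
did not alternate), or when mean percept duration falls below 4 s or
above 150 s. The floor is the stimulus' own timescale: the minimal
alternation pattern spans five pulse + gap cycles,
`stimulus_span(5, 0.4, 0.4)` = 4 s, and a "phase" shorter than that
cannot be a genuine dominance report. The ceiling flags trials whose
reported phases are so long that the trial effectively did not
alternate. The bounds can be read **per percept type** (either
percept's mean out of bounds excludes the trial; the default) or
**across all phases**; the per-percept reading is stricter — whenever
the across-percept mean is out of bounds, some percept's mean is too,
since the overall mean lies between the two per-percept means — and is
the default because the 4 s floor is motivated by a single percept's
minimal span. Both readings are exposed (`scheme =`) and both are
reported by the acceptance script. Exclusion means *include* censored
durations: the canonical non-alternating trial is one 180 s censored
phase, and it must be caught by the 150 s ceiling.

### Rebalancing and aggregation

Exclusion leaves unequal trial counts across conditions. Following the
resampling convention for this design, `rebalance()` draws per-trial
mean durations with replacement within each (condition, percept) cell
until every cell holds `target_n = 45` observations (15 subjects × 3
repetitions); the resampling unit is the per-trial mean, not the raw
phase, and no value outside a cell's observed support is ever
introduced. Subject-level aggregation (`subject_condition_means()`)
pools *all* durations across a subject's repetitions of a condition —
a subject contributing durations {10, 20} and {30} in two repetitions
has mean 20 s, not the 22.5 s a mean-of-trial-means would give.

## Levelt's proposition II

Proposition II says that increasing the difference between percept
strengths mainly lengthens the stronger percept's dominance. Here the
manipulated strength difference is ΔI: the SIM mean-duration curve
should fall with ΔI and the AM curve rise, their proportions likewise,
and the alternation rate (switches per minute of reported time) should
peak at *equidominance* — the ΔI where each percept holds half the
time. `condition_curves()` averages subject-level values per condition
(error bars are SEM across subjects; the convention is ours).
`estimate_equidominance()` finds the 0.5 crossing of the SIM
proportion curve by linear interpolation in dB — the smallest
assumption consistent with plotting these curves against dB — choosing
among multiple crossings the one nearest the alternation-rate peak,
and refusing to extrapolate: a curve that never crosses ½ returns a
boundary flag.

## Within-subject ANOVA

`rm_anova()` implements the standard univariate repeated-measures
decomposition for one or two within factors on a complete balanced
design: each effect is tested against its subject-by-effect
interaction. Alongside F and the uncorrected p it always computes:

* **Mauchly's W** per effect with three or more levels, from the
  covariance of orthonormally contrasted subject scores, with the
  chi-square approximation including the second-order Box term (the
  convention of `stats::mauchly.test` and `car`);
* **Greenhouse–Geisser ε** from the eigenvalues of that contrasted
  covariance, bounded in [1/(m−1), 1], with the corrected
  `p_gg = P(F_{ε·df1, ε·df2} > F)`;
* **partial η²** = SS_effect / (SS_effect + SS_error-of-effect) and
  **generalized η²** = SS_effect / (SS_effect + SS_subject + all error
  SS).

The reporting convention of quoting the corrected p only when Mauchly
reaches significance is deliberately kept out of the estimator and
applied by `anova_report()`. Note that ε-shrinking both degrees of
freedom raises the p-value whenever F ≥ 1 — the regime sphericity
correction exists for — but can lower it for F < 1; the correction is
not uniformly conservative and the package makes no such claim.

Post hoc comparisons (`pairwise_bonferroni()`) are plain two-sided
paired t tests per level pair with p multiplied by the number of pairs
and capped at 1; no sphericity correction is applied within pairs,
matching standard practice. Huynh–Feldt correction is not offered: the
analysis convention this package follows uses GG only.

### Power machinery

`eta2_to_f()` maps partial η² to Cohen's f = √(η²/(1−η²));
`anova_power()` evaluates noncentral-F power with
df₁ = (m−1)ε, df₂ = (N−1)(m−1)ε and noncentrality
λ = f²·N·m·ε/(1−ρ), ρ being the correlation among repeated measures;
`required_sample_size()` searches the smallest N ≥ 3 by integer
bisection (power is monotone in N). The sign convention for ρ is
consequential — λ scales with 1/(1−ρ) — and published sample sizes do
not always say which sign was entered, so ρ is an explicit argument
and both conventions are easy to run. For the reference specification
(η² = .09, m = 5, α = .05, power = .85, ε = 1, |ρ| = .43) this
machinery returns N = 17 with ρ = +.43 and N = 41 with ρ = −.43;
the acceptance script reports both rather than asserting a value.

## Duration distributions and the scaling property

Rivalry phase durations are classically well fit by gamma or
log-normal distributions, and across observers and conditions the
*shape* is conserved while the mean varies — the scaling property:
central moments proportional to powers of the mean, equivalently a
constant coefficient of variation c_v = √μ₂/μ₁ and constant skewness
γ₁ = μ₃/μ₂^{3/2}.

* `normalize_durations()` divides each duration by its group mean.
  The default grouping for pooled histograms and moments is subject ×
  condition × percept; trial × percept grouping (used by the pooled
  correlation method) is the alternative scheme. Which grouping a
  pooled histogram should use is genuinely open; we default to the
  subject-level scheme because it preserves within-subject,
  between-trial variability that trial-level normalization removes.
* `fit_duration_dist()` delegates two-parameter maximum-likelihood
  estimation to `fitdistrplus`; `ks_gof()` reports the one-sample KS
  statistic with its asymptotic p. The parameters having been
  estimated from the same sample biases the plain KS p upward (the
  Lilliefors effect) — the test is conservative for this use, which
  our Monte-Carlo tests confirm, and we report it uncorrected, as is
  conventional in this literature, rather than bootstrapping a
  corrected null.
* `moment_summary()` uses biased (1/n) central moments, matching the
  population-style definitions of the scaling relation. Closed forms
  anchor the tests: a gamma family has γ₁/c_v = 2 for every shape; a
  log-normal has γ₁ = c_v³ + 3c_v.
* `scaling_assessment()` compares c_v and γ₁/c_v across conditions
  with percentile bootstrap intervals on each condition and on every
  pairwise difference. The visual judgement "these curves are flat" is
  thereby given a quantitative wrapper — an artifact decision, flagged
  as such: intervals covering 0 are consistent with scaling. Extreme
  conditions with fewer than `min_phases = 20` pooled phases are
  dropped with a warning, since third moments are hopeless there; the
  default condition set is therefore the intermediate ΔI ∈ {1, 2, 4}.
  The iid bootstrap ignores the (weak) serial dependence of phases, a
  slight anticonservatism we accept for interval width.

## Serial correlations

Two complementary estimators of the lag-1/lag-2 Pearson correlation
between phase durations (Σ(x−μ_x)(y−μ_y)/√(Σ(x−μ_x)²Σ(y−μ_y)²)):

1. **Pooled** (`pooled_corr()`): durations are normalized to the mean
   of their percept type *within each trial* — without this, subjects
   and trials with generally long durations would induce spurious
   positive correlation — then all pairs are pooled and one
   coefficient computed, with a two-sided t-based p (a permutation p
   is available; t is the default since with hundreds to thousands of
   pairs they agree).
2. **Single-trial** (`single_trial_corr()`): the correlation is
   computed on *raw* durations within each trial having at least
   `min_pairs = 3` pairs (the smallest count with a defined t-based
   p), and the distribution of per-trial coefficients is tested
   against zero with a one-sample t. Trials below the threshold are
   skipped and counted.

Lag 1 pairs opposite percepts (SIM→AM, AM→SIM; disjoint sets that
together cover all adjacent pairs), lag 2 pairs the same percept.
Censored phases never enter pairs. First phases are included by
default — the main analysis this design follows found no first-phase
effect. Note a small-sample caveat we document rather than "fix":
within-trial centering biases per-trial Pearson coefficients downward
by O(1/n_pairs), so with ~10 phases per trial both methods recover
serial structure attenuated toward negative values; signs and
significance, the quantities interpreted, are recovered robustly (see
the package tests).

## The synthetic generator

`generate_dataset()` emulates the report stream of the experiment —
not the stimulus. Design: `build_design()` assigns each subject three
blocks, each a row of a randomized Latin square drawn from a pool of
nine distinct grids. Durations: a latent stationary Gaussian AR(2) is
quantile-transformed (Gaussian copula) to the target marginal.
Defaults, chosen once:

| parameter | default | why |
|---|---|---|
| `marginal` | gamma | classic phase-duration family; log-normal available |
| `cv` | 0.6 | the coefficient of variation rivalry data sit near |
| `mean_sim_fn`, `mean_am_fn` | 16·e^{∓0.12(ΔI−2.5)} s | log-linear Levelt-II structure crossing at 2.5 dB, so equidominance falls between the tested 2 and 4 dB; a generator default, not an empirical claim |
| `lag1_corr`, `lag2_corr` | +0.15, −0.15 | small positive lag-1, small negative lag-2 serial dependence |
| `subject_sd` | 0.3 | log-scale SD of a mean-1 multiplicative subject effect (~±35% typical spread) |
| `jitter_sd` | 0.1 s | keypress reaction-time jitter; no published gap statistics exist for this paradigm, so this is a free choice |
| `trial_length_s`, `sample_rate_hz` | 180 s, 100 Hz | the session conditions |

The AR(2) is the minimal stationary process with independently tunable
lag-1 and lag-2 autocorrelations; the Yule–Walker solution is checked
against the stationarity triangle and inadmissible pairs are rejected
with the violated condition named. Because the copula transform is
nonlinear, duration-scale correlations are attenuated relative to the
latent targets; the targets are approximate by design and the tests
assert signs and significance, not the exact values. A single root
seed expands into per-subject and per-trial substreams, so any
subject's data can be regenerated without the rest.

`render_trace()` maps SIM to the left key and AM to the right,
perturbs each internal phase boundary with truncated Gaussian jitter
(bounded by 3·`jitter_sd` and by 45% of each flanking duration, so
boundaries never reorder) and leaves the release/press gap unreported.
With zero jitter, rendering followed by `extract_phases()` recovers
every duration to within one sample period — the round-trip oracle the
tests rely on.

**What the generator does not emulate.** Real sessions contain
non-alternating trials at extreme ΔI (the main driver of trial
exclusion in real data), mixed or uncertain percepts, attention
lapses, first-phase effects and drifting response criteria. None of
these are modelled: synthetic exclusion counts are near zero, and
pooled synthetic means sit below the per-condition mean functions
because subjects with shorter durations contribute more phases.
Passing tests therefore certify the *pipeline* — that each estimator
recovers the structure the generator put in — not that real data will
show that structure.

## Numerical choices and degenerate inputs

* `cv` below 1e−8 switches to the degenerate constant-duration
  marginal instead of a numerically unstable quantile transform.
* A zero-variance sample yields c_v = 0 with undefined (NA) skewness;
  constant samples are refused by the MLE fitter with a clear error.
* Zero-variance paired differences in `pairwise_bonferroni()` give
  p = 1 when the means are equal, and a `degenerate` flag otherwise.
* Rank-deficient within-subject covariances (fewer subjects than
  effect df + 1) make Mauchly's test unavailable: the exported
  `mauchly_epsilon()` errors, while inside `rm_anova()` the W and p
  are set NA with a warning and ε is still computed from the
  eigenvalues.
* Ties introduced by the 100 Hz sampling grid would make the KS test
  warn; the warning is suppressed deliberately and the asymptotic p
  retained.
* The equidominance search tie-breaks multiple crossings by proximity
  to the alternation-rate peak and never extrapolates beyond the
  tested ΔI range.

## Scale of the shipped checks

The package's own test suite and acceptance script run the full
default experiment (15 × 5 × 3 trials of 180 s) end to end, a
510-trial run for parameter recovery, 1000-replicate null calibrations
of the ANOVA F test, and 400–500-replicate Monte-Carlo checks of the
KS and bootstrap machinery — sizes chosen so each property is measured
with useful precision while the whole battery stays fast enough to run
on every change.
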