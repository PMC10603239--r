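---
title: "Modelling the hand-blink reflex and its personality network: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the hand-blink reflex and its personality network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`hbrnet` implements a complete analysis chain for hand-blink-reflex
(HBR) data: trial-level EMG is reduced to one blink-response area (AUC,
mV·ms) per subject and hand position; five hierarchical Bayesian models
of AUC against hand position are fitted and compared by leave-one-out
cross-validation; and the per-subject parameters of the winning model
are related to PID-5 personality domains through a Bayesian Gaussian
graphical model. This vignette documents the statistical model, its
assumptions, the tunable parameters, and the design decisions taken
where the analysis protocol left genuine freedom.

## 1. The response measure

Each trial is an EMG trace sampled at 1 kHz with 200 ms of pre-stimulus
baseline and 300 ms after the stimulus onset. Preprocessing runs in a
fixed order — filter, rectify, quality control, average, integrate —
because rectification and averaging do not commute: the mean of
rectified traces retains the blink energy that the rectified mean would
cancel.

* **Filtering.** `filter_trace()` applies a zero-phase (forward–backward)
  Butterworth filter after reflection padding. The default band is
  10–500 Hz; at 1 kHz sampling the upper corner coincides with the
  Nyquist frequency, so the default reduces to a 10 Hz high-pass that
  removes drift and movement artifact while leaving the blink burst
  untouched. The exact passband of the original recordings is not
  documented; 10–500 Hz is the conventional surface-EMG band for
  orbicularis oculi, and the zero-phase implementation guarantees the
  burst latency is not shifted.
* **Quality control.** The protocol discards trials with abnormal EMG
  activity *before* the response. `qc_trials()` makes that intent an
  explicit statistic: a trial is dropped when its pre-stimulus RMS (last
  100 ms before onset) exceeds `k = 3` times the median pre-stimulus RMS
  across the same subject's trials. The median is robust to the
  artifacts being tested for; `k = Inf` disables the rule. Trials in
  which the subject simply did not blink are deliberately *retained* —
  absence of a response is data, not artifact.
* **Averaging.** Kept rectified trials are averaged pointwise within
  subject × position × recording side, and the two side averages
  (ipsilateral/contralateral eye) are then averaged.
* **AUC.** `compute_auc()` integrates the average waveform over
  [onset, onset + 130 ms] by the trapezoidal rule. At 1 kHz that window
  spans 131 samples and exactly 130 unit intervals, so a constant 1 mV
  waveform yields exactly 130 mV·ms; both endpoint samples carry weight
  ½. The 130-ms window is long enough to always contain the blink.
* **Responder criterion.** A subject × position average counts as a
  response when the mean rectified post-stimulus activity (130-ms
  window) exceeds the mean plus two SDs of the rectified pre-stimulus
  baseline. The published criterion sentence compares "post-stimulus" to
  "post-stimulus" activity — an evident typo; we read the reference
  distribution as the *pre*-stimulus baseline, which is the only
  interpretation under which the criterion discriminates anything. A
  degenerate all-zero baseline yields non-responder with a warning.

## 2. Five candidate models of position dependence

With hand positions encoded ordinally and unit-spaced (FAR = 0,
MIDDLE = 1, NEAR = 2 — so every slope is a per-step rate), the candidate
location functions are

| form | location μ(x) | parameters | response |
|---|---|---|---|
| intercept-only | β₀ | 1 | lognormal |
| linear | β₀ + β₁x | 2 | lognormal |
| quadratic | β₀ + β₁x + β₂x² | 3 | lognormal |
| piecewise | β₀ + β₁·min(x,1) + β₂·max(x−1,0) | 3 | lognormal |
| exponential | a + b·e^{cx} | 3 | normal |

The four lognormal forms model μ on the log-AUC scale with residual
scale σ; the exponential form models the mean AUC directly with normal
residuals. The piecewise form is the scientifically motivated one: its
two slopes (FtoM, MtoN) separate the response growth outside versus
inside the defensive boundary, and it nests the linear model at
β₁ = β₂ (an identity the tests assert pointwise on the likelihood).

**Hierarchy.** Every coefficient carries an independent subject-level
random effect, b_i = β + u_i with u_ij ~ Normal(0, τⱼ²). With only three
observations per subject the subject-level model is saturated, so the
model is identified through partial pooling by the priors on τ — a fact
verified by the parameter-recovery tests rather than assumed. Whether
the original analysis used correlated random effects is not
recoverable; independent effects are the default here.

**Priors.** The original analysis names no priors. Defaults here are
weakly informative on the scales involved: Normal(0, 5) on population
coefficients of the lognormal forms (log-AUC values live near 2–3);
Normal(0, 10) on the exponential form's additive and multiplicative
parameters (response scale) and Normal(0, 2) on its rate; and
half-Normal(0, 2) on every τ and on σ. All are configurable through
`default_priors()` / the `priors` argument of `fit_hbr_model()`.

**Sampling.** Models are fitted with JAGS through `rjags`, 4 chains of
5,000 iterations each including 1,000 warmup (16,000 post-warmup draws)
by default. "Iterations" is counted inclusive of warmup. The random
effects are sampled in the *non-centered* parameterization
(b = β + τ·z, z ~ N(0,1)): with weakly identified τ the centered form
mixes through a funnel and produced split-R̂ up to 1.4 on τ and σ,
whereas the non-centered form keeps all population R̂ at or below ~1.01
at the default run length. Convergence is diagnosed with rank-normalized
split-chain R̂ (maximum of bulk and folded statistics) and bulk/tail
effective sample sizes; a fit with any population R̂ above 1.05 is
returned flagged `converged = FALSE`, never silently. The exponential
model's three parameters trade off over only three positions, so its
identification is fragile; its fits frequently carry the flag, which is
the designed behaviour rather than an error.

## 3. Model comparison

`psis_loo()` implements Pareto-smoothed importance-sampling
leave-one-out cross-validation from scratch: per observation, the
importance ratios 1/p(yᵢ|θ_s) are stabilized by fitting a generalized
Pareto distribution (Zhang–Stephens profile-likelihood estimator, shape
shrunk towards 0.5 with 10 pseudo-observations) to their largest 20%,
replacing that tail by expected order statistics of the fit, and
truncating at the raw maximum. ELPD, its SE (√(n·var) of the pointwise
contributions) and LOOIC = −2·ELPD follow. Observations with Pareto
k > 0.7 are reported, not refitted.

* **Pointwise unit.** One observation is one subject × position AUC
  (165 points at n = 55). Leave-one-*subject*-out is available through
  the `group` argument (log-likelihoods summed within subject before
  smoothing) but is not the default.
* **Conditional likelihood.** Log-likelihoods are conditional on the
  subject-level coefficients. With three observations per subject some
  Pareto k exceed 0.7 — the flags are reported in the comparison table.
* **Ranking.** Higher ELPD (lower LOOIC) wins; exact ties break in
  favour of fewer parameters; models within one SE of the difference
  from the best are flagged indistinguishable.

`bayes_r2()` computes, per posterior draw, Var(fitted) / (Var(fitted) +
Var(residual)) *on the response (mV·ms) scale*, using the lognormal mean
exp(μ + σ²/2) as the fitted value — the scale on which R² for lognormal
and normal response families is comparable. Posterior predictive checks
default to the mean and SD of AUC within each position, with tail
probabilities (counted with a ½ continuity correction so they lie
strictly inside (0,1)).

## 4. The personality network

The node table joins the five PID-5 domain means (0–3 scale) with the
three per-subject posterior medians (intercept, FtoM, MtoN) from the
piecewise fit. After standardization (population-SD convention), the
precision matrix Θ of the 8 nodes gets a conjugate Wishart treatment:
prior Wishart(ν₀, I_p) with ν₀ = p + 2 (proper, weakly informative),
posterior Wishart(ν₀ + n, (I_p + YᵀY)⁻¹). Each posterior draw is
standardized to partial correlations ρᵢⱼ = −θᵢⱼ/√(θᵢᵢθⱼⱼ), and an edge
is kept when its equal-tailed credible interval excludes zero.

Three deliberate choices:

* The reference Bayesian GGM software parameterizes its prior as a
  matrix-F on the partial correlations; with no hyperparameters
  published, exact numerical agreement with it is not claimed. The
  conjugate Wishart above is a transparent simplification whose
  guard-rails are the large-sample consistency checks in the test suite
  (posterior means converge to the inverse-sample-covariance partial
  correlations, within 0.01 at n = 10⁵).
* **85% credible level** by default: deliberately broader than the
  conventional 95%, appropriate for a small sample with small expected
  association magnitudes. Under a global null this admits ≈ 15% of
  edges by construction — the calibration the tests verify.
* **Equal-tailed intervals**, not HPD: order-statistic simple and
  matching the "credibility interval" language.

## 5. What the synthetic data emulate — and what they do not

The generators reproduce the study conditions: 55 subjects, three hand
positions, five trials per position on each of two recording sides,
1 kHz sampling. Defaults for the piecewise population parameters are the
published estimates (β = (2.72, 0.02, 0.18), σ = 0.16 on the log scale).
Subject-level SDs are not reported in the source; the defaults
τ = (0.3, 0.05, 0.1) are declared values chosen to give the "wide
group-level intervals" character of the data while keeping the
population parameters recoverable at n = 55 — they are a modelling
choice, not an inferred quantity.

* **EMG traces** are Gaussian baseline noise plus a blink burst:
  Gaussian-envelope-modulated white noise centred 45 ms after onset
  (envelope SD 15 ms). The burst amplitude is calibrated by a closed
  form — each sample is Normal(0, s²) with s² = σ_b² + (A·g(t))², so its
  expected rectified value is √(2/π)·s — to make the expected extracted
  AUC equal the requested target. Only the AUC integral matters
  downstream; no attempt is made at realistic blink morphology, latency
  jitter, habituation, or stimulus-intensity titration.
* **In the end-to-end pipeline**, each subject × position target is one
  lognormal draw from the generative model (location from the subject's
  true coefficients, scale σ), and the EMG layer adds only trial-level
  measurement noise on top. The preprocessed AUC table therefore carries
  the full residual scale σ; an earlier design that set targets at the
  lognormal median produced an unrealistically small σ̂ ≈ 0.02 and
  poorly mixing fits.
* **Artifact trials** (default rate 1%, matching the reported "less
  than 1%" discard fraction) receive a pre-stimulus burst and an
  internal flag that serves as ground truth for the QC tests; the
  preprocessing never reads the flag.
* **Trait scores** are multivariate Gaussian with a planted
  partial-correlation structure (two clusters — traits and HBR
  parameters — bridged by a positive Detachment–MtoN edge, with a
  positive intercept–FtoM and negative intercept–MtoN relation inside
  the HBR cluster), affinely rescaled to the published domain means and
  SDs. They are *not* clipped to the questionnaire's 0–3 range: the GGM
  operates on standardized values and clipping would distort the
  planted partial correlations. Passing tests therefore demonstrate
  recovery under Gaussian, linearly-related data — not robustness to
  the discreteness, skew and ceiling effects of real questionnaire
  scores, nor to non-blink EMG pathologies beyond the modelled
  artifact type.

## 6. Numerical and testing choices

* Position encoding FAR/MIDDLE/NEAR → 0/1/2 makes printed slopes
  per-step rates; the generator, the design matrices and the location
  functions all share this encoding.
* The AUC window is closed at both ends ([onset, onset + 130 ms], 131
  samples); trapezoidal weights make the rectangle and triangle cases
  exact, which the tests pin down.
* Seeds propagate deterministically: every stage derives its seed from
  the global one (`derive_seed`), and per-chain JAGS RNG seeds derive
  from the MCMC seed, so a config + seed reproduces every summary
  number bit-for-bit.
* Test problem sizes: recovery and comparison tests run at the study
  scale (n = 55) with shortened chains (2 × 1,000–2,500 draws) —
  enough for the ±2-posterior-SD assertions they make; the
  acceptance-grade run uses the full 4 × (1,000 + 4,000) schedule.
  Large-sample oracles use n = 5×10⁴–10⁵ draws where closed-form limits
  are asserted. A per-parameter ±2-SD band covers ~95% of calibrated
  cases, so the multi-form recovery suite asserts aggregate coverage
  (≥ 85% of checks inside 2 SD, none beyond 3.5 SD) rather than
  demanding every single z-score stay below 2.

## 7. Known limitations

* The exponential model's identifiability is fragile by construction;
  comparisons including it rely on LOO, which remains well-defined, but
  its parameter estimates should not be interpreted when flagged.
* Conditional-likelihood LOO with saturated random effects yields
  Pareto-k warnings on a minority of observations; a moment-matching or
  refit fallback is not implemented — flagged observations are
  reported.
* The Wishart GGM is exchangeable across nodes and assumes Gaussian
  margins; with 0–3 bounded, skewed questionnaire scores a rank-based
  or copula treatment would be more faithful.
* Bayesian R² values printed for the simulated study depend on the
  synthetic noise realization and are not comparable to values obtained
  on human recordings.
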