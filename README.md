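# hbrnet

Hierarchical Bayesian modelling of the hand-blink reflex (HBR) and its
relationship to maladaptive personality traits.

## The scientific problem

The defensive peripersonal space (DPPS) is the zone around the body in
which potentially harmful stimuli evoke heightened physiological
reactivity. Its extension can be probed with the hand-blink reflex: an
electrical stimulus to the median nerve at the wrist evokes a blink
(orbicularis-oculi EMG burst) whose magnitude grows as the stimulated
hand approaches the face. Quantifying *how steeply* the response grows
between a FAR (~40 cm), MIDDLE (~20 cm) and NEAR (~4 cm) hand position
gives a per-subject measure of the DPPS boundary, which can then be
related to personality dimensions (the five PID-5 maladaptive domains:
negative affectivity, detachment, antagonism, disinhibition,
psychoticism).

`hbrnet` implements that full analysis as a tested pipeline, with a
synthetic-data module standing in for human recordings:

1. **EMG preprocessing** — zero-phase band-pass filtering, full-wave
   rectification, artifact rejection (pre-stimulus RMS rule), averaging
   within condition and across recording sides, and the blink-response
   area `AUC` (mV·ms) as the trapezoidal integral over a 130-ms
   post-stimulus window, plus a responder criterion.
2. **Five hierarchical Bayesian models** of AUC versus hand position
   x ∈ {0 = FAR, 1 = MIDDLE, 2 = NEAR}, fitted by MCMC (JAGS), each with
   subject-level random effects on every coefficient:
   * intercept-only: μ = β₀
   * linear: μ = β₀ + β₁x
   * quadratic: μ = β₀ + β₁x + β₂x²
   * piecewise: μ = β₀ + β₁·min(x,1) + β₂·max(x−1,0) — two per-step
     slopes, FAR-to-MIDDLE (FtoM) and MIDDLE-to-NEAR (MtoN)
   * exponential: μ = a + b·e^{cx}
   The first four model log-AUC (lognormal response); the exponential
   uses a normal response.
3. **Model selection** — self-contained PSIS-LOO cross-validation
   (ELPD / LOOIC with Pareto-k diagnostics), Bayesian R², posterior
   predictive checks, and rank-normalized split-chain R̂ / bulk / tail
   ESS diagnostics.
4. **Network analysis** — per-subject posterior medians of the piecewise
   parameters joined with the PID-5 domain scores into an 8-node
   Bayesian Gaussian graphical model (conjugate Wishart prior on the
   precision matrix). Edges are partial correlations
   ρᵢⱼ = −θᵢⱼ/√(θᵢᵢθⱼⱼ) whose 85% credible interval excludes zero.

## Worked example

Simulate a 55-subject study from the piecewise lognormal model
(population intercept 2.72, FtoM 0.02, MtoN 0.18, residual σ 0.16 on the
log scale; subject-level SDs 0.3/0.05/0.1) and refit it:

```r
library(hbrnet)
params <- population_params("piecewise", seed = 1)   # the defaults above
auc <- generate_auc_dataset(params, 55)
fit <- fit_hbr_model(auc, "piecewise",
                     mcmc_config(chains = 4, warmup = 1000, iterations = 5000,
                                 seed = 2))
population_summary(fit)
```

```
      parameter median   mean     sd ci_lower ci_upper rhat bulk_ess tail_ess
1     intercept 2.7657 2.7662 0.0416  2.68523    2.850 1.01      698     1159
2          FtoM 0.0386 0.0385 0.0353 -0.02956    0.108 1.00     1562     2603
3          MtoN 0.1363 0.1363 0.0354  0.06665    0.208 1.00     3005     5541
4 tau_intercept 0.2428 0.2449 0.0300  0.19206    0.310 1.00     1135     1797
5      tau_FtoM 0.0437 0.0492 0.0345  0.00216    0.128 1.00     1098     1404
6      tau_MtoN 0.0657 0.0704 0.0457  0.00279    0.171 1.01     1239     2533
7         sigma 0.1751 0.1752 0.0143  0.14695    0.204 1.00     1699     2279
```

The posterior medians sit on the generating values (well within two
posterior SDs), the FtoM interval straddles zero while the MtoN interval
is strictly positive — `posterior_prob_gt(fit, "MtoN")` returns `1.000`
here — and all R̂ are at 1.01 or below.

The full pipeline (EMG synthesis → preprocessing → five fits → LOO
comparison → network) is driven by the numbered scripts:

```sh
Rscript analysis/01_simulate.R     # traces -> auc_table.csv (~3 s)
Rscript analysis/02_fit_models.R   # five fits + comparison (~1 min)
Rscript analysis/03_network.R      # 8-node GGM (~2 s)
```

On the default seed the comparison ranks the piecewise model first
(ELPD −415.5 against −418.6 for the quadratic and −446.3 for the
intercept-only model), Bayesian R² ranges 0.63–0.82 across the five
models, and the network stage detects the planted Detachment–MtoN
bridge with a positive partial-correlation median (0.29):

```
DET-MtoN bridge edge detected: TRUE (median 0.294)
```

## Repository layout

```
R/                  package code (generators, preprocessing, models,
                    model selection, GGM, pipeline)
analysis/           numbered narrative drivers over the package
scripts/            acceptance.R (parameter-recovery reproduction)
tests/testthat/     unit, property and acceptance test suites
vignettes/          methods vignette (model, priors, design choices)
```
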