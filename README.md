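# cardiosex

Sex-specific drug-induced arrhythmogenesis: multiscale cardiac
electrophysiology simulation coupled to multi-fidelity machine-learning risk
classification, in one R package.

Drugs that block cardiac ion channels — above all the rapid delayed rectifier
potassium current I_Kr (hERG) — can prolong ventricular repolarization and
trigger early afterdepolarizations (EADs), the cellular seed of torsades de
pointes. Women develop drug-induced arrhythmia roughly twice as often as men,
yet most computational risk pipelines are calibrated on male-dominated data.
`cardiosex` is for computational cardiac electrophysiologists and
quantitative-safety-pharmacology researchers who want a desk-scale, fully
scripted pipeline that makes sex an explicit biological variable in
proarrhythmic risk assessment.

## What the package computes

1. **Sex- and layer-specific ventricular myocytes.** The O'Hara–Rudy human
   ventricular myocyte model (15 currents, 38 state variables after replacing
   the fast sodium current with the ten Tusscher 2006 formulation) is rescaled
   by a 12-target activity table (I_NaL, I_to, I_pCa, I_Kr, I_Ks, I_K1,
   I_NaCa, I_NaK, I_Kb, SR Ca²⁺ release/uptake, calmodulin buffer) per sex
   (male/female) and transmural layer (endo/mid/epi). The baseline endocardial
   model is treated as a 56% male / 44% female mixture, so
   `0.56·male + 0.44·female = 1` for every endocardial factor.
2. **Hill-equation drug block.** `β = C^h / (IC50^h + C^h)` per channel;
   currents are scaled by `(1 − β)`.
3. **Cellular sensitivity screening.** Latin-hypercube sampling of the
   seven-channel block space `[0, 0.95]⁷`, EAD/repolarization-failure
   detection (depolarizing slope > 0.1 mV/ms or potential never below
   −40 mV in the 50–1,000 ms beat window), multivariable logistic regression
   and normalized average marginal effects,
   `AME_j = mean_i b_j p_i(1−p_i) / Σ_k |AME_k|`.
4. **A 1-D transmural-cable monodomain surrogate** (20% endo / 30% mid /
   50% epi, sex-scaled conductivity from connexin43 expression, isometric
   female geometry scaling) with pseudo-ECG
   `φ_e = −∫ ∇V_m · ∇(1/‖r‖) dV`, QRS/QT extraction and an automated
   arrhythmogenicity label.
5. **Single- and multi-fidelity Gaussian-process classifiers** of the
   (β_CaL, β_Kr) plane: latent GP with Bernoulli likelihood and ARD
   squared-exponential kernel, `η ~ HalfNormal(5)`, `ℓ ~ Gamma(2, 2)`;
   two fidelities coupled by the autoregressive model
   `f_H(x) = ρ f_L(x) + δ(x)`, `ρ ~ Normal(0, 10)`. Exact MCMC by whitened
   elliptical slice sampling (latents) + adaptive Metropolis
   (hyperparameters).
6. **Active learning**: straddle-style acquisition
   `x_new = argmin |μ̂(x)| / Σ̂(x)` over seeded 1,000-point candidate pools,
   with the two-stage 25+25 low-fidelity / 10+15 high-fidelity schedule.
7. **Drug risk stratification**: the critical concentration is the smallest
   multiple of the effective free therapeutic plasma concentration at which
   the drug's concentration–block trajectory crosses the classifier's
   0.5-probability boundary; drugs whose trajectory never crosses are safe.

## Worked example

```r
library(cardiosex)

# female midwall myocyte at steady state
cell  <- build_myocyte("female", "mid")
state <- prepace(cell, pacing_protocol(n_prepace = 1000))$state
beat  <- simulate_ap(cell, state, pacing_protocol(n_prepace = 0, n_beats = 1))
apd90(beat)

# block 70% of IKr on the same cell
blocked <- apply_block(cell, block_vector(IKr = 0.7))
tr <- simulate_ap(blocked, state, pacing_protocol(n_prepace = 0, n_beats = 5))
detect_abnormality(tr)
```

Output (values printed by this code):

```
[1] 362.7012     # female midwall APD90 at 1 Hz, ms
attr(,"upstroke_time")
[1] 1
[1] TRUE         # 70% IKr block triggers repolarization abnormalities
```

The 362.7 ms APD90 is the steady-state 1 Hz action-potential duration at 90%
repolarization of the female midwall cell (the male counterpart is 307.5 ms —
females repolarize substantially more slowly); the `TRUE` label means that
blocking 70% of I_Kr drives this cell into early afterdepolarizations, the
abnormality the sensitivity screen counts.

A fast, fully synthetic classifier demo (no ODE solves):

```r
toy  <- toy_cell_female()
fit  <- run_active_learning(
  function(x) toy_screen(toy, matrix(x, ncol = 2)),
  schedule = training_schedule(25, 10, 0, 0), seed = 1,
  sampler = list(n_chains = 2, n_draws = 500, n_tune = 500))
grid <- probability_grid(fit$draws)
head(extract_boundary(grid))

drug <- drug_definition("ikr_blocker", c_eff = 1,
                        channels = list(IKr = hill_block(ic50 = 10, h = 1)))
critical_concentration(drug, fit$draws)
```

```
  beta_cal   beta_kr piece
1   0.0000 0.2142685     1
2   0.0095 0.2148051     1
...
<risk_assessment> ikr_blocker: critical concentration 2.73x C_eff at (beta_CaL = 0.000, beta_Kr = 0.214)
```

i.e. for this (toy) female cell the IKr blocker becomes arrhythmogenic at
about 2.7 times its therapeutic concentration (the toy female abnormality
boundary sits at beta_Kr ~ 0.21 on the beta_CaL = 0 axis, and
beta_Kr(2.73) = 2.73 / 12.73 ~ 0.214 crosses it).

## Caveats

The organ-scale stage of this pipeline is a one-dimensional transmural cable
(a desk-scale surrogate): QRS/QT magnitudes from a 3-D biventricular model
are not reproduced, only their sex ordering and the arrhythmogenicity
labeling. The shipped drug library contains illustrative placeholder Hill
parameters, not measured patch-clamp values. See the methods vignette
(`vignettes/cardiosex-methods.Rmd`) for the model assumptions, numerical
choices and known limitations.
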