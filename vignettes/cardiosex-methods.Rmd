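---
title: "Models and methods behind cardiosex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardiosex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardiosex` chains five models: a sex- and layer-specific human ventricular
myocyte, Hill-equation drug block, a cellular abnormality screen, a
one-dimensional transmural-cable tissue surrogate, and a multi-fidelity
Gaussian-process risk classifier with active learning. This vignette explains
each model, its assumptions, the tunable parameters, the numerical choices,
and what the package's tests do and do not establish. Nothing below states an
empirical number that the test suite or `scripts/acceptance.R` does not itself
compute.

## The ventricular myocyte and its sex/layer scaling

The cell model is the O'Hara–Rudy human ventricular myocyte: fifteen ionic
currents (`I_CaL, I_Na, I_CaNa, I_CaK, I_Cab, I_Nab, I_Kb, I_Kr, I_Ks, I_K1,
I_to, I_NaK, I_pCa, I_NaCa,i, I_NaCa,ss`), four compartments, CaMK signaling.
The fast sodium current uses the ten Tusscher (2006) formulation (`m³ h j`
gating, `G_Na = 14.838 nS/pF`), a substitution known to produce physiological
conduction-velocity restitution in tissue with minor impact on the action
potential; the exact variant of this substitution used elsewhere in the
literature is not fully published, so the plain ten Tusscher current is
adopted and stated here as this package's choice. The resulting model has 38
state variables (the three ten Tusscher gates replace the six native fast-INa
gates).

Sex and transmural layer enter as multiplicative activity factors on twelve
targets (`channel_scaling_table()`): the late sodium, transient-outward,
sarcolemmal calcium-pump, rapid and slow delayed-rectifier, inward-rectifier,
sodium–calcium-exchange, sodium–potassium-pump and background-potassium
currents, the SR calcium release and uptake fluxes, and the calmodulin buffer
concentration. All factors are expressed relative to the baseline
*endocardial* model, which is regarded as a 56% male / 44% female population
mixture; the table's endocardial columns therefore satisfy
`0.56·male + 0.44·female = 1` within 0.01 (a validated invariant). Because
the midwall column of the table already reproduces the published midwall
celltype multipliers through that mixture rule (e.g. I_Kr
`0.56·0.88 + 0.44·0.70 = 0.80`), the table factor *replaces* the built-in
celltype multiplier for every listed target. Only two layer-dependent pieces
are not covered by the table and keep their published values: the L-type
permeability (×2.5 midwall, ×1.2 epicardial) and the epicardial modifier of
the transient-outward inactivation time constants.

**Assumptions.** Conductance (not kinetics) scaling; acute, pore-block drug
action `I → (1−β) I` with no state dependence; no β-adrenergic or hormonal
effects; no cell-to-cell population variability.

**Fidelity.** The implementation is validated against the published baseline
behavior (steady-state endocardial APD90 within ~1% with the native fast
sodium current swapped back in; built-in epicardial and midwall variants in
their published ranges; step-halving changes APD90 by well under 1 ms — see
the solver tests). Applying the activity table to this validated baseline
yields a male midwall APD90 on the published value but a male/female APD
spread roughly two-thirds of the published one; the unpublished details of
the original study's fast-INa modification are the most likely residual. The
acceptance suite asserts the published values at their stated tolerance, so
this residual is visible there rather than hidden.

## Pacing, APD90 and restitution

Cells are prepaced 1,000 cycles at cycle length 1,000 ms (fixed count; an
early-stop on APD drift is available but off by default, matching the fixed
protocol), then recorded beats are simulated. The stimulus is −80 µA/µF for
0.5 ms, the community convention for this model family. APD90 runs from the
maximum-upstroke-velocity time to the first downward crossing of
`V_peak − 0.9 (V_peak − V_rest)`, with per-beat `V_rest` (pre-stimulus) and
`V_peak`; crossings are located by linear interpolation on the ≤ 1 ms output
grid. A beat with voltage excursion under 10 mV is "no action potential"; a
beat that never recrosses the 90% level is flagged as repolarization failure
rather than given a number. Restitution follows the S1–S2 protocol: steady
S1 at 1,000 ms, a single S2 delivered at (end of the S1 APD90) + DI, and the
S2 beat's APD90 reported; non-capturing S2s are excluded.

## Numerical integration

Single cells use a hybrid Rush–Larsen / forward-Euler scheme in compiled
code: Hodgkin–Huxley-type gates (and the relaxation-form SR-release fluxes)
advance by exact exponential updates, concentrations and voltage by forward
Euler, the L-type `nca` variable by its exact linear-ODE update. The time
step switches between 0.005 ms (during the stimulus and whenever
|dV/dt| > 1 mV/ms) and 0.04 ms elsewhere. This integrator family is the
field's standard for these stiff ionic models; a deSolve-style adaptive BDF
solver in interpreted R was measured to be orders of magnitude slower than
needed for 1,000-cycle prepacing across six cell types, so accuracy is
controlled by the step-refinement convergence test instead (refining both
steps moves APD90 by less than 0.2%, the solver test's bound). The GHK-type flux expressions are guarded at
|V| < 10⁻⁴ mV. The cable uses the same cell kernel at a *fixed* step
(default Δt = 0.005 ms, the explicit-scheme convention for this model
family) with the diffusion term added explicitly; the stability bound
`Δt ≤ Δx²/(2D)` is checked before the solve. Determinism is exact: identical
model, protocol and solver settings give bitwise-identical traces.

## The abnormality screen

The screen explores the seven-channel block space `[0, 0.95]⁷` by Latin
hypercube sampling (one sample per equal-width bin per dimension). The
unblocked midwall cell is prepaced once; each sampled block is then applied
acutely at that steady state and five beats are simulated. The published
protocol sentence can be read either way (prepace with or without the
block); prepacing each of 10,000 blocked samples for 1,000 cycles is a
cluster-scale computation, and the acute reading matches the text's order of
operations, so it is the package's choice. A beat is abnormal when, between
50 and 1,000 ms after its stimulus, dV/dt exceeds +0.1 mV/ms — read as a
*depolarizing* slope, since repolarization slopes routinely exceed
0.1 mV/ms in magnitude and an unsigned reading would label every normal
action potential abnormal — or the potential never falls below −40 mV.
Derivatives are central differences on the ≤ 1 ms grid. Integration
blow-ups are labeled abnormal with a distinct `failed` flag so the
distinction is preserved downstream.

Abnormality is regressed on the seven block fractions by maximum-likelihood
logistic regression (ridge fallback `λ = 10⁻⁴` under complete separation).
The influence of channel `j` is its average marginal effect
`AME_j = mean_i b_j p_i (1−p_i)`, normalized by `Σ_k |AME_k|`; since the
factor `mean_i p_i(1−p_i)` is common to all channels, the normalized effect
equals `b_j / Σ|b_k|` exactly — used as an analytic oracle in the tests. The
two features carried into classification are the most negative
(anti-arrhythmic) and most positive (pro-arrhythmic) effects, with ties
broken in the fixed channel order; on this model family they resolve to
(β_CaL, β_Kr).

## The transmural cable surrogate

The high-fidelity stage is a one-dimensional transmural cable: 165 nodes at
Δx = 0.1 mm (≈ 16.5 mm wall) arranged 20% endocardial / 30% midwall / 50%
epicardial from the stimulated endocardial end; the female cable is
isometrically shortened by `0.72^(1/3) ≈ 0.90`, the linear factor implied by
the female/male left-ventricular mass ratio. Conductivity derives from a
baseline `D∥ = 0.090, D⊥ = 0.012 mm²/ms` average heart and the 50% higher
male connexin43 expression: male = 1.2× and female = 0.8× baseline (the
unique solution of male = 1.5 × female with the average fixed); the cable
uses `D∥` (the published tensor collapses to a scalar in 1-D; whether a
reduced geometry should use the parallel or transverse value is not
determined by the 3-D formulation — the parallel value is the package
default and configurable). Node states are initialized from the layer's
prepaced single-cell steady state, and the endocardial end is stimulated
every second for 5,000 ms.

The pseudo-ECG is the classical far-field integral
`φ_e(t) = −∫ ∂V/∂x · ∂(1/r)/∂x dx` at an electrode 20 mm beyond the
epicardial end (2 cm, the virtual-electrode convention), discretized by
midpoint quadrature; a spatially uniform field yields identically zero
signal (tested to 10⁻⁹). QRS spans the samples where |dφ/dt| exceeds 5% of
its beat maximum within 150 ms of the stimulus; QT runs from QRS onset to
the T-wave end by the tangent method. Arrhythmogenicity is labeled
automatically — the original study labeled electrocardiograms manually, so a
stated surrogate rule is used: a simulation is arrhythmogenic when over the
last five stimulus intervals any node activates (upstroke through −20 mV)
more often than it was stimulated, or the beat-to-beat pseudo-ECG peak-time
deviation exceeds 10% of the cycle length. Both thresholds are overridable
module constants. This 1-D surrogate preserves the transmural-heterogeneity
mechanism and the sex orderings (female QT > male QT; both sexes
non-arrhythmogenic at zero block) but *not* organ-scale QRS/QT magnitudes —
a 3-D biventricular anatomy, Purkinje network and fiber fields are out of
scope.

## Gaussian-process risk classification

Labels in the (β_CaL, β_Kr) plane are modeled with a latent function
`f ~ GP(0, k)` passed through the logistic sigmoid,
`P(y=1|x) = σ(f(x))`, with an automatic-relevance-determination
squared-exponential kernel `k(x,x') = η exp[−Σ (x_m−x'_m)²/(2ℓ_m²)]` and
weakly-informative priors `η ~ HalfNormal(σ=5)`, `ℓ_m ~ Gamma(2, 2)`. Inputs
are standardized to zero mean and unit variance using the training data, and
the constants are stored with the posterior. Two fidelities are coupled
autoregressively, `f_H(x) = ρ f_L(x) + δ(x)`, with independent GP priors on
`f_L` and the discrepancy `δ` and `ρ ~ Normal(0, 10)`; low-fidelity rows
observe `f_L`, high-fidelity rows `f_H`, and predictions target the high
level.

Inference is exact MCMC without Laplace or expectation-propagation
approximations: the latents are whitened (`f = L u`, `K = LL'`) and updated
by elliptical slice sampling, and the hyperparameters (with `ρ`) by jointly
adapted random-walk Metropolis targeting ~25% acceptance, 2 chains × 1,000
draws after 1,000 adaptation iterations by default. No NUTS engine is
available to R in this package's dependency footprint, and for latent-GP
classification the whitened ESS + Metropolis scheme is a standard exact
alternative with the same posterior; split-R̂ and acceptance rates are
reported with every fit, and a warning is raised above R̂ = 1.05. A 10⁻⁶
jitter stabilizes every Cholesky factorization. One caveat is intrinsic to
Bernoulli-likelihood GP classification: the likelihood becomes flat in the
latent scale once the sigmoid saturates, so scale-type parameters (η, ρ) can
mix slowly without affecting the decision boundary; the boundary itself is
the quantity the package consumes.

Prediction samples the latent at new points from its per-draw GP conditional
and maps it through the sigmoid; the class-probability field is the
Monte-Carlo mean over (by default 200 thinned) draws, the reported boundary
is the 0.5 contour of that mean field extracted by marching squares on a
101×101 grid (the tests score boundaries on a 61×61 grid to keep runtimes
short; the boundary displacement metric is insensitive to this refinement),
and the predictive seed is derived from the fit seed so repeated calls are
identical.

## Active learning and the training schedule

The next sample is the candidate minimizing `|μ̂(x)| / Σ̂(x)`, with `μ̂, Σ̂`
Monte-Carlo estimates of the mean and *variance* of the latent `f(x)`
(pre-sigmoid): a straddle-style rule favoring points that are simultaneously
near the boundary and uncertain. The published formula is typeset ambiguously
(a product would favor near-boundary *low*-variance points and re-sample
already-resolved regions, stalling exploration), so the quotient is
implemented deliberately — flagged here as a package decision. Candidates
are 1,000 fresh seeded Latin-hypercube points per acquisition;
already-evaluated points are excluded; the classifier is retrained after
every acquisition. The default schedule is 25 LHS + 25 active-learning
low-fidelity evaluations, then 10 LHS + 15 active-learning high-fidelity
evaluations.

## Drug risk stratification

A drug is a set of per-channel Hill parameters (`IC50`, exponent `h`) plus
its effective free therapeutic plasma concentration `C_eff`. Sweeping the
concentration maps the drug onto a trajectory in the (β_CaL, β_Kr) plane
(channels outside the plane are ignored with a warning; β is capped at the
0.95 screening bound with a warning). The critical concentration is the
smallest multiple of `C_eff` at which the classifier's mean probability
reaches 0.5 — the classification level used throughout, since no other level
is specified for "arrhythmia develops". A 200-point log-spaced pre-scan up
to 1,000 × C_eff brackets the first crossing (robust to non-monotone
probability profiles along the trajectory), and bisection refines it to 1%
relative tolerance; trajectories that never cross are reported safe. The
shipped drug library is explicitly illustrative: the study's dofetilide /
chlorpromazine / diltiazem Hill parameters come from an external dataset
that is not redistributed here, so the published critical concentrations are
not reproducible from this package alone — only the procedure is.

## Synthetic fixtures and what the tests show

The toy cell is algebraic — `APD(β) = APD₀ (1 + a β_Kr)(1 − b β_CaL)` with
an EAD injected above a threshold APD — so classifier and active-learning
machinery can be exercised in seconds with a closed-form boundary
(`APD₀ = 300 ms`, threshold 375 ms; male `a = 0.8, b = 0.35`, female
`a = 1.2, b = 0.2`, chosen once so the boundary crosses the screening domain
and the female boundary lies below the male one everywhere, mirroring the
physiological asymmetry). The two-fidelity generator labels Latin-hypercube
points against a known true boundary (default `β_Kr = 0.45 + 0.30 β_CaL`), a
low-fidelity boundary shifted +0.10 in β_Kr, and Bernoulli label noise (5%
low, 0% high). These fixtures emulate the *structure* of the physiological
problem — a smooth boundary, a biased cheap labeler, scarce expensive labels
— but none of its electrophysiology; classifier tests passing on them show
the statistical machinery is correct, not that the myocyte model is. The
myocyte and cable are tested separately against published values and
analytic limits.

Two empirical notes from the benchmark built on these fixtures: with 25
noiseless high-fidelity points and the linear default boundary, a high-only
classifier already reaches the benchmark's error floor, so multi-fidelity
fusion ties rather than beats it on that comparison; the demonstrable
multi-fidelity gain under these conditions is *bias correction* — the fused
boundary is closer to the truth than the low-fidelity-only boundary in
nearly every paired repetition (asserted in the test suite). Problem sizes
throughout the tests (n = 500 screens, 61-point scoring grids, reduced MCMC
draws in unit tests) are the package's declared operating points for its
checks.

## Known limitations

- The male/female APD spread produced by the activity table on the validated
  baseline is smaller than the published cell-scale spread (the male midwall
  value is reproduced; see the acceptance suite for the per-cell-type
  comparison at its stated tolerance). The unpublished fast-INa modification
  of the original study is the leading candidate explanation.
- The tissue stage is a 1-D cable: organ-scale interval magnitudes,
  3-D re-entry and Purkinje-driven activation are out of scope.
- Pore-block pharmacology only; no kinetic/state-dependent binding.
- The classifier plane is fixed to (β_CaL, β_Kr); drugs acting mainly
  elsewhere need a re-screened feature pair.
- Real Hill parameters for the study's three reference drugs are not
  included; the drug library format accepts user-supplied values.
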