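---
title: "Modeling PGA-catalyzed amoxicillin synthesis: models, sensitivity, inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling PGA-catalyzed amoxicillin synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amoxkin)
```

## The system

Penicillin G acylase (PGA) condenses 6-aminopenicillanic acid (6-APA, the
beta-lactam nucleus, `C_NH`) with p-hydroxyphenylglycine methyl ester
(POHPGME, the activated acyl donor, `C_AB`) into amoxicillin (`C_AN`).
Under kinetic control the same enzyme also hydrolyzes both the ester and
the antibiotic to p-hydroxyphenylglycine (POHPG, `C_AOH`), so the product
yield is set by a race between synthesis and two hydrolysis channels.
`amoxkin` models an isothermal (25 °C, pH 6.5) stirred batch reactor in
which initial 6-APA (30–80 mM) and POHPGME (5–100 mM) are varied over a
13-experiment grid (`make_condition_grid()`).

Two competing kinetic formulations are implemented.

**Model 1 (Michaelis–Menten with competitive inhibition).** Three rates —
ester consumption `v_AB`, amoxicillin hydrolysis `v_h2`, and the
nucleophile-saturating synthesis channel
`v_S = v_AB · C_NH · Tmax / (KEN + C_NH)` — assembled into mass balances
`dC_AN/dt = v_S − v_h2`, `dC_AOH/dt = (v_AB − v_S) + v_h2`,
`dC_NH/dt = −(v_S − v_h2)`, `dC_AB/dt = −v_AB`. Ten parameters: catalytic
constants `kcat1`, `kcat2` (µmol IU⁻¹ min⁻¹), Michaelis constants `Km1`,
`Km2` (mM), inhibition constants `kAB`, `kAN`, `kAOH`, `kNH` (mM), the
6-APA adsorption constant `KEN` (mM) and the maximum conversion `Tmax`
(dimensionless, in (0, 1]).

As printed in its source, the 6-APA term in the `v_AB` denominator is
scaled by `kAOH`, although the narrative of that mechanism assigns 6-APA
inhibition to `kNH`. We implement the printed form as the default and
expose `use_knh = TRUE` as a documented switch, because faithfulness to
the printed rate law matters more than our guess about a suspected typo.

**Model 2 (acyl-enzyme equilibrium mechanism).** A quasi-steady-state
reduction of the elementary mechanism (substrate binding `KS`, acylation
`k2`, nucleophile binding `KN`, partition `k3`/`k4`/`k5`, product
equilibrium `k4`/`k_m4`/`KP`), giving closed-form derivatives for `C_AN`
and `C_AOH` with the shared denominator `k3·KN + (k4 + k5)·C_NH`; `C_NH`
and `C_AB` follow by stoichiometry. Eight parameters.

Both systems conserve `C_AN + C_NH` and `C_AB + C_AN + C_AOH` exactly in
the algebra; the test suite asserts the identities to machine precision
on random states and to 1e-4 relative along simulated trajectories.

The enzyme enters all rates as a constant activity concentration `C_E`
(IU mL⁻¹), so (µmol IU⁻¹ min⁻¹)·(IU mL⁻¹) = mM min⁻¹. Deactivation is not
modeled. Temperature/pH dependence, immobilization effects, solubility
limits and fed-batch operation are out of scope.

## Simulation

Both models are stiff for parts of the sampled parameter space, so
`simulate_batch()` integrates with backward-differentiation formulas
(`deSolve::ode(method = "bdf")`), default tolerances `rel_tol = 1e-3`,
`abs_tol = 1e-6`, on a fixed output grid of 201 equally spaced points
over 500 min. The right-hand sides are compiled (C) for ensemble and
MCMC throughput; the pure-R rate laws are the readable reference and the
two paths are cross-checked in the tests. We deliberately evaluate the
rate laws as written for negative trial states: clipping inside the RHS
breaks stiff-solver error control. Non-negativity is instead a
post-simulation check, and `check_mass_balance()` audits the two
conserved totals (default drift threshold 1e-3).

One genuine feature of the equations deserves note: Model 2's
derivatives do not depend on `C_AOH` at all, so nothing in that model
prevents POHPG from going negative. With its literature parameter values
the reverse (product-consuming) flux is strong enough that `C_AOH` drops
tens of mM below zero on most grid conditions — consistent with that
parameter set's known poor predictive performance — and `simulate_batch()`
warns rather than errors.

## The unpublished inputs and the synthetic study

The experimental time courses behind the original 13-batch study are not
published, and neither is the enzyme load. The package therefore fixes
`C_E` by a declared calibration: the smallest load giving 80% ester
conversion at 300 min on experiment 1 under Model 1 literature
parameters (`calibrate_enzyme_activity()`, a scalar root search —
conversion at fixed time is monotone in `C_E` because the system is
autonomous and linear in `C_E`). This yields `C_E ≈ 1.61` IU mL⁻¹, a
mid-course batch on the 500 min horizon. Every `C_E`-dependent result
inherits this choice.

`generate_experiment()` emulates measurements: simulate, then add
independent Gaussian noise with sd `max(0.05·C, 0.5 mM)`, truncated at
zero — a typical HPLC assay error with a floor near the quantification
limit. Sampling times default to 13 instants (0–500 min, denser early),
like realistic manual batch sampling. All four species are observed.
Truncation applies only to perturbed entries, so a zero-noise
specification reproduces the simulation exactly. What the synthetic data
do **not** emulate: chromatographic drift, detection limits beyond the
truncation, replicate structure, and any model misspecification — so
parameter-recovery tests demonstrate correctness of the inference
machinery, not that either model describes real reactors.

## Global sensitivity analysis

Parameters are sampled within ±260% of their literature values. Since
`v·(1 − 2.6)` is negative and every constant must be positive, the lower
bound is floored at `1e-3·v` (documented, configurable); the upper bound
is `3.6·v`. A Saltelli radial cross-sampling design supports the
Saltelli-2010 first-order and Jansen total-order estimators; with
second-order blocks on (the default), the design has `N(2d + 2)` rows —
36,864 for the 8-parameter model at base `N = 2048`. (For the
10-parameter model the same formula gives 45,056; the figure of 44,056
sometimes quoted for that design is inconsistent with the row-count
formula and is presumed a typo — we surface both numbers rather than
silently correcting.) The base matrix is a seeded Latin hypercube
(`lhs::randomLHS`) over the 2d-dimensional unit cube; a Sobol'
low-discrepancy sequence would converge somewhat faster but is not
available here, and the estimators are validated against analytic
linear-model and Ishigami indices in the tests.

Outputs are the four species at 201 time points under six grid
conditions chosen to span the extremes (experiments 1, 2, 6, 7, 10, 13;
configurable). Indices are computed per (parameter, species, time,
condition) and aggregated by the arithmetic mean over everything, which
is our declared reading of "mean over the 500 min interval"; screening
fixes parameters with aggregate mean `ST < 0.1` at their literature
values. Bootstrap percentile CIs (default n = 1000, 95%) resample whole
base blocks to respect the cross-sampling structure; for full
time-resolved ensembles apply them to a thinned grid — the cost is
O(n_boot · N · d · coordinates).

Two numerical decisions matter and are easy to miss:

* **Unphysical runs are dropped, not imputed.** Under these very wide
  ranges, 10–27% of Model 2 draws push `C_NH` negative, where the
  quasi-steady-state denominator can vanish; trajectories then blow up
  to magnitudes of 1e4 mM with near-arbitrary values. A run is excluded
  (with a logged count) when any |concentration| exceeds the condition's
  total conserved mass `C_NH0 + C_AB0`. Without this screen the
  aggregate indices are dominated by a handful of singular rows and do
  not stabilize with N.
* **Pairwise deletion in the estimators.** An excluded run invalidates
  only the (A, B, AB_i) triples it touches, not the whole base block —
  otherwise a 20% exclusion rate would discard essentially all blocks.

Zero-variance output coordinates (e.g. t = 0, where all trajectories
share the initial state) get indices 0 and are flagged.

At our study conditions the aggregate ranking is stable across base
sample sizes: `kcat1` clearly leads Model 1, and `KS` leads Model 2 with
`k5` negligible and the Model 1 inhibition constants `kAB`, `kAN`, `kNH`
all below the 0.1 screening threshold. The exact aggregate values of the
mid-ranked parameters depend visibly on the enzyme load, the condition
subset and the treatment of singular runs — all choices the original
study leaves unstated — so mid-rank values should be read as
configuration-dependent.

## Bayesian estimation

The posterior `π(P|Y) ∝ π(P)·π(Y|P)` is sampled by Metropolis–Hastings
with the multiplicative proposal `P* = P·(1 + ω·ε)`, `ε` i.i.d. standard
normal per component (our reading of the proposal; a scalar draw is the
alternative) and `ω = 6e-3` by default. The likelihood is independent
Gaussian over all species and times, with per-observation sd taken from
the data's recorded noise model by default and overridable (`sigma_spec`)
— the likelihood family is not stated in the source framework, and
Gaussian is the standard choice it implies. Priors default to
independent uniforms over the sensitivity bounds (always containing the
literature values); a failed simulation at a proposal yields `-Inf` and
auto-rejection. Chains start at the literature values, fixed
(screened-out) parameters never move, and everything is reproducible
given a seed.

The multiplicative kernel is mildly asymmetric; at `ω = 6e-3` the
Hastings ratio deviates from 1 by O(ω²) per component and is omitted by
default, matching the plain-Metropolis description of the method. The
exact correction is available (`hastings = TRUE`) and is what the
known-target tests use, because at test-scale `ω` the asymmetry is not
negligible. Note that this proposal can never change sign, so targets
with support crossing zero are unreachable — known-target tests
therefore use positive-support distributions.

Defaults: 50,000 iterations, 20% burn-in, single chain; acceptance rate
and simulation-failure counts are reported. Two practical notes from our
own calibration experiments on synthetic data: (i) with noise-free data
a tight `sigma_spec` should be paired with a proportionally smaller `ω`,
otherwise acceptance collapses and the chain freezes; (ii) with one
experiment's 52 observations some parameters (notably `KEN` and `Km2`)
are only weakly identified; including them in the estimated set drags
the chain along wide posterior ridges that these chain lengths cannot
traverse, degrading both point recovery and interval calibration — an
additional argument for sensitivity-based screening. Even for the
screened set, single-chain random-walk exploration leaves 95% intervals
slightly anti-conservative (the packaged 10-seed check reports coverage
in the mid-80s rather than 95%). Adaptive or gradient-based samplers
would help but are deliberately out of scope.

AIC (`−2 lnL + 2k`) and BIC (`−2 lnL + k·ln n`) are evaluated at the
posterior mean (switchable in principle to MAP-over-chain), with `k` the
number of estimated parameters and `n` all scalar observations. rRMSE is
`100·sqrt(mean((obs − pred)²))/(max(obs) − min(obs))` — the "root" is
explicit even though the metric's printed form omits the radical, since
the name fixes the intent — computed per species and averaged.
Cross-validation fits each experiment in turn, simulates all experiments
from the posterior-mean parameters, and reports the rRMSE matrix with
off-diagonal row means ranking calibration experiments.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to keep the full suite in
the tens of minutes while leaving the estimators in their asymptotic
regime: Saltelli base N = 256 with the full 201-point grid and six
conditions for the headline sensitivity numbers (N = 2048 reproduces the
published design sizes and is the pipeline default), 20,000-iteration
chains for recovery/coverage checks, and a 4×4 cross-validation subgrid
(experiments 1, 6, 11, 12). `scripts/acceptance.R` recomputes the
sensitivity aggregates from scratch at base N = 256.

## Known limitations

* The enzyme load is calibrated, not measured; all sensitivity and
  inference results are conditional on it.
* Aggregate Sobol values for mid-ranked parameters are
  configuration-dependent (see above); rankings and the
  negligible/dominant splits are the robust outputs.
* Model 2 with literature parameters leaves the physical domain
  (negative POHPG); results for that parameter set describe the
  equations, not a realizable reactor.
* Single-chain random-walk MCMC at default settings under-covers for
  weakly identified parameters; treat 95% intervals for `KEN` and `Km2`
  as approximate when they are estimated.
* rRMSE is undefined for constant observed series (zero range); such
  series raise an error rather than a silent division.
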