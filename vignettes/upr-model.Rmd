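---
title: "An integrated kinetic model of the unfolded protein response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated kinetic model of the unfolded protein response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The biological problem

Accumulation of unfolded protein (UFP) in the endoplasmic reticulum
activates the unfolded protein response (UPR) through three membrane
receptors — IRE1α, PERK and ATF6 — whose downstream programmes range from
adaptive (chaperone synthesis, folding-capacity expansion) to maladaptive
(translational shutdown, CHOP-driven apoptosis). `uprsim` implements a
deterministic ODE reconstruction of this network: 27 species in four
compartments (ER, Golgi, nucleus, cytoplasm), 62 reaction channels and 82
parameters, coupled to a condensed BAX/BAK/BH3 apoptosis switch. The model
operates under the *unmitigated stress* assumption: UFP enters at a constant
controllable rate `mUFPT` and is never cleared by a folding/ERAD feedback;
only slow, non-specific dilution balances the influx. All quantities use
arbitrary concentration and time units (acu, atu).

The three analysis questions the package is built around:

1. How does the balance between stress load and folding capacity partition
   the response into **low** (adaptive), **intermediate** (oscillatory) and
   **high** (apoptotic) activity states?
2. What delimits the oscillatory state — a pair of Hopf bifurcations on the
   PERK branch — and which parameters support high-frequency oscillation
   (mapped by ABC-SMC)?
3. Why does stepwise *preconditioning* (mild before severe stress) protect
   against apoptotic commitment while direct moderate stress does not?

# Rate laws

Four bespoke kinetic forms carry the model (module `rate_laws`):

* **Total-QSSA (extended Michaelis–Menten)** product rate,
  `tqssa_rate()`:
  \[ v = \tfrac12 k_c\!\left[S_t+E_t+K_m -
     \sqrt{(S_t+E_t+K_m)^2-4S_tE_t}\right], \]
  valid when enzyme and substrate totals are comparable and variable — the
  situation of active IRE1α complexes splicing scarce XBP1 mRNA. It is
  exactly symmetric in \(S_t, E_t\), bounded by \(k_c\min(S_t,E_t)\), and
  collapses to the classical law when \(E_t \ll S_t+K_m\). Floating-point
  round-off can push the discriminant marginally negative at \(K_m = 0\),
  \(S_t=E_t\); it is clamped at zero (guard threshold `-1e-12` relative).
* **Competitive multi-regulator transcription**, `regulation_rate()`:
  \(v = \sum_i k_{c,i} w_i / (1+\sum_j w_j)\) with occupancy weights
  \(w_i = [TF]_i/K_{m,i}\); repressors are terms with \(k_c=0\).
  Constitutive expression is an explicit activator of unit weight, so basal
  transcription is never hidden inside another constant. A gene with no
  activators is silent.
* **Hill responses**, `hill_response()`: normalised to \([0,1]\) and scaled
  by explicit rate constants at call sites, keeping units in one place.
* **Receptor activation variants**, `receptor_fluxes()`: the standard model
  (cooperative oligomerisation \(k_f R^n\), spontaneous reversion
  \(k_r R_{act}\)) plus the two UFP hypotheses — direct participation
  (\(v_{act}=k_f\,UFP\,R^n\)) and stabilisation of the active complex
  (\(v_{deact}=k_r R_{act}/(1+ext_{IRE}\,UFP)\)). The reference assembly
  uses the standard variant: steep, lag-phased activation is achieved with
  a high association rate and cooperativity alone.

# Network assembly

Each branch is a composable piece merged on the shared species
(BiP, UFP, CHOP, ATF6p50, XBP1s):

* **Receptor activation** (all three receptors): BiP partitions
  competitively between receptors and UFP (shared association rate `kfB`,
  receptor-specific dissociation rates); free monomers assemble into the
  active complex. IRE1α forms quadromers (`nIRE1 = 4`) with two catalytic
  domains per complex (`ncat = 2`); PERK is modelled with the same
  fourth-order cooperativity but much tighter BiP binding
  (`krbPERK < krbIRE1`), making it the *less* sensitive sensor — the key to
  resolving stress severity (below). ATF6 does not oligomerise.
* **IRE1α branch**: active complexes splice `mXBP1 → mXBP1s` through the
  total-QSSA law with enzyme capacity `ncat * IRE1a`; XBP1s protein
  activates BiP transcription competitively.
* **ATF6 branch**: BiP-sequestered ATF6 on the ER membrane; unbound
  monomers transfer linearly to the Golgi (`ktrATF6`) and are cleaved fast
  (`kcleave`, ratio to transfer > 10) to the transcription factor ATF6p50,
  which activates XBP1, BiP, CHOP and WFS1 with gene-specific weights
  (the "differential contribution" is encoded as distinct kc/Km pairs).
  WFS1 closes a negative feedback by enhancing ER-membrane ATF6
  degradation. Knockouts (`transfer`, `cleavage`, `wfs1`) zero exactly one
  rate constant each, leaving the network structure untouched.
* **PERK branch / translation attenuation**: a zero-order ultrasensitive
  phosphorylation cycle of eIF2α (`Kmphos, Kmdephos ≪ eIF2aT`), driven by
  active PERK and reversed by GADD34 plus the constitutive phosphatase
  CReP. ATF4 translation follows a repressing Hill response of the active
  eIF2α *level* with midpoint `kATF4` and coefficient `nh`; at the
  reference `kATF4 = 0.1 = 10%` of the pool, half-activation corresponds to
  a 90% decrease of active eIF2α. The genetic cascade
  ATF4 → CHOP → GADD34 closes the delayed negative feedback; CHOP also
  attenuates the phosphorylation rate directly (constant `kmChop`).
* **Apoptosis switch**: a condensed BAX/BAK/BH3 module with CHOP as the
  input: CHOP-activated BH3 (Bim) synthesis, BH3-driven and autocatalytic
  BAX activation, and Bcl-2-mediated deactivation with CHOP repressing
  Bcl-2 through a Hill term. Total BAX is conserved (`BAXT`); the Bcl-2
  pool responds to CHOP quasi-instantaneously (algebraic Hill), which keeps
  the module at two dynamic species while preserving the bistable,
  hysteretic structure.

Module-only builds clamp their upstream input as a *parameter* of the same
name the full model uses for the species (`PERKA`, `CHOP`), so identical
rate-law definitions serve both forms. Module builds disable receptor
turnover (receptor totals conserved) and treat total UFP as the conserved
sweep input; the chaperone bound in the BiP:UFP complex still turns over
(the complex releases its UFP while the BiP moiety is degraded), which is
what bounds the folding-capacity plateau.

# The reference parameterisation

The bundled 82-parameter set, `upr_reference_params()`, is the package's own
calibration — a synthetic reconstruction, not a transcription of an external
table. It was fixed once against the documented qualitative targets and is
not a tuning surface:

* protein–protein interactions one to two orders of magnitude faster than
  genetic regulation (time-scale separation by magnitudes, not by
  quasi-steady-state elimination);
* a steep IRE1α response with a brief lag phase;
* a 3–4-fold rise of total BiP from the unstressed state to the saturating
  plateau of the IRE1α module;
* the 90% translation-attenuation midpoint;
* a Hopf pair on the clamped PERK branch enclosing sustained oscillations;
* a bistable BAX switch whose window sits inside the range CHOP actually
  traverses, with the activation threshold near the top of that range;
* the three activity states at `mUFPT = 12 / 15 / 18` and preconditioning
  protection in the stepwise 12 → 15 → 18 protocol.

Two design points deserve comment because the published description leaves
them open:

**How stress severity is resolved.** The maximal BiP production rate (the
folding-capacity *rate* cap, set by the XBP1s-saturated mBiP promoter and
`ktlBiP`) lies between the mild and severe accumulation rates. Under mild
stress the cap exceeds the load: free UFP stays low, free BiP stays high,
and the tightly BiP-bound PERK remains silent while IRE1α runs the adaptive
programme. Under severe stress the load exceeds the cap: excess UFP
titrates BiP away, and PERK — amplifying the free-BiP drop through
fourth-order activation — switches fully on. Moderate stress sits at the
cap and hovers in the oscillatory window. The fourth-order PERK
cooperativity plus its tight BiP binding stretch a ~7-fold difference in
free-UFP excess into a ~40-fold difference in active PERK, which is what
the width of the inter-Hopf window requires.

**The ATF4-activation midpoint is an absolute eIF2α level.** Two readings
of "a 90% decrease of active eIF2α attenuates translation" are possible:
a midpoint on the phosphorylated *fraction*, or on the absolute active
eIF2α *level* (reference value 10% of the default pool). The package uses
the absolute form. With the fractional form, the Hill coefficient and the
pool size act as interchangeable sources of switch steepness and the
oscillatory region pairs high cooperativity with a *small* pool; with the
absolute form, a large pool and a low threshold both deepen the switch
crossing, so the oscillatory region pairs high cooperativity with an ample
pool and a low threshold — the co-occurrence structure reported for the
reference system. The two forms coincide exactly at the reference
configuration.

# Dynamics and numerics

Integration uses deSolve's `lsoda` (stiff-capable) with `rtol = 1e-8`,
`atol = 1e-10` and ≥ 2000 dense output points per scenario; protocol
segment boundaries are integration restarts, never smoothed. The three
canonical builds (full network, clamped PERK branch, apoptosis switch) have
hand-mirrored compiled derivative functions (`src/upr_rhs.c`) used
automatically when the model's structure matches; the generic rate-law
interpreter remains the reference path and the test suite asserts equality
of the two on random states. Structural edits silently fall back to the
interpreter.

Steady states are found by damped Gauss–Newton on the right-hand side
(tolerant of the singular Jacobians that conservation relations produce),
with long-time integration restarts as fallback; residual target `1e-10`.
Stability comes from the eigenvalues of a central finite-difference
Jacobian (relative step `1e-6`); neutral directions from conservation
relations count as stable.

The sustained-oscillation convention (the source system gives only
qualitative descriptions): discard the first 50% of the window, then
require a relative peak-to-trough amplitude above 1% of the series mean,
at least three maxima, and a last/first peak-amplitude ratio above 0.95.
Constant series renormalise to 0 in the 0–100% rescaling (declared
convention). Frequency is (number of maxima − 1) / (time between first and
last maximum).

Continuation is pseudo-arclength with a secant predictor: a single
natural-parameter step seeds the tangent, after which arclength steps adapt
— capped by the requested parameter resolution on flat segments and
released on steep (state-dominated) segments so the branch is never
stranded. Folds are traversed and refined by the vertex of a quadratic in
arclength; Hopf crossings are refined by bisection on the real part of the
crossing complex pair to `1e-8`. Limit-cycle envelopes are measured by
simulation with transient discard (limit-cycle continuation is out of
scope). Bistability uses the two-sweep quasi-static protocol: 1% parameter
increments with 500–800 atu re-equilibration, comparing the up- and
down-sweep attractors.

The reduced delay model is the two-variable ATF4/GADD34 negative-feedback
skeleton: the fast eIF2α cycle is taken at quasi-steady state
(`p = PERKA/(PERKA + kg (GADD34 + CReP))`), ATF4 switches on through a
Hill response of `p`, and GADD34 induction lags ATF4 by a discrete delay
`τ` standing in for the intervening genetic steps. Its defaults were chosen
(by a coarse search, once) so that the intermediate state is a stable
spiral at `τ = 0` and a limit cycle for `τ ≳ 5`, with the period growing in
`τ`. Delay integration uses deSolve's interpolated-history solver; the
machinery is validated against the classical onset of `x'(t) = -x(t-τ)` at
`τ = π/2`.

# The ABC-SMC oscillation scan

The scan maps the parameter region of the clamped PERK branch that supports
high-frequency oscillation. The distance is the Heaviside step on the
simulated oscillation frequency (`f ≥ ε` accepts, the boundary accepting),
with `ε` raised each generation. Defaults, chosen once:

* log-uniform priors spanning ×1/10 to ×10 around the reference values of
  `nh, kATF4, eIF2aT, CReP, extCHOP, kphos, kdephos, kmChop, kmAtff,
  PERKA`;
* 500 particles, 5 generations; first-generation threshold
  `ε₀ = 0.005 atu⁻¹` so that every generation is conditioned on genuine
  oscillation; subsequent thresholds adapt to the 60th percentile of the
  previous generation's frequencies (strictly increasing enforced);
* Gaussian perturbation kernel in log-parameter space with covariance twice
  the weighted covariance of the previous generation; importance weights
  use the standard SMC correction (uniform log-prior over the
  kernel-weighted mixture);
* frequency measured on a 1500 atu simulation at `rtol = 1e-5` (the
  frequency summary agrees with the reference tolerances to ~0.3%),
  transient fraction 0.5; non-sustained oscillation scores `f = 0`;
* full reproducibility under a fixed seed; an acceptance-rate floor of
  `1e-4` aborts with the last completed generation.

The population sensitivity matrix is computed as weighted rank-regression
scores of the frequency on the standardised log-parameter ranks — a
substitution for an unspecified published method, and labelled as such.
Note one interpretive caveat: rank-based scores measure the *strength* of
monotone association within the posterior, not the slope per decade, so a
parameter spread over a wide range with a shallow but consistent frequency
trend can still score highly. In this reconstruction the oscillation
frequency rises roughly two-fold across the inter-Hopf window, so the PERK
activity level retains a non-trivial score; see the test suite for which
population-level statements the reconstruction does and does not reproduce.

# Scenarios, verdicts, interfaces

Scenario runs start from the pre-equilibrated unstressed steady state
(computed, never hard-coded). The activity label uses sustained-oscillation
detection for the intermediate state and CHOP/translation midpoints derived
from the model's own low/high asymptotes (`mUFPT = 6` and `24`) otherwise;
ambiguous signatures are labelled `ambiguous`, never coerced. The BAX
verdict compares the final activated-BAX level against the mid-separatrix
of the apoptosis switch at the prevailing CHOP level (branches located by
settling the standalone switch from both extremes; configurable).

Models serialise to SBML Level 2 Version 4 with genuine MathML kinetic
laws plus a structured annotation in the package namespace; the importer
reconstructs rate laws from the annotation and refuses — naming the
element — documents outside the package's rate-law registry. Trajectories,
diagrams and ABC populations write to tidy CSV with JSON metadata; scenario
configurations are YAML. A thin command-line wrapper over these functions
ships in `inst/cli/uprsim.R`.

# What the reconstruction does and does not show

All behavioural targets above are reproduced and continuously tested at
the reference parameterisation; problem sizes in the test suite (2000–4000
atu scenario windows, 24-point bifurcation grids, a 500-particle scan) were
chosen as the smallest that resolve each property cleanly. Three honest
limitations:

* The supplement-level species/reaction listing of the source system was
  not available to this reconstruction; the network topology follows the
  main-text constraints, and the parameter values are the package's own
  calibration. Quantities not pinned by a documented target (absolute
  concentrations in acu, individual rate constants) should not be read as
  estimates of the original model's values.
* The ATF6 transfer-knockout is reproduced in *direction* (cleaved ATF6
  abolished, membrane ATF6 accumulating and diverting BiP) but not in
  *magnitude*: with receptor pools matched to each other (~2 acu) and a
  chaperone pool an order of magnitude larger, membrane ATF6 cannot divert
  enough BiP to activate IRE1α at zero UFP. A stably high, UFP-independent
  activation level after transfer inhibition would require receptor and
  chaperone pools of comparable size.
* The population-level sensitivity ranking of the oscillation frequency
  depends on the (substituted) sensitivity method; in this reconstruction
  the frequency is genuinely not flat across the intermediate window, and
  the PERK activity level does not rank among the least sensitive
  parameters.
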