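---
title: "Model, calibration and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, calibration and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvinact)
```

## The kinetic scheme and its assumptions

`kvinact` models a Kv1 channel in which fast N-type inactivation
(open-pore block by the amino terminus) is coupled to slow C-type
inactivation of the outer pore.  The state graph is

```
C0 = C1 = C2 = C3 = O = P = N = NC
                     \
                      Cf
```

with `O` (open) and `P` (pre-block: amino terminus docked at the T1
window, pore still conducting) carrying ionic current.  `N` is the
pore-blocked state, `NC` the blocked-and-C-type-inactivated state reached
from `N`, and `Cf` a C-type state entered directly from `O` — the only
inactivation path in amino-terminal deletion (`kv_scheme_dn()`) presets,
and switched off (`kci0 = 0`) in wild-type-like presets, where C-type
entry through the blocked state dominates.  Making the pre-block state
conducting encodes the idea that occlusion, not docking, stops current;
its transitions carry no gating charge (whether docking itself
immobilizes some charge is left out deliberately — the data constrain it
only qualitatively).

Assumptions worth stating explicitly:

* **Charge layout.**  Three identical sensor steps of 3 e0 and a
  concerted opening step of 4 e0, 13 e0 per channel in total
  (Shaker-like).  The e-fold voltages are chosen consistently with the
  assigned charges (`Va = Vb = 2*25.7/3` mV, `Voa = Vob = 2*25.7/4` mV,
  thermal voltage 25.7 mV), so the equilibrium steepness and the
  integrated gating charge agree.
* **Voltage dependence.**  Sensor and opening rates are exponential in
  `V - Vshift`.  Docking, block/unblock and C-type *entry* are voltage
  independent — this is what makes the decay time constant flat above
  +20 mV, as observed.  C-type *recovery* (`kcr`, `kcr0`; values defined
  at −80 mV) carries an optional mild voltage dependence
  `exp(-(V+80)/Vcr)`.  This is a deliberate design choice: a strictly
  voltage-independent two-state C-step cannot simultaneously produce a
  multi-second decay at +40 mV with ~75 % inactivation *and* an equally
  fast recovery at −80 mV, which is exactly the combination the ΔN
  observables demand.  The calibrated e-fold voltage comes out near
  74 mV — a weak dependence of the kind commonly reported for C-type
  recovery.  `Vcr = Inf` (flat) is the default and is kept wherever the
  data do not require otherwise (e.g. the I8Q preset).
* **Modulators.**  External K⁺ scales C-entry by `1/(1 + K_out/K_K)`
  (reciprocal form for U-type-like presets via `u_type`), Zn²⁺ scales it
  by `1 + eta_Zn*Zn/(K_Zn + Zn)` (defaults `K_Zn = 100` µM,
  `eta_Zn = 1.3`, set once from the ΔN Zn²⁺ decay acceleration), and K⁺
  multiplies the unblock rate by `1 + theta_push*K_out/(K_out + K_K)`
  (`theta_push = 0.5`; the push-off is reported only qualitatively, so a
  small gain applied at all voltages is the simplest faithful choice —
  no voltage threshold is introduced because none is reported).
  `K_K` is a per-preset constant: the suppression ratio between 2 and
  98 mM K⁺ is capped at 49 as `K_K → 0`, and the wild-type/I8Q data need
  nearly that cap (`K_K = 0.5` mM) while the ΔN decay slows only ~2-fold
  in high K⁺ (`K_K` calibrates to ~47 mM).  A single shared constant
  cannot express both, and the two pathways (through the blocked pore
  vs. from the open state) are not assumed to share a K⁺ site.
* **Driving force.**  Ohmic, `I = g (p_O + p_P)(V - E_K)` with `E_K`
  from the Nernst equation (`K_in = 100` mM, approximating a K-MES
  internal solution); no Goldman rectification.  Units are ms, mV,
  1/ms, e0 per channel; currents are per channel times unit conductance.
* **Sweep independence.**  Every sweep starts from the stationary state
  at the holding potential, emulating the 20–60 s inter-sweep rests used
  experimentally.

## Calibration from table observables

The channels are characterized in the literature by fitted observables,
not rate constants, so every preset is produced at run time by
`calibrate_preset()` from the stored observable table
(`kv_observables()`).  The procedure has two layers:

1. **Algebraic seed.**  The fast decay τ and conducting fraction fix the
   block rates through `two_state_block()` (`τ = 1/(α+β)`,
   fraction `= β/(α+β)`); the slow decay τ, slow-component fraction and
   st/peak fix C-entry and C-recovery through the three-state
   quasi-steady relations; recovery τ's fix the exit rates after
   accounting for the escape-vs-re-entry branching at −80 mV.
2. **Pipeline refinement.**  The seed is polished by simulating the
   *actual* protocol (1-s or 10-s step, two-pulse family), re-measuring
   each observable through `analyze_decay()` / `analyze_recovery()`, and
   correcting the rates multiplicatively (iterative proportional
   fitting, or per-pair secant steps with clamped step size).  Measuring
   through the pipeline absorbs every systematic bias — activation rise,
   finite fit windows, component selection — which is why the
   re-simulated observables land within a fraction of a percent of the
   printed values rather than merely within the analytic approximation.

Structural constants are fixed per channel rather than fitted: the
wild-type preset has a stable pre-block (`kd/ku = 4`, so a docked
terminus usually blocks before undocking), the I8Q preset an unstable one
(`kd/ku = 0.25`).  This single difference reproduces the qualitative
phenotype set: strong cumulative inactivation and ~40 % gating-charge
immobilization at −80 mV for the wild type versus nearly complete charge
recovery for I8Q and ΔN, and the transient dip of the tandem-pulse ratio
at a −40 mV inter-pulse potential (open/pre-block channels convert to
blocked ones before deactivating).

Gating presets (`kv_gating_preset()`) force `g = 0` (the analogue of the
non-conducting pore mutation used to record gating currents) and
shift-calibrate `Vshift` so the *measured* Q-V midpoint of the standard
10-ms step family matches the published value; because every
voltage-dependent rate depends on `V - Vshift`, the whole Q-V curve
translates exactly and one secant step suffices.

## Numerical choices

* **Propagation.**  `propagate()` solves `dp/dt = pQ` by eigendecomposing
  the generator and evaluating all grid times at once, falling back to
  scaling-and-squaring matrix-exponential stepping (`Matrix::expm`) when
  the eigenbasis is ill-conditioned.  Conservation is enforced to 1e-9
  at every sample; tests cross-check against `deSolve::lsoda` at 1e-8
  and against the exact Gillespie sampler at three Monte-Carlo standard
  errors.
* **Sampling grids.**  Base interval 0.1 ms for sweeps up to 2 s, 1 ms
  beyond; every segment gets at least 10 samples; pulse segments whose
  peaks are measured are sampled at ≤0.25 ms.  Gating sweeps prepend a
  dense head (5 µs for the first millisecond of each segment) because
  gating transients relax orders of magnitude faster than the command
  sampling and trapezoidal charge integrals would otherwise miss the
  spike.  The acquisition rate of the original recordings is not stated
  anywhere; these grids are the package's own choice.
* **Exponential fits.**  Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  a multi-start ladder on the time constants around the crude 1/e
  crossing (five seeds for two components), amplitudes solved linearly
  for each seed; best SSE wins, ties go to the smaller τ ratio; τ's are
  bounded positive.  Decay fits start at the peak sample and are
  re-referenced to it; recovery fits keep the interval axis origin at
  zero because `init = 1 - Σ|A_i|` is an extrapolation to interval 0.
  Fits are unweighted and `Y0` unconstrained (the original analysis does
  not state otherwise).
* **Component selection.**  Two components are reported iff the
  two-exponential SSE improves on the single fit by >10 %, both
  amplitudes exceed 2 % of the peak (or plateau), and τ2/τ1 > 3; the
  rule is deterministic.  Traces relaxing by <2 % of peak are classed
  non-inactivating.  The tandem-pulse ratio "1 ms after the pulse" is
  reported both from the fit and as the raw shortest-interval ratio,
  since the original extrapolation method is ambiguous.
* **P/n subtraction.**  Subtraction sweeps are simulated (not assumed
  ideal) from the −140 mV subtraction holding potential, so the charge
  they move is computed and attached to the corrected trace as the
  procedure's error term.
* **Degenerate inputs.**  Reducible generators (e.g. `kci0 = 0` cutting
  off `Cf`) are handled component-wise with a warning in
  `steady_state()`, and holding-state initialization restricts to the
  component containing the resting closed state.  A preset with
  `kd = 0` can never populate the pre-block/blocked branch.

## The synthetic-data generator

`generate_dataset()` emulates the study's recordings: noiseless
model traces plus (i) additive Gaussian noise scaled to the sweep peak
(default σ = 1 %), (ii) optional linear leak and bi-exponential
capacitive transients (present only to exercise the P/n correction), and
(iii) per-oocyte variability as log-normal multipliers (default CV 10 %)
on all rate constants, mirroring the mean±SD spread of the pooled
tables.  Truth manifests are JSON sidecars; analyses never read truth
from trace files.  What the generator does *not* emulate — endogenous
oocyte currents, series-resistance and clamp-speed artifacts,
temperature variation, expression-level differences beyond rate jitter —
bounds what a passing round-trip shows about real data: it validates the
analysis pipeline and the internal consistency of the model, not the
biological uniqueness of the fitted scheme.

## Problem sizes

The test and acceptance runs use single sweeps of 1 s (0.1–0.25 ms
sampling) and 10 s (1 ms), two-pulse families of 7–13 sweeps with
intervals up to 30 s, gating families of 11–20 sweeps of 10-ms pulses,
Gillespie ensembles of 1e4–1e5 trajectories on ≤4-state reductions, and
replicate ensembles of 10–12 oocytes — sizes chosen to match the study's
protocols while keeping a full run in well under a minute.

## Known limitations

* Single-channel dwell-time statistics, permeation/GHK effects and
  temperature dependence are out of scope.
* The U-type-like inversion of the K⁺ effect (`u_type`) is qualitative:
  its magnitude is uncalibrated because the source data constrain only
  the direction.
* The wild-type steady/peak ratio in ND96 trades off against the
  recovery observables (a strongly coupled scheme drains the conducting
  plateau below the printed 0.078 ± 0.045 by 1 s); calibration
  prioritizes the time constants, and the simulated st/peak stays within
  the reported spread.
* Whether wild-type channels also use the direct `O = Cf` path is left
  open in the source; presets enable it only for ΔN-derived schemes.
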