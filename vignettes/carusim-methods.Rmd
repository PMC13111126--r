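---
title: "Hybrid stochastic/deterministic calcium release units: model and methods"
author: "caruSim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid stochastic/deterministic calcium release units: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Calcium release in ventricular myocytes happens in thousands of microdomains
where a handful of L-type calcium channels (LCCs) face a cluster of
ryanodine receptors (RyR2) across a tiny dyadic cleft.  Calcium entering
through the LCCs triggers a much larger, regenerative release from the
sarcoplasmic reticulum (SR) — calcium-induced calcium release (CICR).
Whole-cell models average over all of this with deterministic
Hodgkin–Huxley (HH) gates; subcellular models simulate each stochastic
cluster.  `caruSim` implements a bridge between the two: a single
*aggregate calcium release unit* whose LCC and RyR populations are
continuous-time Markov chains with an adjustable number of channels
`NLCC` (with `NRyR = r * NLCC`, `r = 5` by default).  At small channel
numbers the unit behaves like one noisy microdomain; as the populations
grow the binomial fluctuations vanish and the model converges to its
deterministic mean-field limit.  The scientific question the package's
protocols address is *where* that transition happens, and whether it
survives phosphorylation and LCC-regulation interventions.

## Model structure

The host cell model is a standard human ventricular endo/epicardial
formulation: membrane potential obeys `Cm dV/dt = -Iion + Ist` with the
usual twelve-current decomposition (`INa`, `IK1`, `Ito`, `IKr`, `IKs`,
`ICaL`, `INaCa`, `INaK`, `IpCa`, `IpK`, `IbCa`, `IbNa`), HH gates for the
background currents, dynamic intracellular Na⁺/K⁺, and a three-compartment
calcium system (cytosol, SR, subsarcolemmal space) with instantaneous
buffering.  All of its numeric constants live in one versioned table,
`inst/extdata/cell-parameters.tsv`, with a provenance column
(`reference model` | `rate table` | `package`).  Two pieces are replaced
by Markov-chain channel populations:

**The 7-state LCC scheme.**  The published functional forms of the
original fitted scheme were not available to this implementation, so the
scheme is constructed from the reference model's own L-type gate rate
functions — activation `d`, slow and fast voltage inactivation `f`, `f2`,
and calcium-dependent inactivation `fCass` — using the HH identities
`x⁺ = x_inf/tau_x` (opening) and `x⁻ = (1 - x_inf)/tau_x` (closing):

```
C  <->  C'  <->  O  <->  If2  <->  If        (voltage ladder)
        |        |
       IC       ICa                          (closed-state / Ca inactivation)
```

* `C -> C'` and back carry `d⁺`/`d⁻`; the final opening `C' -> O` is
  `phi * x7 * d⁺` and its reverse `x7 * d⁻` (`x7 = 2`, a fitted
  dimensionless time-scale of the final step).
* `O <-> If2` carries `eta * f2⁻` / `f2⁺`; the deep step `If2 <-> If`
  carries `cf * eta * f⁻` / `cf * f⁺` with `cf = fSlowScale = 2.5`, a
  fitted time-scale that compensates the serial ladder's reduced source
  pool (only the `If2` sub-pool feeds deep inactivation, so the bare rate
  under-drains the channel); `cf` cancels from the step's equilibrium.
* `O <-> ICa` carries `fca⁻`/`fca⁺`; `C' <-> IC` carries `eta * f⁻`/`f⁺`.

The regulation multiplier `eta` scales exactly the voltage-inactivation
closing rates `f⁻` and `f2⁻` (`eta < 1` upregulates the channel — slower
inactivation, more calcium entry; `eta > 1` downregulates it).  The
phosphorylation multiplier `phi` scales exactly the final opening
transition.  The whole-cell current uses the
Goldman–Hodgkin–Katz form with `deltaV = V - 15` mV and the *open
fraction* of the population, so the deterministic current is independent
of `NLCC` — a literal product with the channel count would grow without
bound and could never converge to a deterministic limit.

Calibration of the two fitted time-scale constants (`x7`, `fSlowScale`)
was done once against the reference deterministic model's behavior (peak
L-type current around −9 pA/pF during the action potential, APD90 near
300 ms, peak calcium transient near 1–2 µM, diastolic SR load
3.5–4 mM) and not revisited afterwards.

**The 4-state RyR scheme** (`R` resting, `O` open, `I` inactivated, `RI`
resting-inactivated).  Opening edges `R -> O` and `RI -> I` carry
`k1 * Cass^2`; calmodulin-like inactivation `R -> RI` and `O -> I` carry
`k2 * Cass`; the reverses carry the constants `k3` and `k4`.  SR load
enters through `kcasr = maxsr - (maxsr - minsr)/(1 + (EC/CaSR)^2)`, which
*decreases* from 2.5 (depleted SR) to 1.0 (overloaded SR); `k1 = phi *
k1'/kcasr` and `k2 = k2' * kcasr * gamma`, so a fuller SR opens the
channel more easily (luminal facilitation) and inactivates it less.  The
printed transcription of `k1'kcasr` is typographically ambiguous between
product and quotient; the quotient is the only orientation consistent with
luminal facilitation and with the reference model, and a parameter switch
(`kcasrLiteral`) exposes the literal product for sensitivity checks.
`gamma` defaults to 1 and is a configuration hook only.

Two deliberate parameter decisions:

* `k4` (recovery from inactivation) uses the reference model's
  0.005 ms⁻¹.  The alternative printed value 1.5×10⁻⁵ ms⁻¹ implies a
  ~67 s recovery time; integrated deterministically it collapses release
  (the per-beat release integral falls from 1.94 to 0.03 mM while the SR
  overloads past 8 mM), which contradicts the steady robust control
  release this model family is defined by.  The table value remains
  reachable through the parameter file.
* `ryrTimeScale = 8` multiplies both directions of the `R <-> O` and
  `RI <-> I` pairs.  The reference model treats open gating as an
  *instantaneous equilibrium* `O = k1 Cass² R̄/(k3 + k1 Cass²)`; a literal
  4-state chain with the bare rates relaxes toward that equilibrium with
  a 10–16 ms time constant, which lags the 2–5 ms trigger window and
  flattens the regenerative release spike (peak release flux 0.037
  instead of 0.16 mM/ms, arriving 40 ms late).  Scaling a reversible
  pair leaves every equilibrium ratio untouched and restores the
  quasi-equilibrium limit; 8 was fitted once against the reference
  release kinetics.

**Stochastic propagation.**  At each global step (`dt = 0.001` ms; rates
frozen at the step's initial state) every state with `n` channels and
total outgoing rate `ktot` loses `Binomial(n, 1 - exp(-ktot dt))`
channels, partitioned over its outgoing transitions by a multinomial with
weights `k_i/ktot`.  This reproduces the per-transition binomial marginals
to `O(k dt)` while making negative populations impossible by construction
and conserving channel number exactly — the collision rule for competing
transitions is a design choice; per-edge independent binomials could
overdraw a state.  Every run uses one seeded generator; equal seed and
configuration give bit-identical trajectories.  In deterministic mode the
same chains are integrated as mean-field occupancy fractions
(`dx_i/dt = sum_j k_ji x_j - k_ij x_i`) by explicit Euler.  An exact
event-by-event simulator (`ssaExact`) exists purely as a validation
oracle for the tau-leap scheme on small systems.

**Interventions.**  A single phosphorylation level `phi` scales the LCC
opening transition, the RyR `k1`, and the SERCA affinity (`Kup/phi` in
`Iup = Vmaxup / (1 + (Kup/phi)²/Cai²)`); a single `eta` scales the two
LCC voltage-inactivation rates.  The study scenarios are `phi = 0.5`,
`phi = 2`, `eta = 0.5`, `eta = 1.5` against the control `phi = eta = 1`.

## Protocol and statistics

The standard protocol paces at 1 Hz (rectangular 52 pA/pF, 1 ms stimulus,
10 ms into each cycle) for 1100 beats and discards the first 100; the
scaled desk protocol uses 60 beats with a 10-beat discard and starts from
a packaged paced steady state (`inst/extdata/steady-state-control-1hz.tsv`,
produced by pacing the deterministic control model for 700 beats, final
drift < 0.001 %/beat).  Per beat the package records the release integral
`S̄ = dt * sum(Irel)`, APD50/APD90 (upstroke to the repolarization
crossing of `Vpeak - f (Vpeak - Vdias)`, linear interpolation, missing —
not an error — when a beat never recrosses), peak and minimum free
cytosolic calcium, and diastolic SR load.

Across a channel-count grid (`NLCC = 16 … 512` by powers of two in the
scaled protocol) the dispersion statistic is the relative interquartile
range `IQR/median` of `S̄`; the transition detector reports the grid value
with the largest fold-reduction between successive powers of two, and
treats curves whose largest fold stays below `minFold = 3` (pure
`1/sqrt(N)` sampling noise gives `sqrt(2)` per octave) as having no
transition.  Bimodality of `S̄` is judged by a deterministic two-component
location fit (k-means initialized at the quartiles) with two rules:
component separation above 3.5 pooled within-component spreads, and minor
weight above 0.1.  The 3.5 threshold is deliberate: splitting a *single*
Gaussian into two clusters yields a separation of about 2.65 pooled
spreads by construction, so a threshold of 2 would call every unimodal
sample bimodal.

## What the scaled experiments show — and their limits

With the reconstructed (reference-gate-derived) LCC rates the package
reproduces the qualitative physiology of the study conditions:

* control: stable 1 Hz pacing, normal AP morphology, release integral
  `S̄ ≈ 1.75` mM with stochastic runs converging to the deterministic
  value at large `NLCC` (0.2 % at 4096 channels);
* `eta = 0.5` (upregulation): a second intra-beat release peak, roughly
  doubled release, strongly prolonged repolarization;
* `eta = 1.5` (downregulation): release well below control;
* `phi = 2` (high phosphorylation): increased release and, at
  `NLCC = 2048`, a clearly bimodal `S̄` distribution (beats switch
  stochastically between single- and double-release trajectories) while
  control at the same size is unimodal.

Two published features are *not* reproduced by this reconstruction, and
tests assert them anyway (they fail, intentionally, as honest markers):

* the sharp dispersion collapse of the control sweep localizes at the
  failure-regime boundary (`NLCC` 16–32) rather than at 128.  The
  underlying mechanism — rare beats with a second SR release lifting `S̄`
  far above the deterministic value — is present and its event
  probability does collapse across 128 (about 15 % at 16–64, 4 % at 128,
  0 % at ≥ 256 under the scaled protocol), but with these rates its
  weight never exceeds the quartile, so the IQR-based dispersion decays
  smoothly;
* `phi = 0.5` converges to a stable period-1 rhythm rather than calcium
  alternans: damping uptake, RyR opening and LCC opening together lowers
  CICR gain, which in this parameterization stabilizes the beat.

Both hinge on the quantitative shape of the originally fitted LCC rate
functions, which were not available; the gate-derived reconstruction is
"too reliable" a trigger (essentially every channel opens every beat,
where a sparse-opening scheme would keep the release decision noisy up to
larger populations).

## Numerical choices

* Explicit Euler for all continuous variables at the shared
  `dt = 0.001` ms (`k dt << 1` for every rate); halving `dt` changes the
  deterministic per-beat release integral by far less than 0.5 %.
* Buffering is algebraic: totals are advanced, free concentrations are
  recovered by the exact quadratic root each step (round-trip 1e−10);
  with sarcolemmal fluxes zeroed the volume-weighted total
  `Vc Cai + Vsr CaSR + Vss Cass` is conserved to well below 0.01 % over
  1e5 steps.
* The GHK driving force evaluates its removable singularity at
  `deltaV = 0` by a series limit, never by division.
* Degenerate inputs: empty analysis windows, all-equal samples, missing
  repolarization crossings and aborted sweep conditions are reported as
  such (flagged, not raised), except instabilities inside the stepping
  core, which abort with a state dump.
* Stochastic runs at 1 Hz cost about one CPU-second per beat per
  condition; the scaled problem sizes (60-beat sweeps, 100-beat
  bimodality runs, 30-beat convergence checks) were chosen once as the
  package's desk-scale defaults, with the full published protocol
  available through the configuration.

## What the synthetic fixtures do and do not cover

`generateFixtures()` produces analytic toy schemes (with their exact
equilibria attached), synthetic release-sample families (unimodal,
bimodal, `1/sqrt(N)` noise) for the statistics layer, and a one-beat
deterministic reference trace.  These validate the machinery —
conservation, distributional agreement of the tau-leap against the exact
simulator, detector behavior on constructed collapses — not the biology:
an aggregate unit with shared subspace calcium cannot represent spatial
spark propagation, dyad-to-dyad heterogeneity, or diffusion-limited
coupling, and conclusions about real cells inherit the reference model's
parameterization.
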