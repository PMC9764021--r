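---
title: "Models and methods behind kirtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kirtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirtraj)
```

## Scope

kirtraj analyses molecular trajectories of inward-rectifier potassium
(Kir) channels — permeation events and currents, activation-gate geometry
and hydration-based closure, and voltage-dependent polyamine (spermine,
SPM) block — and provides a stochastic kinetic generator that emulates the
statistics of such trajectories so that every analyzer can be validated
against an exact ground truth at desk scale. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic data can and cannot stand in for.

## Coordinate convention and pore geometry

All analyses work on axial positions along the pore axis, increasing from
the cytoplasmic domain (CTD) toward the extracellular side. The default
synthetic geometry tiles the extended pore with contiguous half-open
intervals `[z_lo, z_hi)`:

| region | extent (Å) |
|---|---|
| CTD | [−55, −30) |
| G-loop | [−30, −20) |
| cavity | [−20, −6.6) |
| SF sites S6 … S0 | 3.3-Å sites from −6.6 up to 16.5 |
| S_ext | [16.5, 25) |

The 3.3-Å spacing is the canonical inter-site distance of K⁺-channel
selectivity filters; the SF anchor is site S4 with its lower bound at
z = 0. At a shared boundary the upper site wins, so site assignment is
total and never double-counts. For real trajectories the recommended axis
runs through the SF backbone center of mass (residues 144–148) and the CTD
ring (E225/E300), oriented CTD → SF; `residue_map()` lists the landmark
residues. Applied-field simulations convert field to voltage with the
exact constant 1 kcal mol⁻¹ e⁻¹ = 43.3641 mV, so
`field_to_voltage(0.05, 140)` = 303.5 mV. Published field↔voltage pairs
are typically rounded and may not be mutually consistent with a single box
length; the conversion here is exact and any residual discrepancy is a
reporting-precision issue, not resolved by the package.

## The kinetic trajectory generator

`simulate_pore()` runs an exact-jump (Gillespie) simulation of single-file
ion hopping on the compartment chain
`bulk_in – CTD – G_loop – cavity – S6 … S0 – S_ext – bulk_out`.

* **Capacities.** SF sites and S_ext hold at most one ion; the cavity and
  the CTD hold four. Propensities scale with the source-compartment
  occupancy (per-particle mass-action) and vanish when the target is full;
  within a compartment, single-file order is preserved (the ion nearest
  the boundary moves).
* **Voltage.** Each edge carries a coupling δ — the fraction of the
  membrane voltage dropped across it, summing to 1 over the
  intracellular→extracellular path — and rates follow a symmetric Eyring
  bias `k₀·exp(±z_q δ u/2)` with `u = (V/43.3641)/(RT)` and `z_q = +1`
  for K⁺, `+4` for SPM (fully protonated at pH 7).
* **Permeation bookkeeping.** A permeation event is logged when a particle
  whose last extreme position was on one bulk side reaches the other side;
  transient SF visits from either side produce no event. This mirrors the
  analyzers' hysteresis rule, which is why detector/ground-truth
  equivalence is exact rather than approximate.
* **Water co-permeation** is modeled per completed outward permeation as a
  Bernoulli draw with probability `water_coperm_prob` (default 0.22): the
  analyzers consume only the water-to-ion ratio, so explicit single-file
  water is not simulated. Each drawn event is rendered as a short
  synthetic water-marker crossing.
* **Gate.** A two-state gate closes with an absorbing hazard λ_c; closure
  stops hops across the G-loop/cavity edge and switches the hydration and
  gate-distance distributions from their open Gaussians (56 ± 8 waters,
  16.5 ± 0.8 Å I177 diagonal) to the closed ones (20 ± 5 waters, ~10 Å).
  Closure is absorbing because reopening is not observed on the timescales
  the generator emulates.
* **Blocker.** One SPM bead walks a station graph
  (`bulk – CTD – G_loop – cavity – deep_site – SF – translocated`).
  Entering the deep site (between the rectification controller D173 and
  the lower SF) logs a binding event, evicts the cavity/SF ions in the
  direction of the field, and blocks TM-pore hops while bound. The
  deep-site escape edge is calibrated with
  `calibrate_blocker_rates()` so that the mean unbinding time follows
  `τ(V) = (1/k₀)·exp(−|V|/V_s)` exactly through the two anchor points
  (−185 mV, 8.1 µs) and (−310 mV, 0.33 µs), giving `V_s ≈ 39.1 mV`; the
  same law then predicts ≈3.8 µs at −215 mV.
* **Mechanism-constrained mode** replaces free SF hops with the concerted
  four-state knock-on cycle
  `S6[S4,S2],S1 → S5[S4,S2],S1 → S5[S3,S2],S0 → S4[S2,S1],S_ext`,
  each transition firing its constituent single-ion hops atomically. It is
  used to validate the configuration-labeling and knock-on histogram
  analyzers against a known move set.

Frames are rendered from the exact event log (`render_frames()`): ions sit
at site midpoints (wide compartments add one uniform per-dwell offset so
stacked ions spread out) with isotropic Gaussian jitter (default 0.4 Å,
well under half the narrowest site width so site assignment remains
recoverable; jitter-free rendering is available for exact oracle tests).
Hydration waters are drawn per frame from the gate-state Gaussian and
placed uniformly in the cavity cylinder (radius 8 Å, z ∈ [−20, 0)).

### Rate calibration

Absolute hop rates are not published observables; they are free parameters
of the generator, chosen once so that the generated WT trajectories at
+310 mV reproduce the printed steady-state observables: per-region kinetic
occupancies ≈ 2.9 (SF), ≈ 2.7 (cavity), ≈ 2.8–2.9 (CTD); an axial density
profile preferring S1–S3/S4 (this requires graded SF forward rates, fast
at S6 and slower toward S0 — uniform rates peak the profile at the entry
site); a water-to-ion ratio of 0.22; and a current of ~3.5 pA / ~11 pS,
inside the reported 12.9 ± 2.9 pS band. The frozen table lives in the WT
preset (`scenario_preset("WT")`).

Mutant presets modify the WT table. For the CTD-neutralized double mutant
the *observable* is the residence-time increase (≈10× in the CTD, ≈2× in
the cavity). Because single-file exclusion at the G-loop bottleneck
partially compensates when the flux drops (fewer ions queue, so each exits
more freely), literal rate divisions of 10 and 2 realize only ~7× and
~1.4×; the preset therefore divides the CTD exits by 18 and the cavity
exits by 4.5, calibrated so the measured per-visit residence ratios of
generated tracks are ~9.5 and ~1.9. Closure hazards are `ln 2/120 µs⁻¹`
(lipid-bound WT), `ln 2/58` (lipid-depleted), and `ln 2/110` (the
interfacial-helix double mutant, which the data place just below the WT
median rather than exactly at it).

## Analyzers

* **Permeation detection** uses two thresholds: inner = `z_lo(S6) − 2 Å`,
  outer = `z_hi(S0) + 2 Å`. An event is committed only on a full
  inner→outer (or outer→inner) traversal, so sub-Å jitter and transient SF
  visits from the extracellular side can never create or double-count
  events. Currents follow `I = (N_out − N_in)·e/T` (0.1602 pA per event
  per µs) and `g = I/V`.
* **Kinetic occupancy** is the time average of the per-frame ion count in
  a region. Under the `intracellular_entry_only` rule, frames count only
  while the ion's current visit began by crossing the region's lower
  boundary — a causal, streaming criterion (an alternative,
  "ion must eventually permeate", would require future information).
  Standard errors use block averaging with 5 blocks by default, because
  occupancy series are strongly autocorrelated.
* **Residence times** are maximal contiguous visits; visits truncated by
  either trajectory end are flagged censored and excluded from summaries.
  Rendered visits are quantized to the frame grid and miss sub-frame
  dwells, so log-oracle agreement is expected within a frame interval or
  two at the default rates.
* **Knock-on histograms** consider ions inside `[z_lo(S6), z_hi(S0))`;
  a frame contributes only with ≥3 such ions. The left grid bins (lowest
  ion, centroid of the two directly above); the right grid (highest ion,
  centroid of the two directly below). Configuration labels use the
  standard `A[B,C],D` notation over S6…S0 plus S_ext, with reduced forms
  below four ions.
* **Closure detection** calls closure at the first frame from which the
  cavity water count stays ≤ 35 for a persistence window (default 1 µs of
  frames; persistence = 1 recovers plain first-touch, and both modes are
  exposed because the underlying criterion names only the threshold).
  Replicate summaries use Kaplan–Meier survival (via the survival
  package), reporting the median as a lower bound when more than half the
  replicates are censored.
* **Blocker kinetics** smooth the SPM–D173 distance with a centered,
  odd-length running median (default 30 ns; edges use truncated windows —
  no reflected, invented data). Binding fires at ≤ 10 Å, unbinding at
  > 20 Å; the gap is a hysteresis band in which no event fires, so
  bind/unbind events strictly alternate. τ estimation is exponential
  maximum likelihood with right censoring, `τ̂ = (Σ observed + Σ
  censored)/#events`, with χ²(2n) confidence intervals; whether published
  values are MLEs or fitted exponentials is usually unstated, and the MLE
  is this package's choice.
* **Displaced ions** are counted in the cavity+SF region just before deep
  binding minus just after a settle window (default 0.5 µs). The "before"
  frame is taken `pre_margin = 0.05 µs` ahead of the detected binding time
  because the running-median detector lags the true binding by about half
  the smoothing window; without the margin the reference frame can land
  after the eviction itself. The axial extent of "the TM pore" is exposed
  as the `region` argument (default cavity+SF).

## The torsional-correction generator

Selectivity filters can be unstable in long simulations with some force
fields; a per-dihedral additive correction counteracts this. The package
uses a single-cosine well
`ΔE(θ) = −(A/2)(1 + cos(θ − θ₀))`, which meets the two published
constraints — depth exactly `A` (default 4.6 kcal/mol) at the
crystallographic minimum θ₀ relative to θ₀ + 180°, and smooth periodic
behavior — with the fewest parameters; the writer interface accepts any
alternative tabulated shape. The full variant covers φ and ψ of the five
SF residues (143–147), the reduced variant φ only on the two glycines
(145, 147). Reference angles θ₀ must be supplied by the user (from a
crystal structure); the package does not fetch structures.

## What the synthetic data does and does not show

The generator reproduces: steady-state single-file transport statistics
with exclusion, voltage-biased hopping, knock-on-compatible SF dynamics,
Bernoulli water co-permeation, exponential gate closure with
hydration/gate-distance signatures, and two-threshold blocker kinetics
with eviction. It does **not** contain atomistic forces, explicit water
files, lipids, chloride, ion–blocker electrostatics, or conformational
heterogeneity; positional noise is Gaussian and uncorrelated between
frames, whereas real trajectories have correlated fluctuations and
ill-defined site boundaries. Passing the recovery suite therefore shows
that the *analyzers* are correct and well-calibrated on data whose ground
truth is known exactly — it does not by itself validate the physical
conclusions drawn from any particular MD data set.

## Numerical and reproducibility choices

* Exact-jump simulation: no time discretization error; frames are a view
  of the exact event log.
* One master seed per replicate; pipeline replicate streams derive from
  the master seed and replicate index (never the clock), so identical
  configurations reproduce outputs bit-exact.
* Problem sizes used by the validation suite were chosen so each recovery
  has comfortable statistical margin against its tolerance: 110 µs of WT
  permeation (~2,400 events) for the ratio and occupancy, 10 µs for
  hydration, 200 replicates of up to 240 µs for the closure median
  (~96% of replicates close, keeping the survival median essentially
  uncensored), 30 replicates per voltage for unbinding, 25 blocked
  replicates for displacement.
* Degenerate inputs fail loudly: empty hydration series, zero ion events,
  non-contiguous geometries, unsorted frames, jammed rate tables (a
  reachable state with no escape raises a deadlock error naming the
  state), and blocker calibration at equal voltages all raise errors
  rather than returning silently wrong numbers.

## Known limitations

* The generator's absolute rates are calibrated constructs; only the
  observables they were tuned to (and the structure of the model) carry
  meaning.
* Trajectory output is text-based (track table, PDB topology, multi-model
  PDB); DCD is supported for reading only.
* The blocker is a single bead: no polyamine conformational analysis, no
  per-amine contacts, no Mg²⁺ model.
* Real-trajectory mode assumes the provided geometry's axis is adequate
  for the whole trajectory (no per-frame adaptive boundaries).
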