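---
title: "Modelling growth-rate-coupled biofilm-matrix cell-fate decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth-rate-coupled biofilm-matrix cell-fate decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinswitch)
```

## The biological question and the model's shape

In starving *Bacillus subtilis* cultures a subpopulation of cells turns
on biofilm-matrix genes (the *tapA* operon) while another subpopulation
initiates sporulation, and the two fates look mutually exclusive at the
single-cell level even though both are driven by the same master
regulator, phosphorylated Spo0A. `sinswitch` implements a multi-scale
model of this decision:

1. **Batch growth** (`simulate_growth`): a Moser-type model of cell
   density `C` and a normalised nutrient `N` sets the population-mean
   growth rate `mu(t) = k_g N^h1/(N^h1 + K1^h1)`.
2. **Input mapping** (`default_spo0a_map`): growth rate determines the
   Spo0A~P concentration per strain (wild type and the *kinA*, *kinC*,
   *sda* deletions); the upstream phosphorelay is wrapped as a pluggable
   monotone map rather than simulated reaction by reaction.
3. **Gene dosage** (`c_period`, `average_copy_number`,
   `copy_number_at`): chromosome replication takes
   `tau_c = 0.78 + 0.15/mu` hours and starts at birth, so a locus at
   normalised origin distance `p` doubles `p tau_c` into the cycle.
   Slow growth stretches the cycle much more than the C period, which
   erodes the dosage advantage of origin-proximal genes.
4. **The SinI--SinR--SlrR switch** (`build_sin_network`): SinR tetramers
   repress *slrR* and *tapA*; SlrR dimers and Spo0A~P-induced SinI
   sequester SinR dimers. The double-negative SinR--SlrR loop makes the
   switch bistable. One declarative `reaction_network` object feeds
   both engines.
5. **Deterministic analysis** (`find_steady_states`,
   `scan_bifurcation`, `hysteresis_sweep`, `sinr_slrr_ratio`) and
   **stochastic lineage simulation** (`simulate_lineage`,
   `simulate_ensemble`): a compiled next-reaction simulator with
   explicit replication events, per-cycle growth-rate and Spo0A~P
   resampling, and binomial partitioning at division.
6. **Fate statistics** (`classify_cells`, `summarize_population`,
   `mean_dynamics`) and a **synthetic dual-reporter microscopy
   pipeline** (`generate_reporter_table`, `call_expressing`,
   `compare_strains`).

The central mechanism is an incoherent feed-forward loop: slowing
growth *activates* matrix genes by raising Spo0A~P (hence SinI), and
*represses* them by raising total SinR relative to SlrR — SinR is
stable (0.2 h⁻¹) and mostly diluted by growth, SlrR is actively
degraded (0.6 h⁻¹); *slrR* sits near the replication origin, *sinI* and
*sinR* near the terminus. Matrix expression is therefore possible only
in a window of intermediate growth rates, and cells that reach the
sporulation regime (`mu < 0.17` h⁻¹) have typically left that window —
the apparent mutual exclusivity needs no direct cross-inhibition.

## Units, thresholds and fixed constants

Both engines work in molecule counts at a fixed cell volume of 4 fL
(1 µM ≈ 2409 molecules; `uM_to_counts`). Constants fixed by prior
knowledge of the organism: mRNA degradation 8.3 h⁻¹ (5-minute
half-life), SlrR degradation 0.6 h⁻¹, other proteins 0.2 h⁻¹,
translation 200 h⁻¹ per mRNA (dimeric proteins appear at 100 h⁻¹),
C-period law `0.78 + 0.15/mu`, generation-time CV 0.25 with a 0.2 h
floor, time-shift factor `epsilon = 0.2`, sporulation threshold
0.17 h⁻¹, expression threshold 500 TapA molecules, observation times
T4/T6/T8/T12. The TapA readout is given a faster turnover of 1.0 h⁻¹
because the corresponding experimental reporter is a proteolytically
destabilised GFP; with a stable readout the "on" label would lag the
switch state by several hours at low growth rates, where dilution
nearly stops.

## Calibration of the free parameters

Transcription rates, promoter Hill constants, protein--protein binding
rates and the growth-scenario parameters are not fixed by prior
measurements; they were calibrated **once**, against the qualitative
structure the model must reproduce, and then frozen as package
defaults (`sin_network_params`, `growth_params`, `strain_preset`). The
calibration targets were:

* monostable low expression below ≈0.1 µM Spo0A~P and bistability
  above it at the reference fast growth rate, with the high branch
  saturating past 0.4 µM (SinI activation, `K = 0.15` µM, saturates);
* loss of bistability when growth slows below ≈0.25 h⁻¹ at any
  Spo0A~P level (the near-vertical exit boundary);
* a decreasing total-SinR:total-SlrR ratio in growth rate when
  transcriptional regulation is disabled;
* stochastic switching *into* the high state on the hours timescale in
  the permissive window, and switching *off* (not artificial
  persistence) once growth slows past the exit boundary;
* single-cell fractions at T8 with the strain ordering
  Δ*sda* > WT > Δ*kinC*, non-sporulating cells expressing more often
  than sporulating ones within each strain, and a smaller
  non-spo/spo fold change in Δ*sda* than in the wild type.

Two calibration choices deserve comment. First, the absolute
transcription rates set the intrinsic-noise level: the deterministic
switch structure is invariant under jointly scaling all molecule
numbers (rates and repression thresholds up, bimolecular constants
down), while stochastic switching rates are exponentially sensitive to
that scale. The defaults put the mRNAs at a few copies per cell and
SinR pools at tens to hundreds of molecules, which makes
spontaneous activation in the bistable window a per-hour-scale event.
Second, the growth scenario was shaped so that the mean growth rate
declines quasi-linearly (high `K1`, Monod-like `h1 = 1`, partial
nutrient recycling by dying cells): an abrupt collapse makes any
lineage-based reconstruction of the population growth rate lag badly,
because cycle durations are committed at birth and the `epsilon = 0.2`
forward shift only compensates part of one generation.

The "slow" scenario models the nitrogen-reduced medium and differs from
"normal" only in the yield coefficient (`gamma` 4.0 vs 1.4): less
nutrient per unit biomass exhausts the medium earlier, reproducing the
earlier and lower matrix-expression peak.

The Spo0A~P maps are decreasing sigmoids in growth rate per strain,
chosen to respect the published orderings (at slow growth
Δ*sda* > Δ*kinC* > WT > Δ*kinA*; at fast growth WT > Δ*kinC*, with a
single crossover) and to cross the switch's activation threshold while
the growth rate is still above the bistability exit. Exact quantitative
curves would require the full phosphorelay model; a tabulated map from
such a model can be supplied via `spo0a_map_from_table` and used
everywhere the default map is.

## Numerical choices

* **Deterministic engine.** Steady states are found by integrating
  (lsoda, rtol 1e-8) from diverse corner states until the relative
  state change per hour falls below 1e-9, clustering endpoints at 1e-4
  relative distance, polishing by damped Newton iteration with a
  finite-difference Jacobian, and classifying stability by Jacobian
  eigenvalues (margin 1e-8). When exactly two stable states exist the
  separating saddle is located by bisecting the connecting segment on
  basin membership, sliding along the boundary to the point of minimal
  velocity, and polishing. Two-parameter scans seed each grid cell with
  the neighbouring cells' solutions (grid-seeded continuation), which
  is adequate for the smooth two-parameter maps used here.
* **Stochastic engine.** Next-reaction method with putative absolute
  times and Gibson–Bruck rescaling on dependency updates; at
  discontinuous parameter changes (cycle start, gene replication,
  division) all propensities are recomputed and all putative times
  redrawn, which is statistically exact for exponential clocks. The
  fired reaction is always redrawn. Counts are checked nonnegative at
  every event. Samples record the state immediately before any event
  scheduled at the same instant, so a division at a sample time is
  observed pre-division. All randomness flows through R's RNG; lineage
  `i` of an ensemble uses child seed `seed + i`.
* **Reference fast growth rate.** One-parameter bifurcation cuts are
  taken at 0.45 h⁻¹, the initial growth rate of the normal scenario —
  the fastest rate cells actually experience in the calibrated medium.
* **Growth-rate reconstruction check.** The 500-lineage ensemble mean
  of `ln 2 / tau_cyc` over cycles alive at `t` is compared with the
  deterministic `mu(t)` as a maximal absolute deviation relative to
  `k_g` over 1–12 h (tolerance 5%). A pointwise relative criterion is
  not meaningful in the tail where `mu` approaches zero: cycle
  durations are committed at birth, so any lineage reconstruction of a
  collapsing growth rate saturates at the last committed value.
* **Peak detection** on stochastic means uses the argmax of a centred
  three-point moving average.

## What the synthetic data do and do not show

The reporter generator emulates the statistical structure of segmented
dual-reporter micrographs: 9 images (3 images × 3 cultures) of
600–1600 cells, a joint (matrix-on, sporulating) fate per cell,
log-normal signal over Gaussian background, and per-image background
statistics. Thresholding at background mean + 3 SD, per-image
conditional fractions, non-spo/spo fold changes and a Welch two-sample
test across images mirror the analysis stage. What passing these tests
shows is that the analysis stage recovers known ground truth under the
assumed mixture structure; it does not validate segmentation,
autofluorescence structure, optical crosstalk, or spatial correlations
within images, none of which are modelled.

Likewise, the lineage simulations make simplifying assumptions worth
keeping in mind: a single daughter is followed (no branching
population), the cell volume is fixed at 4 fL through the cycle,
multifork replication is not modelled (replication events that would
not finish within a cycle clamp the copy number at 1 with a warning),
the growth rate is constant within a cycle, and Spo0A~P is a
deterministic function of the cycle's growth rate — all extrinsic noise
enters through the generation-time distribution.

## Problem sizes

The bundled analyses use desk-scale settings: ensembles of 200–500
lineages over 14 h sampled every 0.5 h, bifurcation grids of a few
dozen cells, and fixed-condition runs of a few thousand hours for
stationary statistics. All are chosen as the smallest sizes at which
the qualitative claims are statistically stable; larger ensembles
sharpen the fractions but do not change any conclusion.

## Known limitations

* The default Spo0A~P map is phenomenological; quantitative per-strain
  expression levels (as opposed to orderings and dynamics shapes)
  depend on the upstream phosphorelay model that is out of scope here.
* The switch parameters are a calibrated set, not a fitted one: they
  reproduce the qualitative bifurcation structure but individual rate
  constants should not be interpreted as measurements.
* Sporulation is represented only as a growth-rate threshold label;
  spore development and its feedback on gene dosage are not modelled.
* The eps operon is not modelled separately; *tapA* promoter logic
  stands for the matrix regulon.
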