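# sinswitch

Multi-scale modelling of biofilm-matrix cell-fate decisions in starving
*Bacillus subtilis*: how the slowdown of growth controls which cells
turn on matrix genes and why matrix production and sporulation look
mutually exclusive at the single-cell level.

The package is aimed at systems biologists studying bistable gene
circuits and growth-rate coupling. It chains four layers:

1. **Batch growth.** A Moser-type model for cell density `C` and
   nutrient `N` gives the population-mean growth rate
   `mu(t) = k_g N^{h1}/(N^{h1}+K1^{h1})`.
2. **Input mapping.** Per-strain monotone maps from growth rate to
   phosphorylated Spo0A (Spo0A~P), the switch input; the phosphorelay
   is pluggable, not simulated internally.
3. **The SinI–SinR–SlrR switch.** SinR tetramers repress *slrR* and
   *tapA*; SlrR and Spo0A~P-induced SinI sequester SinR dimers. The
   double-negative SinR–SlrR loop is bistable. Gene dosage enters
   through replication timing: a locus at normalised origin distance
   `p` doubles `p·tau_c` into the cycle, `tau_c = 0.78 + 0.15/mu` h.
4. **Single-cell fates.** A compiled next-reaction lineage simulator
   (explicit gene replication, per-cycle growth-rate/Spo0A~P
   resampling, binomial partitioning at division) feeds fate
   classification: sporulating if the cycle growth rate is below
   0.17 h⁻¹, matrix-on if the TapA reporter exceeds 500 molecules.

Together these implement an incoherent feed-forward loop: slowing
growth activates matrix genes via Spo0A~P→SinI but represses them by
raising SinR relative to SlrR (differential degradation 0.2 vs
0.6 h⁻¹ and gene position), so matrix expression is possible only in a
window of intermediate growth rates.

## Worked example

Deterministic structure of the switch at the reference fast growth
rate (0.45 h⁻¹):

```r
library(sinswitch)
net <- build_sin_network()

find_steady_states(net, mu = 0.45, spo0a = 0.05)
#> <steady_states> mu = 0.45, Spo0A~P = 0.05 uM: 1 state(s)
#>   low      stable    TapA = 0.5129

find_steady_states(net, mu = 0.45, spo0a = 1)
#> <steady_states> mu = 0.45, Spo0A~P = 1 uM: 3 state(s)
#>   low      stable    TapA = 22.5
#>   high     stable    TapA = 1220
#>   unstable unstable  TapA = 448.1
```

At 0.05 µM Spo0A~P only the repressed state exists; at 1 µM the
matrix-on state (~1220 TapA molecules, i.e. above the 500-molecule
threshold) coexists with the repressed one, separated by a saddle.

Simulating 200 wild-type lineages through the starvation time course
and classifying fates at T8:

```r
traj <- simulate_growth(growth_params("normal"), t_end = 15)
ens  <- simulate_ensemble(net, traj, default_spo0a_map(), "WT",
                          n_lineages = 200, t_end = 14, seed = 5)
summarize_population(classify_cells(ens, fate_thresholds()))
#> <population_summary> n = 200
#>   fraction on (all / spo / non-spo): 0.120 / 0.074 / 0.151
#>   mean TapA (all / on): 180.6 / 1224.8
```

12% of cells are matrix-on at T8 overall; the fraction is about twice
as high among non-sporulating cells (0.151) as among sporulating ones
(0.074) — the apparent mutual exclusivity, emerging with no direct
cross-inhibition in the model. `mean_dynamics()` and
`fraction_dynamics()` give the pulse-shaped population time courses,
`scan_bifurcation()` maps the bistable region in the
(growth rate, Spo0A~P) plane, and `run_experiment()` orchestrates a
whole scenario from a YAML config, writing CSV tables and a JSON
manifest.

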