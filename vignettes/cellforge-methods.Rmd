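---
title: "Methods: heterocellular coupling and custom-cell design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterocellular coupling and custom-cell design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Delivery of non-excitable cells (mesenchymal stem cells, c-kit+ cardiac
interstitial cells) to failing myocardium is an active therapeutic strategy.
One of their modes of action is electrotonic: a delivered cell that forms gap
junctions with a cardiomyocyte acts as a current source/sink that reshapes the
myocyte's action potential (AP) and, indirectly, its calcium transient (CaT).
`cellforge` asks the design question: which ion-channel complement, expressed
on a small 40 pF "custom" cell, restores a healthy AP and CaT when the cell is
coupled to a heart-failure (HF) cardiomyocyte?

## Models

**Cardiomyocyte.** The human endocardial ventricular myocyte (O'Hara-Rudy
family), with the fast sodium current replaced by the ten Tusscher-Panfilov
formulation — the substitution used by the published HF parameterization this
package follows. The HF phenotype multiplies a documented subset of parameters
(`inst/extdata/params/hf_remodeling.json`): late Na+ conductance and
inactivation time constant x1.8, transient outward x0.4, inward rectifier
x0.68, Na+/Ca2+ exchanger x1.75, Na+/K+ pump x0.7, SERCA x0.55, SR leak x1.3,
CaMKII activity x1.5. These factors were transcribed from the published HF
parameterization of this model family; the file is versioned so the set is
auditable and swappable. Fibrotic HF couples the HF myocyte to five MacCannell
fibroblasts at 1 nS each.

**Fibroblast.** The MacCannell "active" fibroblast: time- and
voltage-dependent K+ current, inward rectifying K+ current, Na+/K+ pump, and a
background Na+ leak; 6.3 pF.

**Custom cell.** An isopotential 40 pF capacitor carrying a roster of channels
drawn from four sources (hCIC, hMSC, cardiac fibroblast, healthy
cardiomyocyte), each scaled by a non-negative factor. Three literal design
readings are implemented on purpose:

- *Fixed intracellular concentrations.* The custom cell has no SR, no
  subspace, and no ion accumulation; every Nernst/GHK computation sees one
  documented concentration set (`[Na]i` 10 mM, `[K]i` 140 mM, `[Ca]i` 0.1 uM,
  config-visible). The merged set (rather than one per source model) keeps a
  union roster's currents additive across sub-rosters.
- *Channel densities.* Conductances are densities per pF referenced to the
  40 pF cell: cardiomyocyte conductances are already per-capacitance,
  MacCannell's are densities, and the hMSC/hCIC whole-cell values are
  normalized by their ~40 pF capacitance.
- *No leak channels.* Source-model leakage/background currents are excluded
  from every roster — they are fitting constructs, not expressible channels.
  The separate `passive` roster is the deliberate exception: a pure linear
  leak (baseline 1 nS across 40 pF, reversal −20 mV, both config-exposed)
  standing in for a purely passive cell; its membrane resistance is not given
  in the source material, so it is a package choice, made once.

**hMSC and hCIC channel models are reconstructions.** The cited source
equations for these two cell types are not redistributable inside this
package, and the build environment is offline. Their channels
(hCIC: Na+, Kir, BK(Ca), Ito; hMSC: Ito with time-dependent and steady-state
components, Na+, CaL, K(Ca), delayed rectifier) are therefore implemented as
Hodgkin-Huxley formulations matching the published rosters and qualitative
electrophysiology (resting potentials near −40 to −60 mV without leak,
current densities of a few pA/pF), with parameters fixed once in
`inst/extdata/params/support_cells.json` and flagged `reconstructed: true`.
Quantitative results that depend on these two models (notably the engineered
hMSC/hCIC minimum-RMSE values) inherit this caveat; results driven by
cardiomyocyte channels (the IK1/ICaL rescue) do not.

## Coupling

One cardiomyocyte, `n_fib` identical fibroblasts, and `n_custom` identical
custom cells obey

```
-C_cm dV_cm/dt   = I_ion,cm   + n_fib G_fib (V_cm - V_fib) + n_custom G_gap (V_cm - V_cust)
-C_x  dV_x/dt    = I_ion,x    + G_x (V_x - V_cm)            for x in {fib, cust}
```

with gap currents in pA converted to densities by each cell's own capacitance.
All `n_custom` custom cells share one state vector (the literal reading of the
single `V_custom` in the coupling equations); so do the fibroblasts. Custom
cells couple only to the cardiomyocyte. Only the cardiomyocyte is stimulated
(rectangular pulse, −80 uA/uF for 0.5 ms — the source model's convention;
amplitude and duration are config-exposed). Per-junction gap current is
recorded, so the current leaving the cardiomyocyte through custom-cell
junctions is exactly `n_custom` times the current entering one custom cell.

## Objectives and metrics

The final beat's AP (mV) and CaT (mM) are sampled on a fixed 1 ms grid over
the first 500 ms from stimulus onset (501 samples; the window start is a
package decision — "first 500 ms of the final beat" does not say whether the
clock starts at the stimulus or the preceding diastole). Scores are

```
RMSE_AP  = RMSE(treated, healthy) / RMSE(untreated, healthy)   # AP
RMSE_CaT = likewise on [Ca]i
```

and a candidate is accepted when both are strictly below 0.5 (ties reject).
The untreated cell scores exactly (1, 1) by construction. Post-hoc metrics:
RMP is the sample at stimulus onset; upstroke velocity is the maximum finite
difference on the stored grid (a deliberate, documented underestimate of the
instantaneous dV/dt); APD50/90 run from the steepest-interval start to the
interpolated downstroke crossing of `peak − x%·(peak − RMP)`; tau50/tau90 are
threshold-crossing times of the CaT decay, not fitted exponential constants —
the "50%/90% decay" definition dictates crossings despite the name "time
constant".

## Genetic algorithm

Genomes hold the searchable channel scalings, a gap-junction scale (on a 1 nS
baseline), and the integer cell count. Initialization: continuous parameters
i.i.d. uniform on [1e-4, 10] (0.01%–1000%), count discrete uniform on 1–5.
Each generation applies, in order: pairwise tournament selection (two
independent pairings of the full population; winner = more objectives < 0.5,
tie broken by lower summed normalized RMSE, tie-of-ties by pair order — the
sum is used for "overall percent RMSE" since ranking is identical to the
mean); crossover (probability 0.9 per random pair, each parameter exchanging
with probability 0.5); mutation (probability 0.01 per parameter, multiplier
`exp(N(0, 0.2))` — sigma is taken in natural-log space because only that
reading satisfies the stated property that >99.9% of multipliers lie within a
0.5- to 2-fold change; mutated values may leave the initialization range);
elitism (each generation's top 10% by the selection ranking key overwrite the
bottom 10% of the next generation's evaluated population — the elitism key is
not specified by the protocol, so it mirrors the selection rule, and the
carry-over form is what guarantees the best summed RMSE never worsens under a
deterministic objective). The count mutates by multiply-round-clamp to [1, 5]. Failed
integrations score (Inf, Inf) rather than aborting. Identical genomes share
one memoized simulation; each genome's score depends only on the genome, so
results are independent of evaluation order. A single seed set at run start
makes the whole run reproducible.

For the engineered hMSC/hCIC comparisons, `min_rmse_search()` minimizes
`RMSE_AP + RMSE_CaT` by seeded random search and takes the minimum pooled over
all evaluated points (whether the printed minima pool generations is not
stated; pooling is adopted and reported as such).

## Numerics

The integrator is a hybrid explicit scheme: Rush-Larsen exponential updates
for gating variables, forward Euler for voltage, concentrations, and CaMK,
with local refinement (substeps targeting ~0.1 mV per step, floor 1 us)
whenever a step would move any cell's voltage by more than 0.2 mV. No stiff
implicit solver is available in the supported environment, so the
"correctness" route required by the design is the same scheme at a 4x finer
ceiling (`dt_max` 0.005 ms vs the throughput default 0.02 ms); the two agree
on APD90 within 1 ms (tested) and differ by <0.1 mV pointwise on a healthy
beat. Voltage-dependent rates are linearly interpolated from a 0.02 mV lookup
table; the single-evaluation RHS functions used by the oracle tests bypass the
table. GHK terms use the `x/expm1(x)` form near V = 0. Steady state is
operational — 500 paced beats at 1 Hz — not a convergence test.

**Desk-scale protocol.** Full-scale runs (2500 x 5 generations x 500 beats)
are hours of CPU. The test suite paces all *reference* waveforms the full 500
beats, but evaluates GA candidates by warm-starting the cardiomyocyte (and
fibroblasts) from the untreated steady state and pacing 8-20 coupled beats
(fewest where the accept/reject margin is largest).
Accept/reject outcomes are insensitive to this (the CaT equilibrates slowly,
but candidates near the acceptance boundary stay on their side; an
insensitivity check is part of the suite), while quantitative minima are
re-scored at 300 beats. A green desk-scale test establishes the qualitative
claims (which rosters can/cannot rescue, the direction of accepted-parameter
distributions) — not the full-scale acceptance percentages.

## Known limitations

- The hMSC/hCIC reconstructions above; values depending on them are labeled.
- No paracrine signaling, no tissue-level propagation, no epicardial or
  mid-myocardial variants, no restitution/alternans metrics (out of scope).
- The stimulus contributes to the K+ balance (the source model's bookkeeping
  convention), and gap current follows the same convention.
- Warm-started short evaluations bias CaT scores by up to ~0.1 of the
  normalized scale for borderline genomes; tests that need quantitative
  accuracy re-evaluate at 300 beats.
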