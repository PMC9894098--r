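# cellforge

Computational design of "custom" therapeutic cells that rescue failing human
cardiomyocytes through gap-junctional coupling.

## The problem

Non-excitable cells delivered to failing myocardium (mesenchymal stem cells,
c-kit+ cardiac interstitial cells) couple electrotonically to host
cardiomyocytes. `cellforge` treats the delivered cell as a designable object:
an isopotential 40 pF membrane carrying a roster of ion channels — drawn from
hCICs, hMSCs, cardiac fibroblasts (CF), and healthy cardiomyocytes (hCM) —
with per-channel conductance scalings, fixed intracellular concentrations, and
no calcium-handling machinery. The design question: which channel complement,
gap-junction conductance `G_gap`, and coupled-cell count `n` restore a healthy
action potential (AP) and calcium transient (CaT) in a heart-failure (HF)
cardiomyocyte?

## The model

The host myocyte is the O'Hara–Rudy human endocardial model (fast sodium
current in the ten Tusscher–Panfilov formulation), with a documented
multiplicative HF remodeling set; fibrotic HF couples the myocyte to 5
MacCannell fibroblasts at 1 nS. One cardiomyocyte and `n` identical custom
cells obey

    -C_cm   dV_cm/dt   = I_ion,cm   + n G_gap (V_cm - V_cust) + n_fib G_fib (V_cm - V_fib)
    -C_cust dV_cust/dt = I_ion,cust + G_gap (V_cust - V_cm)

paced at 1 Hz for 500 beats. A candidate is scored on the final beat's first
500 ms by

    RMSE_AP  = RMSE(treated, healthy) / RMSE(untreated, healthy)
    RMSE_CaT = likewise on [Ca]i

and **accepted** when both are strictly < 0.5. A genetic algorithm
(population 2500, 5 generations; selection → crossover → mutation → elitism)
searches the channel scalings (uniform 0.01%–1000% at initialization),
`G_gap` (scale on 1 nS), and `n` (1–5).

The hMSC and hCIC channel models are reconstructions of the published
descriptions (see the methods vignette, `vignettes/cellforge-methods.Rmd`);
the cardiomyocyte, fibroblast, and GA machinery follow their published
definitions.

## Worked example

Evolve inward-rectifier-only custom cells against the fibrotic HF myocyte at
desk scale (population 100, 3 generations, warm-started 25-beat evaluations):

```r
library(cellforge)
bundle <- run_experiment("ik1-only", seed = 1L, population = 100L,
                         generations = 3L, beats = 25L)
print(bundle$log)
bundle$summary
```

which prints (as produced by this code):

```
<generation_log> 3 generation(s), population 100
  gen 0: accepted 28/100, best total RMSE 0.605
  gen 1: accepted 58/100, best total RMSE 0.595
  gen 2: accepted 82/100, best total RMSE 0.588
  gen 3: accepted 100/100, best total RMSE 0.580
    parameter   median   iqr_lo   iqr_hi
1       cm_k1 4.772353 3.841099 6.508740
2 g_gap_scale 7.181242 6.304178 8.864521
3    n_custom 4.000000 4.000000 4.000000
```

Reading: an accepted design multiplies the cardiomyocyte IK1 conductance
density several-fold on the 40 pF cell, couples at ~6–9 nS (median G_gap scale
7.2 on the 1 nS baseline), and uses 4–5 cells per myocyte — i.e. the rescue
needs strong coupling and a hyperpolarizing inward-rectifier load, while
custom cells restricted to non-excitable channels are never accepted
(`run_experiment("nonexcitable-fibrotic", ...)` yields 0 accepted).

Lower-level surfaces: `simulate()` + `extract_final_beat()` +
`normalized_rmse()` for single designs; `ord_rhs()`, `fibroblast_rhs()`,
`custom_cell_rhs()` for the raw model equations; `ap_metrics()` /
`cat_metrics()` for APD50/90, upstroke velocity, RMP, CaT amplitude and
tau50/tau90; `min_rmse_search()` for the engineered hMSC/hCIC comparisons.

A CLI wraps the experiment presets:

```sh
inst/cli/cellforge run ik1-only --population 100 --generations 3 --beats 25 --seed 1 --out out/
inst/cli/cellforge references hf_fibrosis --out refs/
inst/cli/cellforge report out/
```

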