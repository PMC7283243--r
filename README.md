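# tnfkin

Kinetic and equilibrium analysis of TNF-alpha trimer–monomer dynamics and
therapeutic-scavenger binding, for biosensor experiments of the
electro-switchable (switching-speed) type.

Tumor necrosis factor-alpha (TNF-alpha) signals as a non-covalent homotrimer
of ~17.5 kDa monomers that decays into inactive monomers at low
concentration and re-assembles at high concentration. Anti-TNF biologics
(Adalimumab, Infliximab, Golimumab, Certolizumab, Etanercept and their Fab
fragments) bind the trimer with picomolar affinity and differ in how
strongly they stabilize it — a mode-of-action question this package makes
quantitative. It is aimed at biophysicists and assay scientists analyzing
time-resolved biosensor traces of oligomer decay and 1:1 binding kinetics.

## What it computes

- **Monomerization kinetics** — single-exponential fits
  `y(t) = y0 − A e^(−kt)` of trimer-decay traces, with replicate mean ± SEM
  and below-detection flagging (free-trimer reference rate
  `k = 1.66e-3 s^-1`).
- **1:1 binding kinetics** — global fits over a concentration series:
  shared `k_off` from `y = A e^(−k_off t) + y0`, then shared `k_on` from
  `y = y0 − A e^(−(c·k_on + k_off) t)` (so `k_obs = c·k_on + k_off`), and
  `K_D = k_off / k_on` with first-order error propagation.
- **Biphasic decay decomposition** — global bi-exponential fits
  `y = y0 − a_f e^(−k_fast t) − a_s e^(−k_slow t)` separating trimer decay
  (fast) from scavenger dissociation (slow), plus AICc/F-test model
  selection between mono and bi.
- **Solution-equilibrium affinity** — the depletion-corrected isotherm
  `y(L_T) = y0 + A(1 − b)`,
  `b = ((R_T+L_T+K_D) − sqrt((R_T+L_T+K_D)² − 4 R_T L_T)) / (2 R_T)`,
  fitted with a seeded residual bootstrap; depletion-limited titrations are
  reported as upper bounds (`K_D < x`), not fake point estimates.
- **Sizing** — switching-speed → hydrodynamic-diameter calibration
  (monotone cubic, refused extrapolation), trimer-fraction conversion
  between the measured anchors 5.6 nm (trimer) and 3.9 nm (monomer), and
  classification against measured and PDB-predicted references.
- **Trimer-stabilization panel** — per-scavenger monomerization rates from
  triplicate traces, suppression factors `k_free / k_mono`, and the
  full/strong/moderate/weak classification.
- **Synthetic data** — seeded generators for every experiment type, used
  throughout the tests for parameter-recovery validation.

## Worked example

Simulate a kinetic titration with the published TNF-alpha/Adalimumab-Fab
rates (`k_on = 2.82e6 M^-1 s^-1`, `k_off = 8.52e-5 s^-1`) at 1% noise, then
recover them with the two-step global fit:

```r
library(tnfkin)
library(dplyr)

ser <- gen_kinetic_series(k_on = 2.82e6, k_off = 8.52e-5, sigma = 0.01, seed = 7)
run <- run_kinetics(
  filter(ser, phase == "association"),
  filter(ser, phase == "dissociation")
)
glance(run$report)
#> # A tibble: 1 × 6
#>   k_on_1e6 k_off_1e5 kd_pM se_k_on_1e6 se_k_off_1e5 se_kd_pM
#>      <dbl>     <dbl> <dbl>       <dbl>        <dbl>    <dbl>
#> 1     2.82      8.53  30.3     0.00898      0.00796    0.101
```

`k_on` and `k_off` come back at their generating values and the affinity is
30.3 pM (truth: 30.2 pM), in the display units of the standard rate table
(10^6 M^-1 s^-1, 10^-5 s^-1, pM).

A solution titration at 100 pM receptor, where ligand depletion matters:

```r
tab <- gen_titration(rt = 100e-12, kd = 53.6e-12, sigma = 0.01, seed = 7)
fit_titration(tab, rt = 100e-12, seed = 7)
#> <titration_fit> rt = 100 pM: KD = 47 pM (95% CI 42.1-52.5)
```

a typical single-experiment recovery of the generating 53.6 pM at this
noise level (across 100 simulations the 90% bootstrap intervals cover the
truth at their nominal rate).

The stabilization panel, simulated with rates anchored to the published
values and re-analyzed:

```r
panel <- run_stabilization_panel(gen_stabilization_panel(seed = 7),
  k_free = tnf_refs$k_mono_free
)
tidy(panel)
#> # A tibble: 9 × 7
#>   scavenger        k_mono  below_detection suppression_factor class
#>   Adalimumab     NA        TRUE                     Inf       full_suppression
#>   Golimumab      NA        TRUE                     Inf       full_suppression
#>   Infliximab     NA        TRUE                     Inf       full_suppression
#>   Adalimumab Fab  4.58e-5  FALSE                     36.2     strong
#>   Infliximab Fab  4.68e-5  FALSE                     35.4     strong
#>   Certolizumab    1.99e-4  FALSE                      8.35    moderate
#>   Etanercept      2.01e-4  FALSE                      8.27    moderate
#>   Golimumab Fab   5.53e-4  FALSE                      3.00    weak
#>   buffer          1.66e-3  FALSE                      0.999   weak
```

The avid IgG binders fully suppress monomerization, the
Adalimumab/Infliximab Fabs allow a just-detectable `~4.6e-5 s^-1`,
Certolizumab/Etanercept are moderate, and Golimumab Fab only slows the free
rate threefold — the buffer control sits at the free rate with suppression
factor 1.

Plots: `autoplot()` works on every fit object; `plot_traces()` shows raw
traces.

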