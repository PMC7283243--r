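---
title: "Models and methods: TNF-alpha trimer-monomer dynamics and scavenger binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: TNF-alpha trimer-monomer dynamics and scavenger binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnfkin)
library(dplyr)
```

## The biological system and the measurements

Tumor necrosis factor-alpha (TNF-alpha) is bioactive as a non-covalent
homotrimer of ~17.5 kDa monomers. At low concentration the trimer decays
into inactive monomers; at high concentration monomers re-assemble. Five
therapeutic scavengers (the IgGs Adalimumab, Infliximab, Golimumab; the
PEGylated Fab Certolizumab; the receptor-Fc fusion Etanercept) and papain
Fab fragments bind the trimer with picomolar affinity and differ in how
strongly they stabilize it.

An electro-switchable biosensor reports two observables on surface-tethered
TNF-alpha: a *switching-speed* signal (the dynamic response DR, the time
integral of the normalized fluorescence transition over a window), which
tracks the hydrodynamic friction and hence the hydrodynamic diameter of the
tethered molecule, and time-resolved normalized binding traces. `tnfkin`
implements the complete analysis chain for such experiments: closed-form
kinetic/equilibrium models, global fitting, sizing, and the stabilization
panel comparison, plus seeded generators that emulate the experiments so the
whole chain is testable without instrument data.

## Models

**Trimer decay (monomerization).** First-order decay of tethered trimers is
fitted as `y(t) = y0 - A exp(-k t)` (`mono_exp()`); the free-trimer
reference rate is `k = 1.66e-3 s^-1` (about 30 min to completion), stored in
`tnf_refs`.

**1:1 binding kinetics.** Association at analyte concentration `c` follows
a pseudo-first-order rise with observed rate `k_obs = c k_on + k_off`
(`association_signal()`); dissociation decays as `A exp(-k_off t) + y0`
(`dissociation_signal()`); affinity is `KD = k_off / k_on`
(`kd_from_rates()`, with first-order error propagation).

**Biphasic dissociation.** On partially saturated surfaces the decay is the
sum of trimer monomerization (fast) and scavenger dissociation (slow):
`y(t) = y0 - a_fast exp(-k_fast t) - a_slow exp(-k_slow t)` (`bi_exp()`),
both components sharing the offset.

**Solution equilibrium with depletion.** With receptor and ligand
concentrations comparable to KD, the bound receptor fraction is the exact
mass-action root

    b = ((rt + lt + kd) - sqrt((rt + lt + kd)^2 - 4 rt lt)) / (2 rt),

evaluated in the cancellation-free form `2 lt / (S + sqrt(S^2 - 4 rt lt))`
(`equilibrium_bound_fraction()`). The titration readout measures *free*
receptor, so the response model is `y(lt) = y0 + A (1 - b)`. A typeset form
of this isotherm that places the entire quadratic expression in a
denominator is dimensionally inconsistent with a sigmoidal response; the
package implements the standard depletion-corrected isotherm above, which
reproduces a sigmoid from `A` toward `y0` with a midpoint at
`lt = kd + rt/2`. It is a deliberate 1:1 approximation: both TNF-alpha
(valence 3) and IgG (valence 2) are multivalent, higher-order complexes
steepen the true dose response, and `run_titration()` carries that caveat in
its output.

**Sizing.** DR values map to hydrodynamic diameters through a user-supplied
monotone calibration (`calibration_curve()`, shape-preserving Hyman cubic
interpolation, extrapolation refused, root-solved inverse). Oligomeric
state is expressed as a trimer fraction by linear interpolation between the
measured anchors 5.6 nm (trimer) and 3.9 nm (monomer), clipped to [0, 1] —
an explicit reporting approximation, not a friction model. PDB-predicted
shell-model diameters (trimer 5.76–6.10 nm, monomer 4.39–4.44 nm) are kept
under separate provenance and never silently mixed with measured anchors;
`compare_to_reference()` reports deviations from both. The measured trimer
diameter sits slightly below the predicted range; no correction factor is
defined, so none is applied.

## Fitting procedures

All rate constants are log-parameterized (they span `1e-5`–`1e-1 s^-1` and
must remain positive) and estimated by Levenberg–Marquardt least squares
(`minpack.lm`). Every single-exponential fit starts from a *rate profile*:
on a log-spaced grid of candidate rates the amplitude and offset are solved
linearly, and the grid minimum seeds the refinement — no fit depends on a
lucky starting value.

**Global fits.** The concentration series is analyzed in the standard two
steps: a single shared `k_off` is fitted to all dissociation curves
(amplitudes and offsets per curve), then held fixed while a single shared
`k_on` is fitted to the association curves. The reported `k_off`
uncertainty is the standard error of the mean of the individually fitted
per-curve rates; `k_on` uncertainty comes from the global-fit covariance.

**Bi-exponential initialization.** `k_slow` is seeded from a
single-exponential fit of the trace tail (last 25%), `k_fast` from the
residual early phase, alongside fixed-ratio alternatives; candidates are
scored by the profiled residual sum of squares and the best starts the full
refinement. `k_fast > k_slow` is enforced by relabeling after the fit. A
component whose amplitude is below twice the residual noise, or which decays
by less than 5% over the recorded window (and therefore trades off against
the offset), is flagged unresolvable and the fit is reported as effectively
mono-exponential with `k_effective`.

**Model selection.** `select_decay_model()` compares the two decay models
with AICc and an F-ratio on residual sums of squares and requires agreement
at `alpha = 0.05` to call the decay biphasic; disagreement falls back to the
parsimonious mono decision with an `ambiguous` flag. When the mono fit's
residuals are at numerical zero (noiseless input), the decision is mono
outright — an F-ratio on rounding noise is meaningless. On mono-exponential
data at 1% noise this procedure retains the mono model in ≥95% of seeds (the
conjunction of the two criteria keeps the false-biphasic rate below the
nominal `alpha`).

**Titration confidence intervals.** `fit_titration()` uses a seeded
residual bootstrap (default 1000 resamples). Two small-sample corrections
matter at 12 points with 3 parameters: raw least-squares residuals
underestimate the noise sd by `sqrt((n-p)/n)`, so resampled residuals are
variance-inflated by the inverse factor; and the interval is built as a
normal approximation on `log KD` from the bootstrap spread, which for a
positive scale parameter is better calibrated than the raw percentile
interval (in our recovery simulations: ~90% empirical coverage at nominal
90%, versus 82–84% for the uncorrected percentile bootstrap). When the fit
is depletion-limited (`kd < rt/10`, so the transition midpoint is set by
`rt` rather than `kd`) or the transition is not bracketed by the titrant
grid, the result is reported as an upper bound (the upper confidence limit)
instead of a point estimate.

**Stabilization panel.** Replicate traces are averaged point-wise before
fitting (per-replicate fits are kept for the SEM). Full suppression is an
*amplitude* statement, not a zero-rate estimate: a trace whose fitted decay
amplitude over the window is below twice the residual noise is
below-detection. Class boundaries are configuration defaults chosen from
the assay geometry: `detection_limit = 2e-5 s^-1` (over a 4200 s window a
slower rate moves the signal by only a few times the typical noise),
`strong` up to 3x the detection limit, `moderate` up to `k_free/4`, `weak`
above. The suppression factor is `k_free / k_mono`, infinite under full
suppression and 1 for the buffer control by construction.

## The synthetic-data generators

Every generator is a pure function of its parameters and a seed, and its
defaults are the study conditions: 2000 s monomerization at 2 s sampling;
260 s association / 18,000 s dissociation at 1, 2, 4, 8 nM; a 12-point
titration spanning 7 pM–15 nM at fixed 100 or 500 pM receptor; a 4200 s
stabilization panel in triplicate at a 5 nM scavenger background. Noise is
additive, homoscedastic, Gaussian and independent per point — the simplest
model consistent with normalized traces and sufficient for recovery testing;
1% of the normalized amplitude is the default working level. Association
amplitudes follow the 1:1 Langmuir steady state `A_max c/(c + KD)`; the
kinetic rate equations specify only the observed rate, so the amplitude
structure is a declared modelling choice. The panel's ground-truth rates
are anchored to published values: free trimer `1.66e-3 s^-1`, IgG binders
fully suppressed, Adalimumab/Infliximab Fab at the just-detectable
`4.0e-5 s^-1`, Golimumab Fab at one third of the free rate; the moderate
tier (Certolizumab, Etanercept) uses `2e-4 s^-1`, a representative value for
rates described qualitatively as moderately fast. Re-trimerization traces
use a phenomenological logistic onset in log-concentration around 10 nM
(no published rate law exists) and are demonstration-only.

What the generators do *not* emulate — and therefore what passing recovery
tests cannot certify on real data: mass-transport limitation and analyte
rebinding (suppressed experimentally by low surface density and high flow),
heteroscedastic or correlated noise, baseline drift, the third, slower
dissociation process seen with multivalently anchored analytes (flagged as
`residual_complex`, never fitted), and genuine multivalent binding
mechanisms.

## Numerical choices and degenerate inputs

- The stable quadratic form of the bound fraction agrees with an
  independent 1-D root solve of the mass-action equilibrium to 1e-9
  relative over `rt, lt, kd` spanning `1e-13`–`1e-7` M.
- DR integrals use trapezoidal quadrature on the stored grid (no
  resampling); off-grid window endpoints are linearly interpolated, which
  keeps the integral additive over adjacent windows.
- Flat traces are flagged (below-detection or normalization error), never
  assigned a spurious small rate; a constant-zero trace cannot be
  normalized and raises an error.
- Fits that do not converge raise errors with diagnostics rather than
  returning silent garbage.
- Concentrations are molar throughout the computation layer; the report
  layer converts to the display convention (`k_on` in 1e6 M^-1 s^-1,
  `k_off` in 1e-5 s^-1, KD in pM). The 17.5 kg/mol monomer molar mass is a
  named constant justified by the published 10 nM = 175 ng/ml pairing;
  whether quoted TNF-alpha concentrations are monomer- or trimer-molar is
  not resolvable from the source material — the mass pairing implies
  monomer-equivalent, and kinetic fits use injected analyte concentrations
  as printed, mirroring the 1:1 model.

## Problem sizes used in validation

The recovery studies shipped with the package use 100 seeds per scenario at
the generator default grids, 1000 bootstrap resamples for titration
intervals, and the full eight-scavenger panel in triplicate; these sizes
give stable Monte-Carlo estimates of bias (well below the 2% acceptance
level), CI coverage and ranking reproducibility while keeping a complete
validation run in the minutes range on a single core.

## Worked example

```{r example, eval = FALSE}
# simulate a kinetic titration with the published Fab rates, then re-analyze
ser <- gen_kinetic_series(k_on = 2.82e6, k_off = 8.52e-5, sigma = 0.01, seed = 7)
run <- run_kinetics(
  filter(ser, phase == "association"),
  filter(ser, phase == "dissociation")
)
glance(run$report)

# solution titration at 100 pM receptor
tab <- gen_titration(rt = 100e-12, kd = 53.6e-12, sigma = 0.01, seed = 7)
fit <- fit_titration(tab, rt = 100e-12, seed = 7)
fit

# stabilization panel
panel <- run_stabilization_panel(gen_stabilization_panel(seed = 7),
  k_free = tnf_refs$k_mono_free
)
tidy(panel)
```

## Known limitations

The 1:1 kinetic and equilibrium models are approximations for multivalent
binders; deviations appear as residual-complex flags and steepness mismatch
rather than as fitted multivalent parameters. Trimer-fraction conversion is
linear in diameter between anchors. The titration bound classification
(`kd < rt/10`) is a pragmatic identifiability rule, not an information
criterion. No mass-transport, rebinding, or tri-exponential models are
provided.
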