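#' Synthetic trace generators
#'
#' All generators are pure functions of their parameters and `seed`: the same
#' call yields bit-identical output. Noise is additive, homoscedastic and
#' independent per point (Gaussian with standard deviation `sigma` in signal
#' units), the simplest model consistent with normalized biosensor traces and
#' sufficient for parameter-recovery testing.
#'
#' @name synthdata
NULL

add_noise <- function(y, sigma, seed) {
  if (sigma < 0) rlang::abort("`sigma` must be >= 0")
  if (sigma == 0) {
    return(y)
  }
  withr::with_seed(seed, y + stats::rnorm(length(y), 0, sigma))
}

#' Generate a mono-exponential monomerization trace
#'
#' Forward model of a trimer-decay (monomerization) experiment: the
#' normalized switching-speed signal rises as `y0 - A * exp(-k * t)` while
#' tethered trimers fall apart under buffer flow, plus i.i.d. Gaussian noise.
#'
#' @param k monomerization rate constant, s^-1. Default: the published
#'   free-trimer rate 1.66e-3 s^-1.
#' @param A amplitude, signal units.
#' @param y0 asymptote, signal units.
#' @param t_grid sampling times, seconds, increasing. Default 0..2000 s at
#'   2 s spacing (the buffer-flow protocol: 2000 s monomerization window,
#'   2 s integration time).
#' @param sigma additive noise sd, signal units.
#' @param seed RNG seed (integer).
#' @param replicate_id,scavenger,phase trace metadata.
#' @return a trace tibble.
#' @export
gen_mono_trace <- function(k = tnf_refs$k_mono_free, A = 1, y0 = 1,
                           t_grid = seq(0, 2000, by = 2), sigma = 0.01,
                           seed = 1, replicate_id = "r1",
                           scavenger = NA_character_,
                           phase = "monomerization") {
  y <- mono_exp(t_grid, k, A, y0)
  trace_tbl(t_grid, add_noise(y, sigma, seed),
    phase = phase,
    conc_M = 0, replicate_id = replicate_id, scavenger = scavenger
  )
}

#' Generate an association/dissociation concentration series
#'
#' Emulates a 1:1 kinetic titration: per analyte concentration `c`, the
#' association phase rises with observed rate `k_obs = c * k_on + k_off`
#' toward the Langmuir steady state `A_max * c / (c + KD)`, then the
#' dissociation phase decays from the association endpoint with rate `k_off`
#' toward baseline 0. Time restarts at 0 in each phase. The standard
#' protocol injects analyte for 260 s and running buffer for 18,000 s.
#'
#' @param concs analyte concentrations, mol/L (positive, distinct). Default
#'   1, 2, 4, 8 nM.
#' @param k_on association rate constant, M^-1 s^-1.
#' @param k_off dissociation rate constant, s^-1.
#' @param assoc_T,dissoc_T phase durations, seconds.
#' @param assoc_dt,dissoc_dt sampling intervals, seconds.
#' @param A_max saturating amplitude, signal units.
#' @param sigma additive noise sd.
#' @param seed RNG seed.
#' @return a trace tibble with `association` and `dissociation` phases, one
#'   replicate per concentration.
#' @export
gen_kinetic_series <- function(concs = c(1, 2, 4, 8) * 1e-9,
                               k_on = 2.82e6, k_off = 8.52e-5,
                               assoc_T = 260, dissoc_T = 18000,
                               assoc_dt = 0.5, dissoc_dt = 5,
                               A_max = 1, sigma = 0.01, seed = 1) {
  stopifnot(all(concs > 0), !anyDuplicated(concs))
  kd <- k_off / k_on
  out <- purrr::imap(sort(concs), function(cc, i) {
    rid <- sprintf("c%g_nM", cc * 1e9)
    a_eq <- A_max * cc / (cc + kd)
    t_a <- seq(0, assoc_T, by = assoc_dt)
    y_a <- association_signal(t_a, cc, k_on, k_off, A = a_eq, y0 = a_eq)
    y_end <- y_a[length(y_a)]
    t_d <- seq(0, dissoc_T, by = dissoc_dt)
    y_d <- dissociation_signal(t_d, k_off, A = y_end, y0 = 0)
    dplyr::bind_rows(
      trace_tbl(t_a, add_noise(y_a, sigma, seed + 2L * i - 1L),
        phase = "association", conc_M = cc, replicate_id = rid
      ),
      trace_tbl(t_d, add_noise(y_d, sigma, seed + 2L * i),
        phase = "dissociation", conc_M = cc, replicate_id = rid
      )
    )
  })
  dplyr::bind_rows(out)
}

#' Generate a biphasic dissociation trace
#'
#' Emulates Fab dissociation from a partially saturated TNF-alpha surface:
#' the unstabilized trimer fraction decays with the fast (monomerization)
#' rate and the scavenger-bound fraction with the slow (dissociation) rate.
#' `stabilized_fraction` partitions the total amplitude between the two
#' components: 1 gives a pure slow phase, 0 a pure fast phase.
#'
#' @param k_fast,k_slow rate constants, s^-1 (defaults: published biphasic
#'   pair 1.42e-3 and 8.52e-5 s^-1).
#' @param stabilized_fraction fraction of amplitude in the slow component,
#'   in `[0, 1]`.
#' @param A total amplitude; `y0` baseline offset.
#' @param t_grid sampling times, seconds.
#' @param sigma additive noise sd; `seed` RNG seed.
#' @param replicate_id,conc_M trace metadata.
#' @return a single dissociation-phase trace tibble.
#' @export
gen_biexp_trace <- function(k_fast = tnf_refs$k_fast, k_slow = tnf_refs$k_slow,
                            stabilized_fraction = 0.5, A = 1, y0 = 0,
                            t_grid = seq(0, 18000, by = 5), sigma = 0.01,
                            seed = 1, replicate_id = "r1", conc_M = 0) {
  stopifnot(stabilized_fraction >= 0, stabilized_fraction <= 1)
  a_slow <- stabilized_fraction * A
  a_fast <- (1 - stabilized_fraction) * A
  y <- bi_exp(t_grid, k_fast, k_slow, -a_fast, -a_slow, y0)
  trace_tbl(t_grid, add_noise(y, sigma, seed),
    phase = "dissociation",
    conc_M = conc_M, replicate_id = replicate_id
  )
}

#' Generate a solution-equilibrium titration table
#'
#' Emulates the residual-free-TNF readout: a fixed receptor (TNF-alpha)
#' concentration `rt` is equilibrated against a ligand (antibody) dilution
#' series; the normalized response is proportional to the free-receptor
#' fraction, `slope_scale * (1 - b(rt, lt, kd))`, plus noise.
#'
#' @param rt total receptor concentration, mol/L (e.g. 100e-12 or 500e-12).
#' @param kd solution dissociation constant, mol/L.
#' @param lt_grid titrant concentrations, mol/L; should span >= 3 decades
#'   around `kd`. Default: 12 points log-spaced over 7 pM to 15 nM.
#' @param slope_scale response at `lt = 0` (all receptor free).
#' @param sigma additive noise sd (response units).
#' @param seed RNG seed.
#' @return tibble with columns `lt_M`, `response`, `rt_M`.
#' @export
gen_titration <- function(rt = 100e-12, kd = 53.6e-12,
                          lt_grid = 10^seq(log10(7e-12), log10(15e-9), length.out = 12),
                          slope_scale = 1, sigma = 0.02, seed = 1) {
  stopifnot(rt > 0, kd >= 0, all(lt_grid >= 0))
  b <- equilibrium_bound_fraction(rt, lt_grid, kd)
  resp <- add_noise(slope_scale * (1 - b), sigma, seed)
  tibble::tibble(lt_M = lt_grid, response = resp, rt_M = rt)
}

#' Default trimer-stabilization panel specification
#'
#' The eight therapeutic scavenger formats plus the no-antibody control, with
#' the generator's ground-truth monomerization rates anchored to the
#' published values: free trimer 1.66e-3 s^-1; full suppression (rate 0) for
#' the avid IgG binders Adalimumab, Infliximab and Golimumab; the
#' just-detectable 4.0e-5 s^-1 for Adalimumab and Infliximab Fab; a moderate
#' 2e-4 s^-1 for Certolizumab and Etanercept; and the free rate reduced by a
#' factor of three for Golimumab Fab.
#'
#' @return tibble with columns `scavenger`, `k_mono`, `amplitude_fraction`.
#' @export
default_panel_spec <- function() {
  tibble::tibble(
    scavenger = c(
      "buffer", "Adalimumab", "Infliximab", "Golimumab",
      "Adalimumab Fab", "Infliximab Fab", "Certolizumab",
      "Etanercept", "Golimumab Fab"
    ),
    k_mono = c(
      tnf_refs$k_mono_free, 0, 0, 0,
      tnf_refs$k_mono_fab_bound, tnf_refs$k_mono_fab_bound,
      2e-4, 2e-4, tnf_refs$k_mono_free / 3
    ),
    amplitude_fraction = 1
  )
}

#' Generate a trimer-stabilization panel
#'
#' One stabilization-phase trace per scavenger and replicate: the signal
#' rises by `amplitude_fraction * (1 - exp(-k_mono * t))` as scavenger-bound
#' trimers decay (flat when monomerization is fully suppressed). The standard
#' protocol records 4200 s at a constant 5 nM scavenger background, in
#' triplicate.
#'
#' @param panel tibble with columns `scavenger`, `k_mono` (s^-1) and
#'   `amplitude_fraction` (see [default_panel_spec()]).
#' @param t_grid sampling times, seconds (default 0..4200 s at 2 s).
#' @param sigma additive noise sd per replicate point.
#' @param n_replicates replicates per scavenger (default 3).
#' @param conc_M scavenger background concentration recorded as metadata
#'   (default 5 nM).
#' @param seed RNG seed.
#' @return a trace tibble, phase `"stabilization"`.
#' @export
gen_stabilization_panel <- function(panel = default_panel_spec(),
                                    t_grid = seq(0, 4200, by = 2),
                                    sigma = 0.01, n_replicates = 3,
                                    conc_M = 5e-9, seed = 1) {
  stopifnot(all(panel$k_mono >= 0), all(t_grid >= 0))
  out <- list()
  idx <- 0L
  for (i in seq_len(nrow(panel))) {
    for (r in seq_len(n_replicates)) {
      idx <- idx + 1L
      y <- panel$amplitude_fraction[i] * (1 - exp(-panel$k_mono[i] * t_grid))
      out[[idx]] <- trace_tbl(
        t_grid, add_noise(y, sigma, seed + idx),
        phase = "stabilization",
        conc_M = if (panel$scavenger[i] == "buffer") 0 else conc_M,
        replicate_id = sprintf("r%d", r),
        scavenger = panel$scavenger[i]
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Generate a phenomenological re-trimerization trace (demonstration only)
#'
#' Re-trimerization of surface monomers under free TNF-alpha has a reported
#' concentration onset near 10 nM and completes within minutes above 200 nM,
#' but no published rate law. This generator uses a pseudo-first-order rise
#' whose effective rate follows a soft logistic onset in log-concentration;
#' it exists to exercise plotting/IO and is excluded from quantitative
#' analyses.
#'
#' @param conc free TNF-alpha concentration, mol/L.
#' @param onset_M onset concentration of trimer formation (default 10 nM).
#' @param k_max maximal re-trimerization rate, s^-1 (default ln(2)/120 so the
#'   rise completes within minutes well above onset).
#' @param width logistic width in decades of concentration.
#' @param t_grid sampling times, seconds.
#' @param sigma,seed noise sd and RNG seed.
#' @return a trace tibble, phase `"association"`.
#' @export
gen_retrimerization_trace <- function(conc, onset_M = 10e-9,
                                      k_max = log(2) / 120, width = 0.15,
                                      t_grid = seq(0, 600, by = 2),
                                      sigma = 0.01, seed = 1) {
  stopifnot(conc >= 0)
  k_eff <- if (conc == 0) 0 else {
    k_max / (1 + exp(-(log10(conc) - log10(onset_M)) / width))
  }
  y <- 1 - exp(-k_eff * t_grid)
  trace_tbl(t_grid, add_noise(y, sigma, seed),
    phase = "association",
    conc_M = conc, replicate_id = sprintf("c%g_nM", conc * 1e9)
  )
}
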