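#' Reference constants for TNF-alpha kinetics and sizing
#'
#' Published reference values used throughout the package: the intrinsic
#' trimer-to-monomer decay (monomerization) rate of surface-tethered TNF-alpha,
#' the fast/slow rates of the biphasic Fab dissociation, the residual
#' monomerization rate of Fab-stabilized trimers, measured and PDB-predicted
#' hydrodynamic diameters of trimer and monomer, the monomer molar mass used
#' for molar/mass-concentration conversions, and the kinetic rate-constant
#' table for the TNF-alpha/Adalimumab system in both assay orientations.
#'
#' @format A named list:
#' \describe{
#'   \item{monomer_mass_g_mol}{TNF-alpha monomer molar mass, g/mol (17.5 kDa).}
#'   \item{k_mono_free, se_k_mono_free}{free-trimer monomerization rate and its
#'     uncertainty, s^-1.}
#'   \item{k_fast, k_slow}{fast (trimer decay) and slow (Fab dissociation)
#'     rates of the biphasic dissociation, s^-1.}
#'   \item{k_mono_fab_bound}{residual monomerization rate of trimers bound by
#'     Adalimumab/Infliximab Fab, s^-1.}
#'   \item{dh_trimer_nm, dh_monomer_nm}{measured hydrodynamic diameters, nm.}
#'   \item{dh_trimer_predicted_nm, dh_monomer_predicted_nm}{shell-model
#'     predictions from PDB structures (named by PDB id), nm.}
#'   \item{rate_table}{tibble of k_on (M^-1 s^-1), k_off (s^-1) and their
#'     standard errors per immobilized-ligand/analyte orientation, plus the
#'     published K_D in pM.}
#' }
#' @export
tnf_refs <- list(
  monomer_mass_g_mol = 17500,
  k_mono_free = 1.66e-3,
  se_k_mono_free = 0.25e-3,
  k_fast = 1.42e-3,
  se_k_fast = 0.39e-3,
  k_slow = 8.52e-5,
  se_k_slow = 0.28e-5,
  k_mono_fab_bound = 4.0e-5,
  dh_trimer_nm = 5.6,
  dh_monomer_nm = 3.9,
  dh_trimer_predicted_nm = c("3ALQ" = 5.76, "1TNF" = 6.10),
  dh_monomer_predicted_nm = c("4G3Y" = 4.39, "3WD5" = 4.44),
  rate_table = tibble::tibble(
    immobilized = c("TNF-alpha", "Adalimumab Fab", "TNF-alpha", "Adalimumab"),
    analyte     = c("Adalimumab Fab", "TNF-alpha", "Adalimumab", "TNF-alpha"),
    k_on        = c(2.82e6, 6.73e6, 8.22e6, 7.86e6),
    se_k_on     = c(0.10e6, 0.03e6, 0.15e6, 0.07e6),
    k_off       = c(8.52e-5, 8.62e-5, 7.96e-5, 4.60e-5),
    se_k_off    = c(0.28e-5, 0.23e-5, 0.24e-5, 1.19e-5),
    kd_pM       = c(30.2, 12.8, 9.7, 5.9),
    se_kd_pM    = c(1.5, 0.3, 0.3, 1.5)
  )
)

#' Mono-exponential decay/rise signal
#'
#' The single-exponential model `y(t) = y0 - A * exp(-k * t)` used for
#' TNF-alpha monomerization traces (signal rising toward `y0` as trimers
#' decay) and, with negative `A`, for simple dissociation decays.
#'
#' @param t time, seconds (vectorized).
#' @param k rate constant, s^-1 (`k >= 0`).
#' @param A amplitude, signal units; `y(0) = y0 - A`.
#' @param y0 asymptotic offset, signal units.
#' @return numeric vector of signal values.
#' @examples
#' mono_exp(0, k = 1.66e-3, A = 1, y0 = 1)      # 0
#' mono_exp(log(2) / 1.66e-3, 1.66e-3, 1, 1)    # half amplitude
#' @export
mono_exp <- function(t, k, A, y0) {
  stopifnot(k >= 0)
  y0 - A * exp(-k * t)
}

#' Dissociation-phase signal
#'
#' `y(t) = A * exp(-k_off * t) + y0`: the dissociation decay toward the
#' baseline offset `y0`, the form fitted globally (shared `k_off`) across a
#' concentration series.
#'
#' @param t time since start of dissociation, seconds.
#' @param k_off dissociation rate constant, s^-1.
#' @param A amplitude, signal units.
#' @param y0 offset, signal units.
#' @return numeric vector of signal values.
#' @export
dissociation_signal <- function(t, k_off, A, y0) {
  stopifnot(k_off >= 0)
  A * exp(-k_off * t) + y0
}

#' Association-phase signal under pseudo-first-order 1:1 binding
#'
#' `y(t) = y0 - A * exp(-(c * k_on + k_off) * t)`: the observed rate is
#' `k_obs = c * k_on + k_off`. At `c = 0` this reduces to a mono-exponential
#' with rate `k_off`.
#'
#' @param t time since injection, seconds.
#' @param conc analyte concentration, mol/L (`>= 0`).
#' @param k_on association rate constant, M^-1 s^-1 (`> 0`).
#' @param k_off dissociation rate constant, s^-1 (`>= 0`).
#' @param A amplitude, signal units.
#' @param y0 offset, signal units.
#' @return numeric vector of signal values.
#' @export
association_signal <- function(t, conc, k_on, k_off, A, y0) {
  stopifnot(conc >= 0, k_on > 0, k_off >= 0)
  y0 - A * exp(-(conc * k_on + k_off) * t)
}

#' Observed association rate
#'
#' @param conc analyte concentration, mol/L.
#' @param k_on association rate constant, M^-1 s^-1.
#' @param k_off dissociation rate constant, s^-1.
#' @return `k_obs = conc * k_on + k_off`, s^-1.
#' @export
k_obs_rate <- function(conc, k_on, k_off) conc * k_on + k_off

#' Bi-exponential decay signal
#'
#' `y(t) = y0 - a_fast * exp(-k_fast * t) - a_slow * exp(-k_slow * t)`: the
#' biphasic dissociation model that superimposes trimer monomerization (fast)
#' on scavenger dissociation (slow), both components sharing the offset `y0`.
#' With `a_fast = 0` it reduces pointwise to [mono_exp()] with rate `k_slow`.
#'
#' @param t time, seconds.
#' @param k_fast,k_slow rate constants, s^-1 (`k_fast > k_slow > 0` for a
#'   well-formed biphasic model; not enforced here so degenerate cases can be
#'   evaluated).
#' @param a_fast,a_slow component amplitudes, signal units.
#' @param y0 shared offset, signal units.
#' @return numeric vector of signal values.
#' @export
bi_exp <- function(t, k_fast, k_slow, a_fast, a_slow, y0) {
  y0 - a_fast * exp(-k_fast * t) - a_slow * exp(-k_slow * t)
}

#' Equilibrium bound-receptor fraction with depletion correction
#'
#' Exact mass-action solution for `R + L <=> RL` when receptor and ligand
#' concentrations are comparable to the dissociation constant, so ligand
#' depletion cannot be neglected. The bound fraction of total receptor is
#'
#' `b = ((rt + lt + kd) - sqrt((rt + lt + kd)^2 - 4 rt lt)) / (2 rt)`
#'
#' evaluated in the numerically stable form
#' `b = 2 lt / (S + sqrt(S^2 - 4 rt lt))`, `S = rt + lt + kd`, which avoids
#' catastrophic cancellation when `lt << rt + kd`.
#'
#' @param rt total receptor concentration, mol/L (`> 0`). In the titration
#'   assay this is the fixed TNF-alpha concentration.
#' @param lt total ligand (titrant) concentration, mol/L (`>= 0`), e.g. the
#'   titrated antibody.
#' @param kd dissociation constant, mol/L (`>= 0`).
#' @return bound fraction in `[0, min(1, lt/rt)]`. The free-receptor fraction
#'   read out by the residual-free-TNF assay is `1 - b`.
#' @examples
#' equilibrium_bound_fraction(100e-12, 100e-12, 53.6e-12)
#' @export
equilibrium_bound_fraction <- function(rt, lt, kd) {
  if (any(rt <= 0)) {
    rlang::abort("`rt` must be > 0; use the limit lt/(lt + kd) for rt -> 0.")
  }
  stopifnot(all(lt >= 0), all(kd >= 0))
  s <- rt + lt + kd
  disc <- s^2 - 4 * rt * lt
  disc[disc < 0] <- 0 # guard tiny negative rounding
  2 * lt / (s + sqrt(disc))
}

#' Dissociation constant from kinetic rate constants
#'
#' `KD = k_off / k_on`. When standard errors are supplied the uncertainty is
#' propagated to first order:
#' `se_kd / kd = sqrt((se_k_on/k_on)^2 + (se_k_off/k_off)^2)`.
#'
#' @param k_on association rate constant, M^-1 s^-1 (`> 0`).
#' @param k_off dissociation rate constant, s^-1 (`>= 0`).
#' @param se_k_on,se_k_off optional standard errors.
#' @return `KD` in mol/L (numeric, vectorized); if both standard errors are
#'   given, a tibble with columns `kd` and `se_kd`.
#' @examples
#' kd_from_rates(2.82e6, 8.52e-5) * 1e12  # pM
#' @export
kd_from_rates <- function(k_on, k_off, se_k_on = NULL, se_k_off = NULL) {
  if (any(k_on <= 0)) rlang::abort("`k_on` must be > 0.")
  stopifnot(all(k_off >= 0))
  kd <- k_off / k_on
  if (is.null(se_k_on) || is.null(se_k_off)) {
    return(kd)
  }
  se_kd <- kd * sqrt((se_k_on / k_on)^2 +
    ifelse(k_off > 0, (se_k_off / k_off)^2, 0))
  tibble::tibble(kd = kd, se_kd = se_kd)
}

#' Convert molar to mass concentration
#'
#' @param conc molar concentration, mol/L (`>= 0`).
#' @param molar_mass molar mass, g/mol (`> 0`); defaults to the TNF-alpha
#'   monomer mass of 17.5 kg/mol, which reproduces the 10 nM = 175 ng/ml
#'   pairing used for re-trimerization onset concentrations.
#' @return mass concentration in g/L (numerically equal to mg/ml * 1e-3;
#'   multiply by 1e6 for ng/ml).
#' @examples
#' molar_to_mass_conc(10e-9) * 1e6   # 175 ng/ml
#' @export
molar_to_mass_conc <- function(conc, molar_mass = tnf_refs$monomer_mass_g_mol) {
  stopifnot(all(conc >= 0), molar_mass > 0)
  conc * molar_mass
}

#' Dynamic-response integral of a normalized switching trace
#'
#' The switching-speed observable (dynamic response, DR) is the time integral
#' of the normalized fluorescence transition over a window:
#' `DR = integral_{t1}^{t2} F_norm dt`. Computed by trapezoidal quadrature on
#' the stored grid; window endpoints falling between grid points use linearly
#' interpolated signal values, so DR is additive over adjacent windows.
#'
#' @param trace a trace tibble (see [trace_tbl()]) holding a single trace with
#'   columns `time_s` and `signal`.
#' @param t1,t2 integration window, seconds, with `t1 < t2`, both inside the
#'   trace's time range.
#' @return the dimensionless DR value (scalar).
#' @export
dr_integral <- function(trace, t1, t2) {
  trace <- validate_traces(trace, single = TRUE)
  t <- trace$time_s
  y <- trace$signal
  if (t1 >= t2) rlang::abort("`t1` must be < `t2`.")
  if (t1 < t[1] || t2 > t[length(t)]) {
    rlang::abort(sprintf(
      "integration window [%g, %g] outside trace range [%g, %g]",
      t1, t2, t[1], t[length(t)]
    ))
  }
  inside <- t > t1 & t < t2
  tt <- c(t1, t[inside], t2)
  yy <- c(stats::approx(t, y, t1)$y, y[inside], stats::approx(t, y, t2)$y)
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}
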