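# Independent oracle: bound fraction from a 1-D root solve of the mass-action
# equilibrium (R + L <=> RL), kept free of the closed-form implementation.
bound_fraction_rootsolve <- function(rt, lt, kd) {
  if (lt == 0) {
    return(0)
  }
  f <- function(x) (rt - x) * (lt - x) - kd * x
  hi <- min(rt, lt)
  x <- stats::uniroot(f, c(0, hi), tol = hi * 1e-14)$root
  x / rt
}

# Dense noiseless dissociation trace in Eq-3 form (A e^-kt + y0).
make_dissoc_trace <- function(k_off, A = 1, y0 = 0, t_max = 18000, dt = 5,
                              replicate_id = "r1", conc_M = 1e-9) {
  t <- seq(0, t_max, by = dt)
  trace_tbl(t, A * exp(-k_off * t) + y0,
    phase = "dissociation",
    conc_M = conc_M, replicate_id = replicate_id
  )
}
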