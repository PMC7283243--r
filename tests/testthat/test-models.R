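test_that("dr_integral computes trapezoidal window integrals", {
  t <- seq(0, 1, by = 0.001)
  flat <- trace_tbl(t, rep(1, length(t)), phase = "monomerization")
  expect_equal(dr_integral(flat, 0, 1), 1.0)

  doubled <- trace_tbl(t, rep(2, length(t)), phase = "monomerization")
  expect_equal(dr_integral(doubled, 0, 1), 2 * dr_integral(flat, 0, 1))

  decay <- trace_tbl(t, exp(-t), phase = "monomerization")
  expect_equal(dr_integral(decay, 0, 1), 1 - exp(-1), tolerance = 1e-6)

  # additive over adjacent windows, including off-grid cut points
  expect_equal(
    dr_integral(decay, 0, 0.3712) + dr_integral(decay, 0.3712, 1),
    dr_integral(decay, 0, 1)
  )

  expect_error(dr_integral(decay, -0.5, 1), "outside")
  expect_error(dr_integral(decay, 0.8, 0.2), "t1")
})

test_that("mono_exp has the right anchors and half-life", {
  expect_equal(mono_exp(0, k = 0.5, A = 0.7, y0 = 1.2), 1.2 - 0.7)
  expect_equal(mono_exp(1e9, k = 0.5, A = 0.7, y0 = 1.2), 1.2)
  expect_equal(mono_exp(c(0, 10, 100), k = 1, A = 0, y0 = 3), rep(3, 3))
  # half the amplitude remains at t = ln 2 / k; published rate 1.66e-3 s^-1
  k <- 1.66e-3
  t_half <- log(2) / k
  expect_equal(t_half, 417.6, tolerance = 1e-3)
  y <- mono_exp(t_half, k, A = 1, y0 = 1)
  expect_equal((1 - y) / 1, 0.5)
})

test_that("association_signal observed rate is affine in concentration", {
  # published IgG rates: c*k_on + k_off at 8 nM
  expect_equal(k_obs_rate(8e-9, 8.22e6, 7.96e-5), 6.584e-2, tolerance = 1e-3)
  expect_equal(k_obs_rate(0, 8.22e6, 7.96e-5), 7.96e-5)
  c1 <- k_obs_rate(1e-9, 8.22e6, 7.96e-5)
  c2 <- k_obs_rate(2e-9, 8.22e6, 7.96e-5)
  c3 <- k_obs_rate(3e-9, 8.22e6, 7.96e-5)
  expect_equal(c3 - c2, c2 - c1) # affine with slope k_on
  # c = 0 reduces to the dissociation form with the same k_off, A, y0
  t <- seq(0, 5000, by = 10)
  expect_equal(
    association_signal(t, 0, k_on = 8.22e6, k_off = 7.96e-5, A = -0.8, y0 = 0.1),
    dissociation_signal(t, 7.96e-5, A = 0.8, y0 = 0.1)
  )
})

test_that("bi_exp reduces to mono_exp and decays per component", {
  t <- seq(0, 18000, by = 20)
  expect_equal(
    bi_exp(t, k_fast = 1.42e-3, k_slow = 8.52e-5, a_fast = 0, a_slow = 0.6, y0 = 1),
    mono_exp(t, k = 8.52e-5, A = 0.6, y0 = 1)
  )
  expect_equal(
    bi_exp(0, 1.42e-3, 8.52e-5, a_fast = 0.3, a_slow = 0.5, y0 = 1),
    1 - 0.3 - 0.5
  )
  # published rate pair: fast component ~5.85% left at 2000 s, slow ~84.3%
  expect_equal(exp(-1.42e-3 * 2000), 0.0585, tolerance = 1e-2)
  expect_equal(exp(-8.52e-5 * 2000), 0.8433, tolerance = 1e-3)
  y <- bi_exp(2000, 1.42e-3, 8.52e-5, a_fast = 0.5, a_slow = 0.5, y0 = 1)
  expect_equal(1 - y, 0.5 * exp(-1.42e-3 * 2000) + 0.5 * exp(-8.52e-5 * 2000))
})

test_that("equilibrium_bound_fraction matches the mass-action root solve", {
  # published condition: rt = 100 pM, kd = 53.6 pM, equimolar titrant
  b <- equilibrium_bound_fraction(100e-12, 100e-12, 53.6e-12)
  expect_equal(b, 0.488, tolerance = 1e-3)
  expect_equal(b, bound_fraction_rootsolve(100e-12, 100e-12, 53.6e-12),
    tolerance = 1e-9
  )

  expect_equal(equilibrium_bound_fraction(1e-10, 0, 5e-11), 0)

  # no-depletion limit: rt -> 0 gives lt / (lt + kd)
  lt <- 2e-10
  kd <- 5e-11
  expect_equal(
    equilibrium_bound_fraction(kd * 1e-6, lt, kd), lt / (lt + kd),
    tolerance = 1e-5
  )
  expect_error(equilibrium_bound_fraction(0, 1e-10, 1e-11), "rt")

  # log-grid property check against the independent root solve
  grid <- 10^seq(-13, -7, length.out = 7)
  for (rt in grid) {
    for (lt in grid) {
      for (kd in grid) {
        expect_equal(
          equilibrium_bound_fraction(rt, lt, kd),
          bound_fraction_rootsolve(rt, lt, kd),
          tolerance = 1e-9
        )
      }
    }
  }
  # bounds: 0 <= b <= min(1, lt/rt)
  rt <- 3e-10
  lt <- 10^seq(-13, -8, length.out = 50)
  b <- equilibrium_bound_fraction(rt, lt, 4e-11)
  expect_true(all(b >= 0 & b <= pmin(1, lt / rt) + 1e-12))
})

test_that("kd_from_rates reproduces the published rate table and propagates error", {
  tab <- tnf_refs$rate_table
  kd_pM <- kd_from_rates(tab$k_on, tab$k_off) * 1e12
  expect_equal(round(kd_pM, 1), c(30.2, 12.8, 9.7, 5.9))
  # identity: kd * k_on == k_off up to floating rounding
  expect_equal(kd_from_rates(tab$k_on, tab$k_off) * tab$k_on, tab$k_off)
  expect_equal(kd_from_rates(2.82e6, 0), 0)
  expect_error(kd_from_rates(-1, 1e-5), "k_on")
  # first-order propagation
  res <- kd_from_rates(2.82e6, 8.52e-5, se_k_on = 0.10e6, se_k_off = 0.28e-5)
  expect_equal(
    res$se_kd,
    res$kd * sqrt((0.10 / 2.82)^2 + (0.28 / 8.52)^2)
  )
})

test_that("molar_to_mass_conc reproduces the published concentration pairings", {
  expect_equal(molar_to_mass_conc(10e-9) * 1e6, 175) # ng/ml
  expect_equal(molar_to_mass_conc(200e-9) * 1e3, 3.5) # ug/ml
  expect_equal(molar_to_mass_conc(0), 0)
  expect_error(molar_to_mass_conc(1e-9, molar_mass = 0))
})
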