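test_that("generators are pure functions of parameters and seed", {
  a <- gen_mono_trace(sigma = 0.02, seed = 7)
  b <- gen_mono_trace(sigma = 0.02, seed = 7)
  expect_identical(a, b)
  c <- gen_mono_trace(sigma = 0.02, seed = 8)
  expect_false(identical(a$signal, c$signal))

  s1 <- gen_kinetic_series(sigma = 0.01, seed = 5)
  s2 <- gen_kinetic_series(sigma = 0.01, seed = 5)
  expect_identical(s1, s2)

  p1 <- gen_stabilization_panel(seed = 3)
  p2 <- gen_stabilization_panel(seed = 3)
  expect_identical(p1, p2)

  t1 <- gen_titration(seed = 9)
  expect_identical(t1, gen_titration(seed = 9))
})

test_that("sigma = 0 gives exactly the analytic curves", {
  tg <- seq(0, 2000, by = 4)
  tr <- gen_mono_trace(k = 1.66e-3, A = 0.9, y0 = 1.1, t_grid = tg, sigma = 0)
  expect_identical(tr$signal, mono_exp(tg, 1.66e-3, 0.9, 1.1))

  bt <- gen_biexp_trace(stabilized_fraction = 1, sigma = 0, t_grid = tg)
  expect_equal(bt$signal, exp(-tnf_refs$k_slow * tg), tolerance = 1e-12)
  bt0 <- gen_biexp_trace(stabilized_fraction = 0, sigma = 0, t_grid = tg)
  expect_equal(bt0$signal, exp(-tnf_refs$k_fast * tg), tolerance = 1e-12)

  tit <- gen_titration(rt = 1e-10, kd = 5e-11, sigma = 0)
  expect_equal(
    tit$response,
    1 - equilibrium_bound_fraction(1e-10, tit$lt_M, 5e-11)
  )
  # lt = 0 point responds with the full scale (all receptor free)
  tit0 <- gen_titration(rt = 1e-10, kd = 5e-11, lt_grid = c(0, 1e-11, 1e-10, 1e-9, 1e-8, 1e-7), sigma = 0)
  expect_equal(tit0$response[1], 1)
  # saturation: lt >> rt + kd drives the response to 0
  expect_lt(tit0$response[6], 0.01)
})

test_that("kinetic series has Langmuir amplitude ordering and phase structure", {
  ser <- gen_kinetic_series(sigma = 0)
  ends <- ser |>
    dplyr::filter(phase == "association") |>
    dplyr::group_by(conc_M) |>
    dplyr::summarise(end = dplyr::last(signal), .groups = "drop") |>
    dplyr::arrange(conc_M)
  expect_true(all(diff(ends$end) > 0)) # steady state monotone in c
  # dissociation starts where association ended (noiseless continuity)
  d0 <- ser |>
    dplyr::filter(phase == "dissociation") |>
    dplyr::group_by(conc_M) |>
    dplyr::summarise(start = dplyr::first(signal), .groups = "drop") |>
    dplyr::arrange(conc_M)
  expect_equal(d0$start, ends$end, tolerance = 1e-10)
})

test_that("stabilization panel generator anchors rates to the published values", {
  spec <- default_panel_spec()
  expect_equal(spec$k_mono[spec$scavenger == "buffer"], 1.66e-3)
  expect_equal(spec$k_mono[spec$scavenger == "Adalimumab Fab"], 4.0e-5)
  expect_equal(spec$k_mono[spec$scavenger == "Golimumab Fab"], 1.66e-3 / 3)
  expect_equal(
    spec$k_mono[spec$scavenger %in% c("Adalimumab", "Infliximab", "Golimumab")],
    rep(0, 3)
  )
  # k_mono = 0 -> flat trace
  flat <- gen_stabilization_panel(
    panel = tibble::tibble(scavenger = "x", k_mono = 0, amplitude_fraction = 1),
    sigma = 0, n_replicates = 1
  )
  expect_true(all(flat$signal == 0))
  # triplicates with independent noise
  p <- gen_stabilization_panel(seed = 2)
  reps <- p |>
    dplyr::filter(scavenger == "buffer") |>
    dplyr::distinct(replicate_id)
  expect_equal(nrow(reps), 3)
  r1 <- p$signal[p$scavenger == "buffer" & p$replicate_id == "r1"]
  r2 <- p$signal[p$scavenger == "buffer" & p$replicate_id == "r2"]
  expect_false(identical(r1, r2))
})

test_that("re-trimerization generator has a soft onset near 10 nM", {
  low <- gen_retrimerization_trace(1e-9, sigma = 0)
  high <- gen_retrimerization_trace(200e-9, sigma = 0)
  expect_lt(max(low$signal), 0.05) # essentially no rise below onset
  expect_gt(max(high$signal), 0.9) # completes within minutes above 200 nM
})
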