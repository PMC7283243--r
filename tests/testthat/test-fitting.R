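test_that("normalize_trace is scale-invariant and idempotent", {
  tr <- gen_mono_trace(A = 0.8, y0 = 2, sigma = 0, t_grid = seq(0, 500, 5))
  norm1 <- normalize_trace(tr, "initial_value")
  expect_equal(norm1$signal[1], 1)
  scaled <- dplyr::mutate(tr, signal = signal * 5)
  expect_equal(normalize_trace(scaled, "initial_value")$signal, norm1$signal)
  expect_equal(normalize_trace(norm1, "initial_value")$signal, norm1$signal)

  base <- normalize_trace(tr, "baseline", baseline_window = c(0, 50))
  expect_equal(
    mean(base$signal[base$time_s <= 50]), 1,
    tolerance = 1e-12
  )

  zero <- trace_tbl(0:10, rep(0, 11), phase = "monomerization")
  expect_error(normalize_trace(zero, "initial_value"), "zero")
})

test_that("fit_monomerization recovers the generating rate and flags flat traces", {
  tr <- gen_mono_trace(k = 1.66e-3, sigma = 0)
  f <- fit_monomerization(tr)
  expect_s3_class(f, "exp_fit")
  expect_equal(f$k, 1.66e-3, tolerance = 1e-3)
  expect_equal(f$A, 1, tolerance = 1e-6)
  expect_identical(f$flag, "ok")

  flat <- trace_tbl(seq(0, 2000, 2), rep(0.5, 1001), phase = "monomerization")
  ff <- fit_monomerization(flat)
  expect_identical(ff$flag, "below_detection")

  expect_error(
    fit_monomerization(make_dissoc_trace(1e-4)),
    "phase"
  )
})

test_that("replicate monomerization fits report mean and SEM, excluding failures", {
  traces <- dplyr::bind_rows(lapply(1:4, function(i) {
    gen_mono_trace(sigma = 0.01, seed = 40 + i, replicate_id = paste0("r", i))
  }))
  reps <- fit_monomerization_replicates(traces)
  expect_equal(reps$n_used, 4)
  # SEM is sd/sqrt(n) of the per-replicate rates (hand formula)
  expect_equal(reps$k_sem, stats::sd(reps$summary$k) / 2)
  expect_equal(reps$k_mean, mean(reps$summary$k))
  expect_equal(reps$k_mean, 1.66e-3, tolerance = 0.03)

  # a flat replicate is excluded with a reason, SEM over the remainder
  with_flat <- dplyr::bind_rows(
    traces,
    trace_tbl(seq(0, 2000, 2), rep(1, 1001),
      phase = "monomerization",
      replicate_id = "r5"
    )
  )
  reps2 <- fit_monomerization_replicates(with_flat)
  expect_equal(reps2$n_used, 4)
  expect_equal(nrow(reps2$excluded), 1)
  expect_match(reps2$excluded$reason, "detection")
})

test_that("global dissociation fit shares k_off and matches per-curve fits when noiseless", {
  traces <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_dissoc_trace(8.52e-5, A = 0.2 * i, y0 = 0.05 * (i - 1), replicate_id = paste0("r", i))
  }))
  g <- global_fit_dissociation(traces)
  expect_equal(g$k_off, 8.52e-5, tolerance = 1e-3)
  expect_equal(g$per_trace$A, 0.2 * (1:4), tolerance = 1e-4)
  # noiseless: shared fit equals each per-curve fit
  expect_equal(g$per_trace$k_off_individual, rep(8.52e-5, 4), tolerance = 1e-3)
  expect_true(is.na(suppressWarnings(
    global_fit_dissociation(make_dissoc_trace(8.52e-5))
  )$sem_k_off))
  expect_warning(global_fit_dissociation(make_dissoc_trace(8.52e-5)), "single")
})

test_that("global association fit recovers k_on; k_obs regresses on concentration", {
  ser <- gen_kinetic_series(k_on = 8.22e6, k_off = 7.96e-5, sigma = 0)
  assoc <- dplyr::filter(ser, phase == "association")
  a <- global_fit_association(assoc, k_off = 7.96e-5)
  expect_equal(a$k_on, 8.22e6, tolerance = 1e-3)
  # independent cross-check: linear regression of individually fitted k_obs on c
  lmfit <- stats::lm(k_obs_individual ~ conc_M, data = a$per_trace)
  expect_equal(unname(stats::coef(lmfit)[2]), 8.22e6, tolerance = 1e-3)
  expect_equal(unname(stats::coef(lmfit)[1]), 7.96e-5, tolerance = 1e-2)

  zero_conc <- gen_mono_trace(sigma = 0, phase = "association")
  expect_error(global_fit_association(zero_conc, 7.96e-5), "conc_M > 0")
})

test_that("bi-exponential global fit recovers both rates with shared rates", {
  traces <- dplyr::bind_rows(
    gen_biexp_trace(stabilized_fraction = 0.4, sigma = 0, replicate_id = "r1"),
    gen_biexp_trace(stabilized_fraction = 0.7, sigma = 0, replicate_id = "r2")
  )
  fb <- fit_biexp_global(traces)
  expect_equal(fb$k_fast, 1.42e-3, tolerance = 5e-3)
  expect_equal(fb$k_slow, 8.52e-5, tolerance = 5e-3)
  expect_gt(fb$k_fast, fb$k_slow) # ordering enforced
  expect_identical(fb$flag, "ok")
  # amplitude partition per trace
  expect_equal(-fb$per_trace$a_fast, c(0.6, 0.3), tolerance = 1e-3)
  expect_equal(-fb$per_trace$a_slow, c(0.4, 0.7), tolerance = 1e-3)

  # a_fast = 0 -> flagged effectively mono-exponential; the resolvable rate
  # is the generating slow rate, wherever the fit labeled it
  pure_slow <- gen_biexp_trace(stabilized_fraction = 1, sigma = 0.005, seed = 2)
  fs <- fit_biexp_global(pure_slow)
  expect_true(startsWith(fs$flag, "effective_mono") ||
    fs$flag == "rates_unresolved")
  if (startsWith(fs$flag, "effective_mono")) {
    expect_equal(fs$k_effective, tnf_refs$k_slow, tolerance = 0.05)
  }
})

test_that("decay model selection prefers the generating model", {
  bi <- gen_biexp_trace(stabilized_fraction = 0.5, sigma = 0.01, seed = 11)
  sel_bi <- select_decay_model(bi)
  expect_identical(sel_bi$decision, "bi")
  expect_lt(sel_bi$p_value, 0.05)

  mono <- gen_mono_trace(
    k = 8.52e-5, A = -1, y0 = 0, t_grid = seq(0, 18000, 10),
    sigma = 0.01, seed = 12
  )
  mono$phase <- "dissociation"
  sel_mono <- select_decay_model(mono)
  expect_identical(sel_mono$decision, "mono")

  # rate ratio -> 1: second component unidentifiable, mono chosen
  near <- gen_biexp_trace(
    k_fast = 1.1e-4, k_slow = 1.0e-4,
    stabilized_fraction = 0.5, sigma = 0.01, seed = 13
  )
  expect_identical(select_decay_model(near)$decision, "mono")
})

test_that("kinetics_report assembles rates, SEM-based errors and the KD identity", {
  ser <- gen_kinetic_series(k_on = 2.82e6, k_off = 8.52e-5, sigma = 0.005, seed = 21)
  d <- global_fit_dissociation(dplyr::filter(ser, phase == "dissociation"))
  a <- global_fit_association(dplyr::filter(ser, phase == "association"), d$k_off)
  rep <- kinetics_report(a, d)
  expect_equal(rep$kd * rep$k_on, rep$k_off) # exact identity
  expect_equal(rep$kd, 30.2e-12, tolerance = 0.02)
  # k_off error is the SEM of the individually fitted per-trace rates
  expect_equal(
    rep$se_k_off,
    stats::sd(d$per_trace$k_off_individual) / sqrt(4)
  )
  # hand-computed SEM example
  ks <- c(4.0e-5, 5.0e-5, 4.8e-5)
  expect_equal(mean(ks), 4.6e-5)
  expect_equal(stats::sd(ks) / sqrt(3), 3.06e-6, tolerance = 1e-2)
})
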