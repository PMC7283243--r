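test_that("titration fit round-trips the generating KD without noise", {
  tab <- gen_titration(rt = 100e-12, kd = 53.6e-12, sigma = 0)
  f <- fit_titration(tab, rt = 100e-12, nboot = 100, seed = 1)
  expect_equal(f$kd, 53.6e-12, tolerance = 1e-2)
  expect_false(f$bound_only)
  expect_equal(f$A, 1, tolerance = 1e-6)
})

test_that("titration fit is order-invariant and scale is absorbed by A", {
  tab <- gen_titration(rt = 100e-12, kd = 40e-12, sigma = 0.01, seed = 5)
  f1 <- fit_titration(tab, rt = 100e-12, nboot = 20, seed = 2)
  shuffled <- tab[sample(nrow(tab)), ]
  f2 <- fit_titration(shuffled, rt = 100e-12, nboot = 20, seed = 2)
  expect_equal(f1$kd, f2$kd)
  expect_equal(f1$ci, f2$ci)

  scaled <- dplyr::mutate(tab, response = response * 7)
  f3 <- fit_titration(scaled, rt = 100e-12, nboot = 20, seed = 2)
  expect_equal(f3$kd, f1$kd, tolerance = 1e-9)
  expect_equal(f3$A, 7 * f1$A, tolerance = 1e-9)
})

test_that("depletion-limited titrations report a bound, not a point estimate", {
  # kd far below rt: the transition midpoint sits at ~rt/2, insensitive to kd
  tab <- gen_titration(rt = 500e-12, kd = 10e-12, sigma = 0.01, seed = 3)
  f <- fit_titration(tab, rt = 500e-12, nboot = 100, seed = 3)
  expect_true(f$bound_only)
  expect_true(is.finite(f$bound))

  # published-style condition rt = 500 pM with kd ~ 30 pM also yields a bound
  tab2 <- gen_titration(rt = 500e-12, kd = 30e-12, sigma = 0.01, seed = 4)
  f2 <- fit_titration(tab2, rt = 500e-12, nboot = 100, seed = 4)
  expect_true(f2$bound_only)
})

test_that("titration input contracts are enforced", {
  expect_error(fit_titration(tibble::tibble(), rt = 1e-10), "lt_M")
  small <- gen_titration(sigma = 0)[1:4, ]
  expect_error(fit_titration(small, rt = 1e-10), "at least 6")
})
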