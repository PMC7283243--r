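make_cal <- function() {
  # synthetic calibration from a known smooth decreasing map
  dr <- seq(0.2, 1.4, by = 0.1)
  calibration_curve(dr, dh_nm = 8 * exp(-0.9 * dr))
}

test_that("calibration interpolation hits knots, stays monotone, tracks the oracle", {
  cal <- make_cal()
  expect_equal(dh_from_signal(cal$dr, cal)$dh_nm, cal$dh_nm)
  probe <- seq(0.21, 1.39, length.out = 101)
  out <- dh_from_signal(probe, cal)
  expect_true(all(diff(out$dh_nm) < 0)) # monotone in, monotone out
  # oracle: the generating function; < 0.5% inside the calibrated range
  expect_lt(max(abs(out$dh_nm / (8 * exp(-0.9 * probe)) - 1)), 0.005)
  expect_error(dh_from_signal(1.6, cal), "extrapolation")
  expect_error(calibration_curve(c(1, 2, 3), c(5, 5.5, 4)), "decreasing")
})

test_that("dh -> dr -> dh inverse consistency holds to 1e-9", {
  cal <- make_cal()
  dr <- seq(0.25, 1.35, length.out = 31)
  dh <- dh_from_signal(dr, cal)$dh_nm
  dr_back <- dr_from_dh(dh, cal)
  expect_equal(dr_back, dr, tolerance = 1e-9)
})

test_that("trimer_fraction is the clipped linear interpolation between anchors", {
  refs <- size_refs(5.6, 3.9)
  expect_equal(trimer_fraction(5.6, refs), 1)
  expect_equal(trimer_fraction(3.9, refs), 0)
  expect_equal(trimer_fraction(4.75, refs), 0.5)
  expect_equal(trimer_fraction(c(3.0, 6.5), refs), c(0, 1)) # clipped
  # affine between endpoints
  d <- seq(3.9, 5.6, length.out = 9)
  expect_equal(diff(trimer_fraction(d, refs)), rep(1 / 8, 8))
  expect_error(size_refs(4, 4), "dh_trimer")
})

test_that("compare_to_reference classifies anchors and flags the midpoint", {
  res <- compare_to_reference(c(5.6, 3.9, 4.75))
  expect_equal(res$state, c("trimer", "monomer", "intermediate"))
  expect_equal(res$deviation_nm[1:2], c(0, 0))
  # deviations from the PDB-predicted ranges stay separate from measured ones
  expect_equal(res$dev_trimer_predicted_nm[1], 5.76 - 5.6, tolerance = 1e-12)
  expect_equal(res$dev_monomer_predicted_nm[2], 4.39 - 3.9, tolerance = 1e-12)
  inside <- compare_to_reference(5.9)
  expect_equal(inside$dev_trimer_predicted_nm, 0)
  # deterministic under repetition
  expect_identical(res, compare_to_reference(c(5.6, 3.9, 4.75)))
})
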