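# Instrument-readout quantification: FACS arithmetic, standard curves, ddPCR
# Poisson statistics, PMA differencing and Ct arithmetic.

test_that("gate events convert to concentrations by consumed volume", {
  expect_equal(events_to_concentration(10000, 10.1, 10.0)$cells_per_ml, 1e5)
  expect_equal(events_to_concentration(0, 10.1, 10.0)$cells_per_ml, 0)
  expect_equal(
    events_to_concentration(2e6, 10.05, 10.00, dilution_factor = 1000,
                            fluid_density = 1.0)$cells_per_ml,
    4e10)
  expect_equal(
    events_to_concentration(10000, 10.1, 10.0, feces_g_per_ml = 0.02)$cells_per_gram,
    5e6)
  expect_error(events_to_concentration(10, 10.0, 10.1), "consumed volume")
  expect_error(events_to_concentration(10, 10.1, 10.0, dilution_factor = 0.5),
               "dilution_factor")
})

test_that("standard curves recover slope, intercept and efficiency", {
  # perfect doubling: slope = -1/log10(2) = -3.3219..., efficiency 1
  lg <- 3:6
  ct <- 40 - log2(10) * lg  # one Ct per doubling
  curve <- fit_standard_curve(ct, lg)
  expect_equal(curve$slope, -log2(10), tolerance = 1e-9)
  expect_equal(curve$efficiency, 1, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1, tolerance = 1e-9)

  # two-point construction via a 3-standard collinear series:
  # (10^3 -> Ct 30, 10^6 -> Ct 20) gives slope -10/3, intercept 40
  lg2 <- c(3, 4.5, 6)
  ct2 <- 30 - 10 / 3 * (lg2 - 3)
  curve2 <- fit_standard_curve(ct2, lg2)
  expect_equal(curve2$slope, -10 / 3, tolerance = 1e-9)
  expect_equal(curve2$intercept, 40, tolerance = 1e-9)

  expect_error(fit_standard_curve(c(20, 20, 20), 3:5), "degenerate")
  expect_error(fit_standard_curve(c(20, 25), c(3, 4)), "3 distinct")
})

test_that("Ct inversion follows the curve and composes to identity", {
  curve <- fit_standard_curve(40 - log2(10) * (3:6), 3:6)
  expect_equal(ct_to_copies(curve, curve$intercept), 1, tolerance = 1e-9)
  expect_equal(ct_to_copies(curve, 30), 10^(10 / log2(10)), tolerance = 1e-6)
  # 10^(10/3.3219) = 1.024e3 to the quoted precision
  expect_equal(ct_to_copies(curve, 30) / 1.024e3, 1, tolerance = 1e-3)
  # scale factors multiply through
  expect_equal(ct_to_copies(curve, 30, template_dilution = 1000,
                            reaction_to_gram_factor = 50),
               ct_to_copies(curve, 30) * 5e4)
  # round trip
  copies <- c(12.5, 1e4, 3.3e7)
  expect_equal(ct_to_copies(curve, copies_to_ct(curve, copies)), copies,
               tolerance = 1e-9)
})

test_that("ddPCR Poisson quantification matches the closed form", {
  # p = 1 - exp(-1) at v = 1 uL gives exactly 1 copy/uL
  n <- 1e6
  pos <- round(n * (1 - exp(-1)))
  expect_equal(ddpcr_concentration(pos, n, droplet_volume = 1)$copies_per_ul,
               1, tolerance = 1e-5)
  res <- ddpcr_concentration(2000, 10000)
  expect_equal(res$copies_per_ul, -log(0.8) / 0.00085, tolerance = 1e-12)
  expect_equal(res$copies_per_ul, 262.5, tolerance = 1e-3)
  expect_false(res$below_detection)

  zero <- ddpcr_concentration(0, 10000)
  expect_equal(zero$copies_per_ul, 0)
  expect_true(zero$below_detection)
  expect_error(ddpcr_concentration(10000, 10000), "saturated")

  # monotone in the positive fraction
  conc <- vapply(c(10, 100, 1000, 5000, 9000), function(k) {
    ddpcr_concentration(k, 10000)$copies_per_ul
  }, 0)
  expect_true(all(diff(conc) > 0))
})

test_that("fixed copy-number conversion and the mock spec agree", {
  expect_equal(copies_to_cells_fixed(6.435e10, 6.435), 1e10)
  expect_equal(copies_to_cells_fixed(123, 1), 123)
  expect_equal(copies_to_cells_fixed(0, 6.435), 0)
  expect_error(copies_to_cells_fixed(10, 0), "average_copy_number")
  mc <- mock_community()
  expect_equal(nrow(mc$species), 12)
  expect_equal(mc$average_copy_number, 6.435, tolerance = 1e-9)
  expect_equal(mc$expected_cells_per_ml[1] / mc$expected_cells_per_ml[2], 2)
})

test_that("PMA differencing recovers fractions and cancels shared yield", {
  est <- estimate_extracellular_fraction(c(1e10, 2e10), c(6e9, 1.2e10))
  expect_equal(unname(est$fractions), c(0.4, 0.4))
  expect_equal(est$mean_fraction, 0.4)
  expect_equal(est$mean_decrease, (4e9 + 8e9) / 2)

  same <- estimate_extracellular_fraction(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$mean_fraction, 0)

  # a shared multiplicative factor on a pair leaves fractions unchanged
  u <- c(a = 1e10, b = 3e10, c = 2e10)
  tr <- u * c(0.6, 0.7, 0.5)
  scaled <- estimate_extracellular_fraction(u * 17.3, tr * 17.3)
  expect_equal(scaled$fractions, estimate_extracellular_fraction(u, tr)$fractions)

  expect_error(estimate_extracellular_fraction(c(x = 1), c(y = 1)), "pairing")
  expect_error(estimate_extracellular_fraction(c(1, 2), c(0, 1)), "> 0")
})

test_that("Ct-difference arithmetic matches doubling algebra", {
  expect_equal(delta_ct_signal_reduction(1, efficiency = 1), 50)
  expect_equal(delta_ct_signal_reduction(0), 0)
  expect_equal(delta_ct_signal_reduction(11.6), (1 - 2^-11.6) * 100,
               tolerance = 1e-12)
  expect_equal(delta_ct_signal_reduction(11.6), 99.9677, tolerance = 1e-4)
  # monotone, saturating at 100
  red <- vapply(c(0.5, 1, 2, 5, 10, 20), delta_ct_signal_reduction, 0)
  expect_true(all(diff(red) > 0))
  expect_lt(max(red), 100)
  # per-sample averaging mode differs from mean-Ct mode (Jensen)
  dct <- c(10.2, 11.9, 12.7)
  expect_lt(delta_ct_signal_reduction(dct, mode = "per_sample"),
            delta_ct_signal_reduction(dct, mode = "mean_ct"))
  expect_warning(delta_ct_signal_reduction(-1), "negative")
  expect_error(delta_ct_signal_reduction(1, efficiency = 1.5), "efficiency")
})

test_that("mock-series evaluation preserves scale and sign structure", {
  expected <- 3.3e6 / 2^(0:5)
  exact <- evaluate_mock_series(expected, expected, expected)
  expect_equal(exact$ratios_a, rep(1, 6))
  expect_equal(exact$pearson_r, 1)

  # constant 30x overestimation: ratios 30, correlation still 1
  over <- evaluate_mock_series(expected * 30, expected, expected)
  expect_equal(over$ratios_a, rep(30, 6))
  expect_equal(over$pearson_r, 1)

  # one channel reported as Ct (linear in -log2 concentration): against a
  # log-scale channel r = -1 exactly; against the raw concentrations it stays
  # strongly negative but not -1
  ct_channel <- 40 - log2(expected / expected[6])
  mixed <- evaluate_mock_series(log2(expected), ct_channel, expected,
                                ratio_scale = c(FALSE, FALSE))
  expect_equal(mixed$pearson_r, -1, tolerance = 1e-12)
  expect_null(mixed$ratios_b)
  raw <- evaluate_mock_series(expected, ct_channel, expected,
                              ratio_scale = c(TRUE, FALSE))
  expect_lt(raw$pearson_r, -0.9)
  expect_gt(raw$pearson_r, -1)

  expect_error(evaluate_mock_series(1:3, 1:4, 1:4), "length")
  expect_error(evaluate_mock_series(1:2, 1:2, 1:2), "3 dilutions")
})
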