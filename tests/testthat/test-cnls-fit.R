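# Multistart complex non-linear least-squares fitting and R_b extraction.

test_that("series-resistance fixing rule reads Re(Z) at the highest frequency", {
  flat <- impedance_spectrum(10^seq(5, -1, length.out = 13),
                             rep(1000 + 0i, 13))
  expect_identical(fix_series_resistance(flat), 1000)
  sp <- circuit_impedance(default_truth(), make_sweep())
  expect_lt(abs(fix_series_resistance(sp) - 120), 0.5)
})

test_that("residual vector is the stacked weighted Re/Im mismatch", {
  truth <- default_truth()
  sp <- circuit_impedance(truth, make_sweep())
  r <- cnls_residuals(truth, sp, "modulus")
  expect_length(r, 2 * 61)
  expect_true(all(r == 0))
  off <- circuit_params(1800, 1e-4, 0.9, 120, 800, 2e-6)
  r_off <- cnls_residuals(off, sp, "modulus")
  expect_gt(sum(r_off^2), 0)
  # modulus weighting is scale invariant: doubling the circuit impedance
  # (2x resistances, Q and C halved) and the observations leaves it unchanged
  sp2 <- impedance_spectrum(sp$frequencies, 2 * sp$z)
  off2 <- circuit_params(3600, 5e-5, 0.9, 240, 1600, 1e-6)
  expect_equal(cnls_residuals(off2, sp2, "modulus"), r_off,
               tolerance = 1e-12)
  # unit weighting is not
  expect_false(isTRUE(all.equal(cnls_residuals(off2, sp2, "unit"),
                                cnls_residuals(off, sp, "unit"))))
})

test_that("noiseless spectra are recovered to well under 0.1% with fixed series resistance", {
  truth <- default_truth()
  sp <- circuit_impedance(truth, make_sweep())
  fit <- fit_spectrum(sp, fit_config(seed = 21))
  expect_identical(fit$params$r_electrolyte, fix_series_resistance(sp))
  expect_identical(fit$r_electrolyte_fixed, fix_series_resistance(sp))
  for (nm in c("r_ce", "q_ce", "alpha_ce", "r_barrier", "c_barrier")) {
    expect_lt(abs(fit$params[[nm]] - truth[[nm]]) / truth[[nm]], 1e-3)
  }
  expect_equal(extract_rb(fit), 900, tolerance = 1e-3)
})

test_that("co-fitting the series resistance reaches the exact zero-cost minimum", {
  truth <- default_truth()
  sp <- circuit_impedance(truth, make_sweep())
  fit <- fit_spectrum(sp, fit_config(seed = 21, fix_r_electrolyte = FALSE))
  expect_lt(fit$cost, 1e-18)
  for (nm in names(unclass(truth))) {
    expect_lt(abs(fit$params[[nm]] - truth[[nm]]) / truth[[nm]], 1e-6)
  }
})

test_that("barrier-free model recovers blank devices; full model flags them", {
  blank <- baseline_parameters("blank", seed = 31, jitter_cv = 0)
  sp <- circuit_impedance(blank, make_sweep())
  fit <- fit_spectrum(sp, fit_config(seed = 5, model = "barrier_free"))
  expect_lt(abs(fit$params$r_ce - blank$r_ce) / blank$r_ce, 1e-3)
  expect_lt(abs(fit$params$q_ce - blank$q_ce) / blank$q_ce, 1e-3)
  expect_lt(abs(fit$params$alpha_ce - blank$alpha_ce) / blank$alpha_ce, 1e-3)
  expect_identical(fit$params$r_barrier, 0)
  full <- fit_spectrum(sp, fit_config(seed = 5))
  expect_true("no_barrier" %in% full$flags)
  expect_true("no_barrier" %in% attr(extract_rb(full), "flags"))
  # whatever pseudo-barrier the full model places on a blank device is a
  # negligible sliver of the DC resistance
  expect_lt(as.numeric(extract_rb(full)),
            0.02 * (full$params$r_ce + full$params$r_electrolyte))
})

test_that("fits are deterministic given (spectrum, config) and seed-stable in R_b", {
  sp <- simulate_spectrum(default_truth(), noise = noise_model(0.01),
                          seed = 99)
  cfg <- fit_config(seed = 13)
  expect_identical(fit_spectrum(sp, cfg), fit_spectrum(sp, cfg))
  # on noiseless data any seed reaching the global basin gives the same R_b
  clean <- circuit_impedance(default_truth(), make_sweep())
  rb1 <- extract_rb(fit_spectrum(clean, fit_config(seed = 1)))
  rb2 <- extract_rb(fit_spectrum(clean, fit_config(seed = 2)))
  expect_lt(abs(rb1 - rb2) / rb1, 1e-4)
})

test_that("best cost is non-increasing in n_starts (nested start sets)", {
  sp <- simulate_spectrum(default_truth(), noise = noise_model(0.01),
                          seed = 3)
  costs <- vapply(c(1, 4, 16, 32), function(ns) {
    fit_spectrum(sp, fit_config(n_starts = ns, seed = 7))$cost
  }, numeric(1))
  expect_true(all(diff(costs) <= 1e-12))
})

test_that("fitted R_b scatter grows with the noise level", {
  sigmas <- c(0, 0.005, 0.01, 0.02)
  cfg <- fit_config(n_starts = 8, seed = 17)
  spread <- vapply(sigmas, function(s) {
    rb <- vapply(1:8, function(i) {
      sp <- simulate_spectrum(default_truth(), noise = noise_model(s),
                              seed = 5000 + i)
      extract_rb(fit_spectrum(sp, cfg))
    }, numeric(1))
    sd(rb)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("fit preconditions are enforced", {
  small <- impedance_spectrum(c(100, 10, 1), rep(50 - 5i, 3))
  expect_error(fit_spectrum(small), "fewer than 12")
  zero <- impedance_spectrum(10^seq(4, -1, length.out = 13),
                             c(0 + 0i, rep(100 - 1i, 12)))
  expect_error(cnls_residuals(default_truth(), zero, "modulus"),
               "zero \\|Z_obs\\|")
})
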