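# Forward equivalent-circuit model: element impedances, parallel/series
# composition, Bode quantities and the 500 Hz cross-section.

test_that("capacitor impedance follows 1/(j omega C)", {
  z <- capacitor_impedance(1e-6, 500)
  expect_equal(Mod(z), 1 / (2 * pi * 500 * 1e-6), tolerance = 1e-12)
  expect_equal(Mod(z), 318.3099, tolerance = 1e-6)
  expect_equal(Arg(z) * 180 / pi, -90)
  expect_equal(Re(z), 0)
  # 1/omega scaling: one decade up in frequency is one decade down in |Z|
  expect_equal(Mod(capacitor_impedance(1e-6, 5000)), Mod(z) / 10,
               tolerance = 1e-12)
  expect_error(capacitor_impedance(0, 500), "capacitance")
  expect_error(capacitor_impedance(1e-6, -1), "frequency")
})

test_that("CPE impedance has constant phase -alpha*90 and reduces to a capacitor at alpha = 1", {
  f <- sweep_frequencies(make_sweep())
  expect_identical(cpe_impedance(1e-6, 1, f), capacitor_impedance(1e-6, f))
  withr::with_seed(11, {
    for (i in 1:10) {
      q <- 10^runif(1, -8, -2)
      alpha <- runif(1, 0.05, 1)
      fi <- 10^runif(1, -1, 5)
      z <- cpe_impedance(q, alpha, fi)
      expect_equal(Arg(z) * 180 / pi, -alpha * 90, tolerance = 1e-10)
      expect_lte(Im(z), 0)
    }
  })
  # modulus formula |Z| = 1/(q omega^alpha)
  z <- cpe_impedance(1e-4, 0.8, 0.1)
  expect_equal(Mod(z), 1 / (1e-4 * (2 * pi * 0.1)^0.8), tolerance = 1e-12)
  expect_error(cpe_impedance(1e-4, 1.2, 1), "alpha")
  expect_error(cpe_impedance(1e-4, 0, 1), "alpha")
})

test_that("parallel combination works in admittance space with open/short handling", {
  expect_equal(parallel_impedance(100 + 0i, open_impedance()), 100 + 0i)
  expect_equal(parallel_impedance(100, 100), 50 + 0i)
  expect_true(barrierEIS:::is_open_impedance(
    parallel_impedance(open_impedance(), open_impedance())))
  expect_equal(parallel_impedance(0, open_impedance()), 0 + 0i)
  # R // C against the closed form R/(1 + j omega R C)
  zc <- capacitor_impedance(1e-6, 500)
  z <- parallel_impedance(1000, zc)
  z_expected <- 1000 / (1 + 2i * pi * 500 * 1000 * 1e-6)
  expect_equal(z, z_expected, tolerance = 1e-12)
  expect_equal(Mod(z), 303.31, tolerance = 1e-4)
  expect_equal(Arg(z) * 180 / pi, -72.34, tolerance = 1e-4)
})

test_that("circuit impedance composes the two-branch series model", {
  # pure resistor chain: open CPE and open barrier capacitor
  chain <- circuit_params(50, 0, 1, 100, 850, 0)
  sp <- circuit_impedance(chain, make_sweep())
  expect_true(all(sp$z == 1000 + 0i))
  # high frequency: both parallel branches contribute < 0.5 Ohm real part
  sp <- circuit_impedance(default_truth(), make_sweep())
  expect_lt(abs(Re(sp$z[1]) - 120), 0.5)
  # DC limit: CPE and capacitor are open
  lowf <- circuit_impedance(default_truth(),
                            frequency_sweep(1e-6, 1e-5, 1))
  expect_equal(Re(lowf$z[length(lowf$z)]), 2000 + 120 + 900,
               tolerance = 1e-3)
  # blank encoding (r_barrier = c_barrier = 0): barrier term is exactly zero,
  # leaving the CE branch in series with the electrolyte resistance
  blank <- circuit_params(2000, 1e-4, 0.9, 120, 0, 0)
  sp_blank <- circuit_impedance(blank, make_sweep())
  f <- sp_blank$frequencies
  ce_only <- parallel_impedance(2000, cpe_impedance(1e-4, 0.9, f)) + 120
  expect_equal(sp_blank$z, ce_only, tolerance = 1e-14)
})

test_that("model is passive with Re(Z) monotone non-increasing in frequency", {
  withr::with_seed(23, {
    for (i in 1:10) {
      sp <- circuit_impedance(random_truth(), make_sweep())
      expect_true(all(Im(sp$z) <= 0))
      expect_true(all(Re(sp$z) > 0))
      # frequencies stored descending, so Re(Z) must be non-decreasing
      # along the stored order
      expect_true(all(diff(Re(sp$z)) >= -1e-9 * Re(sp$z[-1])))
    }
  })
})

test_that("forward model matches the independent complex-arithmetic oracle", {
  f <- sweep_frequencies(make_sweep())
  withr::with_seed(31, {
    for (i in 1:3) {
      p <- random_truth()
      z_pkg <- circuit_impedance(p, make_sweep())$z
      z_ora <- oracle_circuit_z(p, f)
      expect_lt(max(Mod(z_pkg - z_ora) / Mod(z_ora)), 1e-12)
    }
  })
})

test_that("bode returns magnitude and signed phase in degrees", {
  sp <- impedance_spectrum(c(100, 10), c(100 + 0i, 0 - 100i))
  b <- bode(sp)
  expect_equal(b$magnitude_ohm, c(100, 100))
  expect_equal(b$phase_deg, c(0, -90))
  full <- bode(circuit_impedance(default_truth(), make_sweep()))
  expect_lt(abs(full$phase_deg[1]), 5)  # near-resistive at 100 kHz
})

test_that("cross-section interpolates log|Z| vs log f and honours exact hits", {
  flat <- impedance_spectrum(10^seq(5, -1, length.out = 61),
                             rep(1000 + 0i, 61))
  expect_equal(crosssection(flat, 500), 1000)
  expect_equal(crosssection(flat, 0.37), 1000)
  hit <- impedance_spectrum(c(1000, 500, 100), c(10 + 0i, 42 + 0i, 7 + 0i))
  expect_identical(crosssection(hit, 500), 42)
  # R//C on the default grid (500 Hz falls between 398.1 and 501.2 Hz)
  rc <- circuit_params(1e-3, 0, 1, 0, 1000, 1e-6)
  sp <- circuit_impedance(rc, make_sweep())
  closed_form <- Mod(1000 / (1 + 2i * pi * 500 * 1000 * 1e-6))
  expect_equal(crosssection(sp, 500), closed_form, tolerance = 5e-3)
  expect_error(crosssection(sp, 1e7), "outside")
})

test_that("sweep grid is inclusive log-spaced in sweep direction", {
  f <- sweep_frequencies(make_sweep())
  expect_length(f, 61)
  expect_equal(f[1], 1e5)
  expect_equal(f[61], 0.1, tolerance = 1e-12)
  expect_true(all(diff(f) < 0))
  expect_equal(sweep_frequencies(frequency_sweep(1, 1000, 1)),
               c(1000, 100, 10, 1), tolerance = 1e-12)
  expect_error(frequency_sweep(-1, 10), "f_min")
  expect_error(frequency_sweep(10, 5), "f_max")
})

test_that("constructors enforce domain invariants", {
  expect_error(circuit_params(-1, 1e-4, 0.9, 120, 900, 2e-6), ">= 0")
  expect_error(circuit_params(2000, 1e-4, 1.5, 120, 900, 2e-6), "alpha")
  expect_error(impedance_spectrum(c(1, 2), c(1 + 0i)), "equal length")
  expect_error(impedance_spectrum(c(1, 1), c(1 + 0i, 2 + 0i)), "duplicate")
  expect_error(impedance_spectrum(c(-1, 2), c(1 + 0i, 2 + 0i)), "> 0")
  # spectra are stored in descending-frequency sweep order
  sp <- impedance_spectrum(c(1, 100, 10), c(1 + 0i, 2 + 0i, 3 + 0i))
  expect_equal(sp$frequencies, c(100, 10, 1))
  expect_equal(sp$z, c(2 + 0i, 3 + 0i, 1 + 0i))
})
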