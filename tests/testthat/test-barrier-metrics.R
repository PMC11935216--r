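# Time-course analytics: normalised cross-sections, R_b trajectories,
# fold-changes versus baseline and versus the control arm.

test_that("normalised 500 Hz cross-section is 1 at baseline and tracks the programmed drop", {
  ps <- intervention_presets()
  tc <- simulate_timecourse(ps$control, noise = noise_model(0), seed = 3)
  v <- normalized_crosssection_series(tc)
  expect_identical(v$value[v$timepoint_h == 0], 1)
  expect_equal(v$value, rep(1, 7))
  tc_pro <- simulate_timecourse(ps$pro_inflammatory, noise = noise_model(0),
                                seed = 3)
  v_pro <- normalized_crosssection_series(tc_pro)
  expect_identical(v_pro$value[v_pro$timepoint_h == 0], 1)
  # oracle: closed-form |Z| at 500 Hz with the programmed R_b scaling,
  # interpolated on the same log-log rule from the analytic grid values
  base <- tc_pro$truth$baseline
  z500 <- function(rb_frac) {
    p <- base
    p$r_barrier <- base$r_barrier * rb_frac
    crosssection(circuit_impedance(p, make_sweep()), 500)
  }
  expect_equal(v_pro$value[v_pro$timepoint_h == 24], z500(0.40) / z500(1),
               tolerance = 1e-10)
  # lower programmed R_b fraction => lower normalised cross-section
  grid <- seq(0.2, 1, by = 0.1)
  vals <- vapply(grid, z500, numeric(1))
  expect_true(all(diff(vals) > 0))
  no_base <- tc
  no_base$timepoints <- no_base$timepoints[-1]
  no_base$spectra <- no_base$spectra[-1]
  expect_error(normalized_crosssection_series(no_base), "baseline")
})

test_that("R_b series recovers programmed trajectories on noiseless data", {
  ps <- intervention_presets()
  cfg <- fit_config(n_starts = 8, seed = 2)
  tc <- simulate_timecourse(ps$control, noise = noise_model(0), seed = 6)
  rb <- rb_series(tc, cfg)
  truth_rb <- tc$truth$baseline$r_barrier
  expect_true(all(abs(rb$value - truth_rb) / truth_rb < 1e-3))
  tc_pro <- simulate_timecourse(ps$pro_inflammatory, noise = noise_model(0),
                                seed = 6)
  rb_pro <- rb_series(tc_pro, cfg)
  fracs <- rb_pro$value / rb_pro$value[rb_pro$timepoint_h == 0]
  expect_equal(fracs, tc_pro$truth$rb_fractions, tolerance = 1e-3)
})

test_that("blank devices are flagged at every timepoint", {
  tc <- simulate_timecourse(intervention_presets("blank")[[1]],
                            noise = noise_model(0), seed = 4,
                            timepoints = c(0, 24))
  rb <- rb_series(tc, fit_config(n_starts = 8, seed = 2))
  expect_true(all(grepl("no_barrier", rb$flag)))
})

test_that("fold-change is R_b(t)/R_b(0) per device", {
  series <- data.frame(device_id = "d1", intervention = "x",
                       timepoint_h = c(0, 24), metric = "rb",
                       value = c(900, 450), flag = "",
                       stringsAsFactors = FALSE)
  fc <- rb_foldchange(series)
  expect_identical(fc$value, c(1, 0.5))
  const <- series
  const$value <- c(700, 700)
  expect_identical(rb_foldchange(const)$value, c(1, 1))
  missing_base <- series[series$timepoint_h != 0, ]
  expect_error(rb_foldchange(missing_base), "t = 0")
  flagged <- series
  flagged$flag <- c("fit_failed", "")
  expect_error(rb_foldchange(flagged), "flagged")
})

test_that("the programmed commensal recovery shape survives the fit pipeline", {
  tc <- simulate_timecourse(intervention_presets()$ecoli_top10,
                            noise = noise_model(0), seed = 9,
                            timepoints = c(0, 8, 24))
  fc <- rb_foldchange(rb_series(tc, fit_config(n_starts = 8, seed = 2)))
  expect_gt(fc$value[fc$timepoint_h == 24], fc$value[fc$timepoint_h == 8])
})

test_that("control-normalised endpoint ratios match the programmed plateaus", {
  ps <- intervention_presets(c("control", "pro_inflammatory"))
  cfg <- fit_config(n_starts = 8, seed = 2)
  tcs <- simulate_cohort(ps, n_biological = 1, n_technical = 2,
                         noise = noise_model(0), seed = 15)$timecourses
  tcs <- lapply(tcs, function(tc) {
    tc$timepoints <- c(0, 24)
    tc$spectra <- tc$spectra[c("0", "24")]
    tc
  })
  fc <- do.call(rbind, lapply(tcs, function(tc) {
    rb_foldchange(rb_series(tc, cfg))
  }))
  out <- foldchange_vs_control(fc, t = 24)
  ctrl <- out$per_device$value[out$per_device$intervention == "control"]
  expect_equal(mean(ctrl), 1, tolerance = 1e-6)
  pro <- out$summary[out$summary$intervention == "pro_inflammatory", ]
  expect_equal(pro$mean, 0.40, tolerance = 1e-3)
  expect_equal(pro$n, 2L)
  expect_error(foldchange_vs_control(fc, t = 13), "t = 13")
})

test_that("metrics computed from disk equal in-memory metrics", {
  ds <- simulate_cohort(intervention_presets("control"), 1, 1,
                        noise = noise_model(0.01), seed = 33)
  dir <- withr::local_tempdir()
  man <- read_manifest(write_dataset(ds, dir))
  tc_disk <- load_timecourses(man)[[1]]
  tc_mem <- ds$timecourses[[1]]
  expect_equal(normalized_crosssection_series(tc_disk)$value,
               normalized_crosssection_series(tc_mem)$value,
               tolerance = 1e-12)
})
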