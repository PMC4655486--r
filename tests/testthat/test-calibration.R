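test_that("the pre-era equation identifies the natural rate in closed form", {
  p <- calibrate_mortality(ev_params(), seed = 1, n_reps = 6, max_iter = 1)
  # with no pre-era poisoning the natural rate equals the pre-era target
  expect_equal(p$m_natural_annual, 0.02)
  expect_false(is.na(p$p_poison_per_exit))
})

test_that("forcing the poisoning hazard to zero exposes the era inconsistency", {
  expect_error(
    calibrate_mortality(ev_params(), seed = 1, n_reps = 4,
                        p_poison_fixed = 0),
    class = "neophron_calibration_error"
  )
})

test_that("an unreachable post-era target is a calibration failure", {
  # natural mortality alone (2%) already exceeds a 1% post-era target
  expect_error(
    calibrate_mortality(ev_params(m_breeder_post_target = 0.01),
                        seed = 1, n_reps = 4),
    class = "neophron_calibration_error"
  )
})

test_that("reproduction line: two-point algebra, degeneracy, ordering error", {
  p <- calibrate_reproduction(ev_params(), post_exit_fraction = 0.6)
  expect_equal(p$repro_slope, 0.5)
  expect_equal(p$repro_intercept, 0.5)
  # the line passes through the pre-era point exactly
  expect_equal(p$repro_intercept - p$repro_slope * 0.2, 0.4)

  # post-era exit fraction at or below the pre-era one cannot give a
  # declining line
  expect_error(calibrate_reproduction(ev_params(), post_exit_fraction = 0.2),
               class = "neophron_calibration_error")
  expect_error(calibrate_reproduction(ev_params(), post_exit_fraction = 0.1),
               class = "neophron_calibration_error")
  expect_error(calibrate_reproduction(ev_params()),
               class = "neophron_calibration_error")
})

test_that("kappa = 0 silences the competitor entirely", {
  p <- test_params()
  p$kappa_interception <- 0
  drv <- driver_series(p, 2010:2013)
  ens <- run_ensemble(p, drv, n_reps = 3, seed = 2)
  expect_equal(sum(ens$records$rabbit_kg_gv, na.rm = TRUE), 0)
})

test_that("full calibration hits its targets and is idempotent", {
  cal <- cached_cal()
  rep <- calibration_report(cal)
  expect_equal(nrow(rep), 6)
  expect_true(all(abs(rep$residual[rep$quantity ==
                                     "pre-era breeder mortality"]) <= 0.005))
  expect_true(all(abs(rep$residual[rep$quantity ==
                                     "post-era breeder mortality"]) <= 0.01))

  # idempotence: recalibrating an already calibrated set moves nothing
  # beyond the pilot Monte-Carlo tolerance
  cal2 <- calibrate_params(cal, seed = 42, n_reps = 40)
  expect_equal(cal2$m_natural_annual, cal$m_natural_annual)
  expect_equal(cal2$p_poison_per_exit, cal$p_poison_per_exit,
               tolerance = 0.15)
  expect_equal(cal2$kappa_interception, cal$kappa_interception,
               tolerance = 0.15)
  expect_equal(cal2$repro_intercept, cal$repro_intercept, tolerance = 0.05)
})
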