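test_that("find_peaks locates and refines sinusoid maxima", {
  traj <- synth_trajectory(period = 24, phase = 0, t_end = 120)
  pk <- find_peaks(traj, "M", window = c(80, 120))
  expect_equal(pk$time, 96, tolerance = 1e-4)
  pk_all <- find_peaks(traj, "M")
  expect_equal(pk_all$time, c(24, 48, 72, 96), tolerance = 1e-4)
  expect_equal(pk_all$height, rep(3, 4), tolerance = 1e-6)
  flat <- synth_trajectory(amplitude = 0, t_end = 100)
  expect_equal(nrow(find_peaks(flat, "M")), 0)
})

test_that("estimate_period recovers analytic periods to < 0.01 h", {
  for (per in c(20, 22.5, 24, 25.4, 27.5, 30)) {
    traj <- synth_trajectory(period = per, phase = 0.7, t_end = 150)
    expect_lt(abs(estimate_period(traj, "M")$period - per), 0.01)
  }
  # damped sinusoids keep their peak spacing close to the period
  damped <- synth_trajectory(period = 24, damping = 0.01, t_end = 150)
  expect_lt(abs(estimate_period(damped, "M")$period - 24), 0.2)
})

test_that("estimate_period extends past the window when peaks are sparse", {
  # a 30 h rhythm places one peak inside [80, 120]
  traj <- synth_trajectory(period = 30, phase = pi, t_end = 160)
  pe <- estimate_period(traj, "M", window = c(80, 120))
  expect_lt(abs(pe$period - 30), 0.01)
  expect_error(estimate_period(synth_trajectory(amplitude = 0), "M"),
               class = "clockstim_arrhythmic_error")
})

test_that("phase shifts are measured circularly with sign conventions", {
  a <- synth_trajectory(period = 24, phase = 0, t_end = 200)
  expect_equal(estimate_phase_shift(a, a)$shift, 0, tolerance = 1e-6)
  b <- synth_trajectory(period = 24, phase = -2 * pi * 3 / 24, t_end = 200)
  sab <- estimate_phase_shift(a, b)
  expect_equal(sab$shift, 3, tolerance = 1e-3)
  expect_equal(estimate_phase_shift(b, a)$shift, -sab$shift,
               tolerance = 1e-3)
  expect_equal(estimate_phase_shift(a, b, wrap = "lag")$shift, 3,
               tolerance = 1e-3)
  c14 <- synth_trajectory(period = 24, phase = -2 * pi * 14 / 24, t_end = 200)
  expect_equal(estimate_phase_shift(a, c14)$shift, -10, tolerance = 1e-3)
  expect_equal(estimate_phase_shift(a, c14, wrap = "lag")$shift, 14,
               tolerance = 1e-3)
  drifting <- synth_trajectory(period = 25, t_end = 200)
  expect_error(estimate_phase_shift(a, drifting),
               class = "clockstim_not_entrained_error")
  expect_silent(estimate_phase_shift(a, drifting, period_tol = 1.5))
})

test_that("arrhythmia detection compares amplitude to the free-running one", {
  flat <- synth_trajectory(amplitude = 0, t_end = 120)
  res <- detect_arrhythmia(flat, "M", reference_amplitude = 2.4)
  expect_true(res$arrhythmic)
  expect_equal(res$amplitude, 0)
  live <- synth_trajectory(amplitude = 1.2, t_end = 120)
  expect_false(detect_arrhythmia(live, "M",
                                 reference_amplitude = 2.4)$arrhythmic)
  free <- acceptance_traj("freerun",
    function() simulate_oscillator(settings = solver_settings(t_end = 160)))
  expect_false(detect_arrhythmia(free, "M")$arrhythmic)
})

test_that("a degenerate constant-light scan returns the free-running period", {
  scan <- scan_constant_light("fly", c_grid = 0)
  expect_equal(round(scan$period, 1), 23.7)
  expect_equal(scan$status, "rhythmic")
  expect_equal(attr(scan, "turning_point"), 0)
  expect_error(scan_constant_light("fly", c_grid = c(0.2, 0.1)),
               class = "clockstim_config_error")
})

test_that("a zero-magnitude pulse produces an identically zero PRC", {
  prc <- phase_response_curve(pulse_magnitude = 0, ct_grid = c(0, 12),
                              settings = solver_settings(t_end = 240))
  expect_equal(prc$shift, c(0, 0), tolerance = 1e-6)
  expect_equal(prc$status, c("rhythmic", "rhythmic"))
})

test_that("the PRC is periodic in the pulse's circadian time", {
  prc <- phase_response_curve(ct_grid = c(3, 27),
                              settings = solver_settings(t_end = 288))
  expect_equal(prc$shift[1], prc$shift[2], tolerance = 0.05)
  expect_false(isTRUE(all.equal(prc$shift[1], 0, tolerance = 0.01)))
})

test_that("entrainment range locks at resonance and not without a stimulus", {
  res <- entrainment_range(variant_spec("fly", alpha = 1),
                           T_grid = c(23.7, 24))
  expect_equal(res$status, c("locked", "locked"))
  expect_equal(attr(res, "locked_interval"), c(23.7, 24))
  # amplitude zero: the free-running clock only "locks" at its own period
  res0 <- entrainment_range(variant_spec("fly", alpha = 1), amplitude = 0,
                            T_grid = c(23.7, 24))
  expect_equal(res0$status, c("locked", "unlocked"))
})

test_that("resynchronization time finds the first sub-threshold offset", {
  t <- seq(0, 240, by = 0.05)
  ref <- synth_trajectory(period = 24, phase = 0, t_end = 240)
  # offset rhythm: 6 h shift before t = 120, in phase afterwards
  v <- 2 + cos(2 * pi * (t - ifelse(t < 120, 6, 0)) / 24)
  traj <- ref; traj$M <- v
  rs <- resynchronization_time(ref, traj, variable = "M", t_switch = 120)
  expect_false(is.na(rs$time))
  expect_lt(rs$time, 30)
  expect_gt(rs$time, 0)
})
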