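test_that("a zero right-hand side yields a constant trajectory", {
  traj <- integrate_clock(function(t, y) c(0, 0), c(a = 1, b = 2),
                          solver_settings(t_end = 10))
  expect_equal(range(traj$a), c(1, 1))
  expect_equal(range(traj$b), c(2, 2))
  expect_true(all(diff(traj$t) > 0))
})

test_that("integration errors carry a classed condition", {
  expect_error(
    integrate_clock(function(t, y) y^2, c(x = 1),
                    solver_settings(t_end = 5)),
    class = "clockstim_integration_error")
  expect_error(integrate_clock(function(t, y) 0, c(x = NaN),
                               solver_settings(t_end = 1)),
               class = "clockstim_config_error")
})

test_that("the default model free-runs at about 23.7 h with state >= 0", {
  traj <- acceptance_traj("freerun",
    function() simulate_oscillator(settings = solver_settings(t_end = 160)))
  pe <- estimate_period(traj, "M", window = c(80, 120))
  expect_equal(round(pe$period, 1), 23.7)
  expect_gte(min(as.matrix(traj[-1])), -1e-9)
})

test_that("trajectories self-converge under tolerance refinement", {
  coarse <- simulate_oscillator(settings = solver_settings(
    rel_tol = 1e-8, abs_tol = 1e-10, t_end = 100))
  fine <- simulate_oscillator(settings = solver_settings(
    rel_tol = 1e-9, abs_tol = 1e-11, t_end = 100))
  expect_lt(abs(coarse$M[nrow(coarse)] - fine$M[nrow(fine)]), 1e-5)
  expect_lt(max(abs(coarse$M - fine$M)), 1e-4)
})

test_that("declared breakpoints are an accuracy aid, not a semantic change", {
  v <- variant_spec("mrna_decay", alpha = 0.5)
  fs <- stim_food_switch(phi_tilde = pi, phi = 0, t_switch = 30)
  p <- core_parameters()
  rhs <- function(t, y) {
    names(y) <- c("M", "P0", "P1", "P2", "PN")
    variant_rhs(y, p, v, stim_eval(fs, t))
  }
  st <- solver_settings(t_end = 60)
  with_bp <- integrate_clock(rhs, unclass(oscillator_state()), st,
                             breakpoints = 30)
  without_bp <- integrate_clock(rhs, unclass(oscillator_state()), st)
  shared <- intersect(with_bp$t, without_bp$t)
  expect_gt(length(shared), 1000)
  expect_lt(max(abs(with_bp$M[match(shared, with_bp$t)] -
                    without_bp$M[match(shared, without_bp$t)])), 1e-6)
  expect_true(30 %in% with_bp$t)
})

test_that("an entrained trajectory maps onto itself after one Zeitgeber period", {
  traj <- acceptance_traj("entrained_phi0", function()
    simulate_oscillator(variant = variant_spec("mrna_decay", alpha = 0.05),
                        stimulus = stim_periodic(phi = 0),
                        settings = solver_settings(t_end = 240)))
  t1 <- traj$t >= 168 & traj$t < 192
  t2 <- traj$t >= 192 & traj$t < 216
  expect_lt(max(abs(traj$M[t1] - traj$M[t2])), 0.05)
})

test_that("trajectories round-trip through TSV", {
  traj <- simulate_oscillator(settings = solver_settings(t_end = 5,
                                                         sample_dt = 0.5))
  path <- tempfile(fileext = ".tsv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(names(back), names(traj))
  expect_equal(back$M, traj$M, tolerance = 1e-8)
  first <- readLines(path, n = 1)
  expect_equal(first, paste(c("t", "M", "P0", "P1", "P2", "PN"),
                            collapse = "\t"))
})
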