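test_that("coupling terms compute their rate contributions", {
  expect_equal(antiphase_coupling_term(1, 2, 0.5), -1)
  expect_equal(antiphase_coupling_term(1, 0, 0.5), 0)
  expect_equal(p2_coupling_term(2, 1, 0.5), -1)
  expect_equal(p2_coupling_term(2, 0, 0.5), 0)
  # gating: a large source silences the decay, beta = 0 removes the gate
  expect_equal(inphase_coupling_term(1, 1e6, 0.5, beta = 2), 0,
               tolerance = 1e-12)
  expect_equal(inphase_coupling_term(1.3, 5, 0.5, beta = 0), -0.5 * 1.3)
  # monotone decreasing in the source amount
  src <- seq(0, 4, by = 0.25)
  v <- inphase_coupling_term(1, src, 0.5, beta = 2)
  expect_true(all(diff(v) > 0))   # less negative as source grows
  # dual input degenerates to the gated term without food
  expect_equal(dual_input_term(1, 0.7, 0.3, 2, u_food = 0, delta = 0.4),
               inphase_coupling_term(1, 0.7, 0.3, 2))
  expect_equal(dual_input_term(1, 0.7, 0.3, 2, u_food = 0.5, delta = 0.4) -
                 inphase_coupling_term(1, 0.7, 0.3, 2),
               -0.2, tolerance = 1e-12)
  # linearity of the product couplings in the source
  expect_equal(antiphase_coupling_term(1.5, 2 * 1.7, 0.5),
               2 * antiphase_coupling_term(1.5, 1.7, 0.5))
})

test_that("network validation catches dangling references", {
  a <- oscillator_unit("a")
  expect_error(network_spec(list(a, oscillator_unit("a"))),
               class = "clockstim_config_error")
  expect_error(
    network_spec(list(a),
                 list(coupling_term("b", "product_decay", c("a", "P0"), 0.5))),
    class = "clockstim_config_error")
  expect_error(
    network_spec(list(a),
                 list(coupling_term("a", "product_decay", c("ghost", "P0"), 0.5))),
    class = "clockstim_config_error")
  expect_error(
    network_spec(list(a, oscillator_unit("b", stimulus = stim_tap("ghost")))),
    class = "clockstim_config_error")
  expect_error(coupling_term("a", "gated_decay", c("b", "P0"), 0.5),
               class = "clockstim_config_error")  # missing beta
  expect_error(coupling_term("a", "dual_input", c("b", "P0"), 0.5, beta = 2,
                             delta = 0.4),
               class = "clockstim_config_error")  # missing food stimulus
})

test_that("uncoupled oscillators in a network match standalone runs", {
  st <- solver_settings(t_end = 60)
  net <- network_spec(list(
    oscillator_unit("a"),
    oscillator_unit("b", variant = variant_spec("fly", alpha = 1),
                    stimulus = stim_periodic(phi = pi))))
  tr <- simulate_network(net, st)
  solo_a <- simulate_oscillator(settings = st)
  solo_b <- simulate_oscillator(variant = variant_spec("fly", alpha = 1),
                                stimulus = stim_periodic(phi = pi),
                                settings = st)
  expect_equal(tr$`a.M`, solo_a$M, tolerance = 1e-7)
  expect_equal(tr$`b.PN`, solo_b$PN, tolerance = 1e-7)
  expect_gte(min(as.matrix(tr[-1])), -1e-9)
})

test_that("declaration order does not change network trajectories", {
  st <- solver_settings(t_end = 48)
  central <- oscillator_unit("c", variant = variant_spec("mrna_decay", 0.05),
                             stimulus = stim_periodic(phi = pi))
  periph <- oscillator_unit("p")
  cp <- coupling_term("p", "product_decay", c("c", "P0"), 0.5)
  t1 <- simulate_network(network_spec(list(central, periph), list(cp)), st)
  t2 <- simulate_network(network_spec(list(periph, central), list(cp)), st)
  expect_equal(t1$`p.M`, t2$`p.M`, tolerance = 1e-9)
  expect_equal(t1$`c.P0`, t2$`c.P0`, tolerance = 1e-9)
})

test_that("a signal tap through the fly port equals explicit product decay", {
  st <- solver_settings(t_end = 72)
  central <- oscillator_unit("c", variant = variant_spec("mrna_decay", 0.05),
                             stimulus = stim_periodic(phi = pi))
  via_tap <- network_spec(list(
    central,
    oscillator_unit("p", variant = variant_spec("fly", alpha = 0.5),
                    stimulus = stim_tap("c", "P0"))))
  via_coupling <- network_spec(
    list(central, oscillator_unit("p")),
    list(coupling_term("p", "product_decay", c("c", "P0"), 0.5)))
  expect_equal(simulate_network(via_tap, st)$`p.M`,
               simulate_network(via_coupling, st)$`p.M`,
               tolerance = 1e-8)
})

test_that("homogeneous ensembles stay phase-identical; readout scales with n", {
  spec1 <- build_ensemble(1, alpha = 1, spread = 0)
  spec4 <- build_ensemble(4, alpha = 1, spread = 0,
                          stimulus = stim_pulse(30, 1, 1))
  st <- solver_settings(t_end = 90)
  tr1 <- ensemble_readout(simulate_network(build_ensemble(1, spread = 0,
                            stimulus = stim_pulse(30, 1, 1)), st))
  tr4 <- ensemble_readout(simulate_network(spec4, st))
  expect_equal(tr4$`osc1.M`, tr4$`osc4.M`, tolerance = 1e-9)
  expect_equal(tr4$readout, 4 * tr1$`osc1.M`, tolerance = 1e-7)
  expect_equal(ensemble_readout(simulate_network(spec1, st))$readout,
               simulate_network(spec1, st)$`osc1.M`)
})

test_that("a critically timed pulse desynchronizes an inhomogeneous ensemble", {
  spec <- build_ensemble(5, alpha = 1, spread = 0.5,
                         stimulus = stim_pulse(87.8, 1, 2))
  traj <- ensemble_readout(simulate_network(spec,
            solver_settings(t_end = 200, rel_tol = 1e-6, abs_tol = 1e-8)))
  amp <- function(w) {
    sel <- traj$t >= w[1] & traj$t <= w[2]
    diff(range(traj$readout[sel]))
  }
  expect_lt(amp(c(140, 190)), amp(c(30, 80)))
  expect_lt(amp(c(140, 190)), 0.6 * amp(c(30, 80)))
})
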