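test_that("parameter and state constructors validate their invariants", {
  expect_s3_class(core_parameters(), "core_parameters")
  expect_error(core_parameters(vs = -1), class = "clockstim_config_error")
  expect_error(core_parameters(n = 2.5), class = "clockstim_config_error")
  expect_error(oscillator_state(M = -1), class = "clockstim_config_error")
  expect_error(oscillator_state(M = NaN), class = "clockstim_config_error")
})

test_that("core derivatives match hand-computed values", {
  p <- core_parameters()
  d <- core_rhs(oscillator_state(M = 0, P0 = 0.5, P1 = 0.5, P2 = 0.6, PN = 0), p)
  expect_equal(d[["PN"]], 1.9 * 0.6, tolerance = 1e-12)
  d <- core_rhs(oscillator_state(), p)
  expect_equal(d[["PN"]], 1.9 * 0.6 - 1.3 * 1.5, tolerance = 1e-12)
  expect_equal(d[["M"]], 0.76 / (1 + 1.5^4) - 0.65 * 0.5 / (0.5 + 0.5),
               tolerance = 1e-12)
  expect_error(core_rhs(c(M = Inf, P0 = 1, P1 = 1, P2 = 1, PN = 1), p),
               class = "clockstim_config_error")
})

test_that("derivatives agree with the stoichiometric oracle on random states", {
  p <- core_parameters()
  for (s in random_states(100)) {
    got <- core_rhs(s, p)
    want <- oracle_rhs(s, p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("hill_form switch selects the alternative printed numerators", {
  p <- core_parameters()
  s <- oscillator_state()
  dK1 <- core_rhs(s, p, hill_form = "K1")
  dmix <- core_rhs(s, p, hill_form = "mixed")
  expect_equal(dK1[["M"]] - core_rhs(s, p)[["M"]],
               0.76 * 16 / (16 + 1.5^4) - 0.76 / (1 + 1.5^4),
               tolerance = 1e-12)
  expect_equal(dmix[["M"]], oracle_rhs(s, p, hill_num = p$K1)[["M"]],
               tolerance = 1e-12)
})

test_that("every variant reduces to the core model at zero stimulus", {
  p <- core_parameters()
  kinds <- c("mrna_decay", "fly", "mammal")
  for (s in random_states(20, seed = 7)) {
    base <- core_rhs(s, p)
    for (k in kinds)
      expect_equal(variant_rhs(s, p, variant_spec(k), u = 0), base,
                   tolerance = 1e-14)
    expect_equal(variant_rhs(s, p, variant_spec("mammal_machinery"), u = 0,
                             aux = c(T = 1, Tstar = 0)),
                 base, tolerance = 1e-14)
  }
})

test_that("variant terms add exactly one bilinear contribution", {
  p <- core_parameters()
  s <- oscillator_state()
  base <- core_rhs(s, p)
  d <- variant_rhs(s, p, variant_spec("fly", alpha = 1), u = 2)
  expect_equal(d[["P0"]] - base[["P0"]], -1 * 2 * 0.5, tolerance = 1e-12)
  expect_equal(d[setdiff(names(d), "P0")], base[setdiff(names(base), "P0")])
  s0 <- oscillator_state(M = 0)
  d <- variant_rhs(s0, p, variant_spec("mammal", gamma = 2, rho = 1), u = 1)
  expect_equal(d[["M"]] - core_rhs(s0, p)[["M"]], 2, tolerance = 1e-12)
  d <- variant_rhs(s, p, variant_spec("mrna_decay", alpha = 0.3), u = 2)
  expect_equal(d[["M"]] - base[["M"]], -0.3 * 2 * 0.5, tolerance = 1e-12)
  expect_error(variant_rhs(s, p, variant_spec("none"), u = 1),
               class = "clockstim_config_error")
})

test_that("transcription machinery conserves its total pool", {
  d <- machinery_rhs(T = 1, Tstar = 0.2, u = 1, rho_m = 1, xi = 0.5)
  expect_equal(d[["T"]], -1 + 0.1, tolerance = 1e-12)
  expect_equal(sum(d), 0)
  expect_equal(machinery_rhs(1, 0, u = 0, rho_m = 1, xi = 0.5),
               c(T = 0, Tstar = 0))
  set.seed(11)
  for (i in 1:25) {
    d <- machinery_rhs(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 3),
                       runif(1, 0.1, 2), runif(1, 0.1, 2))
    expect_equal(sum(d), 0, tolerance = 1e-14)
  }
  expect_error(machinery_rhs(1, 0, 1, rho_m = -1, xi = 0.5),
               class = "clockstim_config_error")
  # along a trajectory, T + T* stays at T0
  v <- variant_spec("mammal_machinery",
                    machinery = list(rho_m = 1, xi = 0.5, T0 = 1))
  traj <- simulate_oscillator(variant = v,
                              stimulus = stim_periodic(),
                              settings = solver_settings(t_end = 60))
  expect_lt(max(abs(traj$T + traj$Tstar - 1)), 1e-8)
})

test_that("cooperativity pair balances at u = gamma_h and exposes M1*M2", {
  r <- cooperativity_rhs(1, 1, u = 0.5, gamma_h = 0.5)
  expect_equal(unname(r$deriv), c(0, 0))
  r <- cooperativity_rhs(1, 2, u = 2, gamma_h = 0.5)
  expect_equal(r$deriv[["M1"]], 1.5, tolerance = 1e-12)
  expect_equal(r$signal, 2)
  # equal starting amounts stay equal: the pair obeys the same linear law
  rhs <- function(t, y) {
    unname(cooperativity_rhs(y[1], y[2], u = 1 + sin(t), gamma_h = 0.4)$deriv)
  }
  traj <- integrate_clock(rhs, c(M1 = 0.7, M2 = 0.7),
                          solver_settings(t_end = 30))
  expect_lt(max(abs(traj$M1 - traj$M2)), 1e-9)
})
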