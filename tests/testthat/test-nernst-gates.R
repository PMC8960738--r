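test_that("Nernst potential matches direct arithmetic and its symmetries", {
  # equal concentrations: no driving force
  expect_equal(nernst_potential(1, 5.4, 5.4), 0)
  # direct arithmetic oracle: (R T / z F) ln(co/ci) for K+ at 37 C
  R <- 8.3143; F <- 96.4867; T <- 310.15
  ek_oracle <- R * T / F * log(5.4 / 139)
  expect_equal(nernst_potential(1, 139, 5.4, T), ek_oracle)
  expect_equal(ek_oracle, -86.815, tolerance = 1e-4)
  # valence antisymmetry and divalent scaling
  expect_equal(nernst_potential(-1, 139, 5.4), -nernst_potential(1, 139, 5.4))
  expect_equal(nernst_potential(2, 1e-4, 1.8),
               nernst_potential(1, 1e-4, 1.8) / 2)
  expect_error(nernst_potential(1, 0, 5.4), "strictly positive")
  expect_error(nernst_potential(0, 1, 1), "non-zero")
})

test_that("gate steady states hit their printed half-points", {
  # I_Kr activation half-rise
  expect_equal(gate_kinetics("xr", v = 4.4451)$steady_state, 0.5,
               tolerance = 1e-6)
  # I_Ks at V = p1: sqrt(1/2)
  expect_equal(gate_kinetics("xs", v = 18.802)$steady_state, sqrt(0.5),
               tolerance = 1e-6)
  # f_Ca half-saturation at the printed [Ca]i, tau fixed at 2 ms
  fca <- gate_kinetics("fca", cai = 0.00035)
  expect_equal(fca$steady_state, 0.5)
  expect_equal(fca$tau, 2)
  # q_Ca: half-point, zero at zero flux, cubic Hill at 10x the half-point
  expect_equal(gate_kinetics("qca", fn = 1.1e-10)$steady_state, 0.5)
  expect_equal(gate_kinetics("qca", fn = 0)$steady_state, 0)
  expect_equal(gate_kinetics("qca", fn = 1.1e-9)$steady_state, 1 - 1 / 1001)
  # I_rel voltage-inactivation midpoint after the +40 mV shift
  expect_equal(gate_kinetics("w", v = 80)$steady_state, 0.5, tolerance = 1e-6)
  expect_error(gate_kinetics("nope", v = 0), "arg")
})

test_that("every gate stays within [0,1] with physiological time constants", {
  vs <- seq(-120, 80, by = 2.5)
  for (g in c("m", "h", "j", "d", "f", "ua", "uif", "uis", "xr", "xs", "w")) {
    k <- gate_kinetics(g, v = vs)
    expect_true(all(k$steady_state >= 0 & k$steady_state <= 1), label = g)
    expect_true(all(k$tau > 0), label = g)
  }
})

test_that("steady-state curves are monotone with the expected orientation", {
  vs <- seq(-90, 40, by = 1)
  inc <- function(g) expect_true(all(diff(gate_kinetics(g, v = vs)$steady_state)
                                     >= -1e-12), label = g)
  dec <- function(g) expect_true(all(diff(gate_kinetics(g, v = vs)$steady_state)
                                     <= 1e-12), label = g)
  inc("m"); inc("d"); inc("ua"); inc("xr"); inc("xs")
  dec("h"); dec("j"); dec("f"); dec("w")
  # combined availability h*j decreases as in the activation/inactivation plots
  hj <- gate_kinetics("h", v = vs)$steady_state *
    gate_kinetics("j", v = vs)$steady_state
  expect_true(all(diff(hj) <= 1e-12))
})

test_that("pig tau scalings multiply the source-model time constants", {
  p1 <- pig_params()
  p0 <- pig_params(tau_m_scale = 1, tau_h_scale = 1, tau_j_scale = 1)
  v <- -40
  expect_equal(gate_kinetics("m", v = v, params = p1)$tau,
               1.7 * gate_kinetics("m", v = v, params = p0)$tau)
  expect_equal(gate_kinetics("h", v = v, params = p1)$tau,
               2 * gate_kinetics("h", v = v, params = p0)$tau)
  expect_equal(gate_kinetics("j", v = v, params = p1)$tau,
               2 * gate_kinetics("j", v = v, params = p0)$tau)
  # slow I_Kur inactivation shares the steady state, 20x slower
  expect_equal(gate_kinetics("uis", v = v)$steady_state,
               gate_kinetics("uif", v = v)$steady_state)
  expect_equal(gate_kinetics("uis", v = v)$tau,
               20 * gate_kinetics("uif", v = v)$tau)
})
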