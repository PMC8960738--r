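# effectively-zero values that satisfy the strict-positivity invariants
.eps <- 1e-300

test_that("total Ca2+ is conserved when transmembrane Ca2+ flux is zero", {
  # bookkeeping oracle: myoplasm + buffers + SR contents before vs after a
  # step, with all transmembrane Ca2+ pathways disabled
  p <- pig_params(g_cal = .eps, g_bca = .eps, i_pca_max = .eps,
                  i_naca_max = .eps)
  s <- fix_resting()
  tot0 <- pigatria:::total_calcium(s)
  tot1 <- pigatria:::total_calcium(step_cell(s, p))
  expect_lt(abs(tot1 - tot0), 1e-9)
})

test_that("the discrete bookkeeping error vanishes quadratically in dt", {
  # during active release the rapid-buffering update carries an O(dt^2)
  # bookkeeping error per step; conservation is exact in continuous time,
  # so halving dt must shrink the one-step error about fourfold
  p <- pig_params(g_cal = .eps, g_bca = .eps, i_pca_max = .eps,
                  i_naca_max = .eps)
  s <- fix_resting(); s[["u"]] <- 0.3; s[["v_rel"]] <- 0.6
  s[["cai"]] <- 3e-4; s[["carel"]] <- 1.2    # release in progress
  err_at <- function(dt) {
    tot0 <- pigatria:::total_calcium(s)
    abs(pigatria:::total_calcium(step_cell(s, p, dt = dt)) - tot0) / dt
  }
  e1 <- err_at(0.02); e2 <- err_at(0.01); e3 <- err_at(0.005)
  expect_lt(e2, e1 / 1.7)
  expect_lt(e3, e2 / 1.7)
})

test_that("SR compartments stay fixed when all SR fluxes vanish", {
  p <- pig_params(k_rel = .eps, i_up_max = .eps, tau_tr = 1e300)
  s <- fix_resting()
  s1 <- step_cell(s, p)
  expect_equal(s1[["caup"]], s[["caup"]], tolerance = 1e-14)
  expect_equal(s1[["carel"]], s[["carel"]], tolerance = 1e-14)
})

test_that("SR release inactivates with the shifted, steepened voltage gate", {
  # midpoint at +80 mV, steeper than the source model's slope
  w <- gate_kinetics("w", v = c(40, 80, 120))
  expect_gt(w$steady_state[1], 0.98)   # open at plateau voltages
  expect_equal(w$steady_state[2], 0.5, tolerance = 1e-6)
  expect_lt(w$steady_state[3], 0.02)
  w2 <- gate_kinetics("w", v = c(75, 85))
  slope <- diff(w2$steady_state) / 10
  w_crn <- function(v) 1 - 1 / (1 + exp(-(v - 40) / 17))
  slope_crn <- (w_crn(45) - w_crn(35)) / 10
  expect_gt(abs(slope), 1.5 * abs(slope_crn))
})

test_that("a paced beat releases SR Ca2+ and activates the chloride gate", {
  p <- pig_params()
  sim <- simulate_cell(p, duration = 400, stim_times = 5,
                       state = fix_paced_1hz(), record_every = 0.5,
                       currents = TRUE)
  expect_gt(max(sim$i_rel), 0.01)          # release fires
  expect_gt(max(sim$f_n), 1e-12)           # net influx positive during AP
  expect_gt(max(sim$cai), sim$cai[1])      # Ca2+ transient
  expect_gt(max(sim$qca), 0)               # I_ClCa gate responds
  # Ca2+ returns toward diastolic levels by the end of the beat
  expect_lt(sim$cai[nrow(sim)], 2 * sim$cai[1])
})
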