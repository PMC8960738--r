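test_that("the resting state is a quiescent equilibrium", {
  p <- pig_params()
  rs <- fix_resting()
  # a single unstimulated step barely moves the voltage
  s1 <- step_cell(rs, p)
  expect_lt(abs(s1[["v"]] - rs[["v"]]), 1e-4)
  # reloaded fixture stepped 1 s unstimulated: |dV| < 0.1 mV
  sim <- simulate_cell(p, duration = 1000, state = rs, record_every = 1000)
  expect_lt(abs(attr(sim, "final_state")[["v"]] - rs[["v"]]), 0.1)
  # 10 s unstimulated: every Ca2+ compartment drifts < 1%
  s10 <- equilibrate_state(p, state = rs, duration = 10000)
  for (k in c("cai", "caup", "carel"))
    expect_lt(abs(s10[[k]] / rs[[k]] - 1), 0.01, label = k)
})

test_that("a stimulated beat produces a full AP with ordered APDs", {
  p <- pig_params()
  sim <- simulate_cell(p, duration = 900, stim_times = 10,
                       state = fix_paced_1hz(), record_every = 0.05)
  f <- extract_ap_features(sim)
  expect_true(f$captured)
  expect_gt(f$apa, 90)
  expect_lt(f$rmp, -70)
  expect_gt(f$dvdt_max, 100)
  apds <- unlist(f[paste0("apd_", seq(10, 90, 10))])
  expect_true(all(diff(apds) >= 0))
  expect_gt(f$apd_90, 100); expect_lt(f$apd_90, 300)
})

test_that("halving dt changes APD90 by less than 1 ms (dt refinement)", {
  st <- fix_paced_1hz()
  apd90 <- vapply(c(0.02, 0.01), function(dt) {
    p <- pig_params(dt = dt)
    sim <- simulate_cell(p, duration = 900, stim_times = 10, state = st,
                         record_every = 0.05)
    extract_ap_features(sim)$apd_90
  }, numeric(1))
  expect_lt(abs(diff(apd90)), 1)
})

test_that("trajectories are deterministic and gates remain probabilities", {
  p <- pig_params()
  st <- fix_paced_1hz()
  a <- simulate_cell(p, duration = 500, stim_times = 10, state = st)
  b <- simulate_cell(p, duration = 500, stim_times = 10, state = st)
  expect_identical(as.data.frame(a), as.data.frame(b))
  fs <- attr(a, "final_state")
  gates <- fs[c("m", "h", "j", "d", "f", "fca", "ua", "uif", "uis",
                "xr", "xs", "qca", "u", "v_rel", "w")]
  expect_true(all(gates >= 0 & gates <= 1))
})

test_that("Rush-Larsen gate integration reproduces the Euler solution", {
  st <- fix_paced_1hz()
  pe <- pig_params()
  prl <- pig_params(rush_larsen = TRUE)
  fe <- extract_ap_features(simulate_cell(pe, 900, 10, state = st,
                                          record_every = 0.05))
  frl <- extract_ap_features(simulate_cell(prl, 900, 10, state = st,
                                           record_every = 0.05))
  expect_lt(abs(fe$apd_90 - frl$apd_90), 1)
  expect_lt(abs(fe$apa - frl$apa), 1)
})

test_that("the integrator rejects invalid time steps", {
  expect_error(simulate_cell(pig_params(dt = 0.1), 10), "0, 0.05")
  expect_error(step_cell(fix_resting(), pig_params(), dt = 0.2), "0, 0.05")
})
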