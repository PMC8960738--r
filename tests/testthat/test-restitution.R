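test_that("late-repolarisation APD restitution is monotone in cycle length", {
  r <- fix_restitution()
  expect_true(all(r$captured))
  r <- dplyr::arrange(tibble::as_tibble(r), cl)
  for (cn in c("apd_60", "apd_70", "apd_80", "apd_90"))
    expect_true(all(diff(r[[cn]]) >= 0), label = cn)
})

test_that("early APD shows the pig-specific downward trend at long CL", {
  r <- fix_restitution()
  # early repolarisation (up to APD50): value at CL 4000 exceeds CL 1000
  a4000 <- r[r$cl == 4000, ]
  a1000 <- r[r$cl == 1000, ]
  expect_gt(a4000$apd_20, a1000$apd_20)
  expect_gt(a4000$apd_10, a1000$apd_10)
})

test_that("peak I_ClCa and peak Ca2+ flux fall as CL shortens below 1 s", {
  r <- dplyr::arrange(tibble::as_tibble(fix_restitution()), cl)
  sub <- r[r$cl <= 1000, ]
  expect_gte(nrow(sub), 3)
  expect_true(all(diff(sub$peak_iclca) >= 0))   # increasing with CL
  expect_true(all(diff(sub$peak_ca_flux) >= 0))
})

test_that("sustained pacing at CL 200 ms fails 1:1 propagation in tissue", {
  # the tissue refractory period (~ERP) exceeds 200 ms, so every other
  # stimulus is blocked
  sim <- simulate_cable(3, pig_params(), stim_times = stim_train(8, 200, 0),
                        probe_pos_cm = c(1, 2), duration = 2100,
                        state = fix_paced_1hz())
  up <- pigatria:::upcross_times(sim$probe_times, sim$probe_v[, 1], -35)
  expect_lt(length(up), 8)
})

test_that("ERP bisection captures far outside refractoriness and is dt-robust", {
  p <- pig_params()
  st <- fix_paced_1hz()
  erp1 <- measure_erp(p, state = st)
  expect_gt(erp1, 150); expect_lt(erp1, 300)
  # an S2 at 500 ms coupling is far outside the refractory period
  expect_gt(500, erp1)
  p2 <- pig_params(dt = 0.01)
  erp2 <- measure_erp(p2, state = st)
  expect_lt(abs(erp1 - erp2), 2)
})
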