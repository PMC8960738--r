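test_that("a rectangular pulse yields APD equal to its width at all levels", {
  t <- seq(0, 100, by = 0.05)
  w <- 30
  v <- ifelse(t >= 20 & t < 20 + w, 20, -80)
  f <- extract_ap_features(tibble::tibble(time = t, v = v), stim_times = 19.8)
  expect_true(f$captured)
  for (x in seq(10, 90, 10))
    expect_equal(f[[paste0("apd_", x)]], w, tolerance = 0.1)
})

test_that("features are invariant to shifting the pre-stimulus window", {
  sim <- simulate_cell(pig_params(), duration = 700, stim_times = 100,
                       state = fix_paced_1hz(), record_every = 0.1)
  f1 <- extract_ap_features(sim)
  # drop the first 80 ms of quiescent baseline
  tr <- dplyr::filter(tibble::as_tibble(sim), time >= 80)
  f2 <- extract_ap_features(tr, stim_times = 100)
  for (cn in c("rmp", "apa", "dvdt_max", "apd_50", "apd_90"))
    expect_equal(f1[[cn]], f2[[cn]], tolerance = 1e-6, label = cn)
  # idempotence
  f3 <- extract_ap_features(sim)
  expect_identical(as.data.frame(f1), as.data.frame(f3))
})

test_that("a subthreshold response is flagged as no-capture, not an error", {
  sim <- simulate_cell(pig_params(), duration = 400, stim_times = 10,
                       state = fix_resting(), stim_amplitude = 2)
  f <- extract_ap_features(sim)
  expect_false(f$captured)
  expect_true(is.na(f$apd_90))
  expect_true(is.finite(f$rmp))
})

test_that("per-beat APDs are ordered on every model beat", {
  sim <- simulate_cell(pig_params(), duration = 3000,
                       stim_times = stim_train(3, 1000, 10),
                       state = fix_paced_1hz(), record_every = 0.1)
  f <- extract_ap_features(sim)
  expect_equal(nrow(f), 3)
  for (b in seq_len(3)) {
    apds <- unlist(f[b, paste0("apd_", seq(10, 90, 10))])
    expect_true(all(diff(apds) >= 0))
  }
  expect_equal(f$cl[2:3], c(1000, 1000))
})
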