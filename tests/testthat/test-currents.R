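test_that("current zero-crossings sit at the printed reversal conditions", {
  p <- pig_params()
  s <- fix_resting()
  ek <- nernst_potential(1, s[["ki"]], p$k_o, p$temperature)

  # I_K1 vanishes exactly at V = E_K + 5 and changes sign there
  s1 <- s; s1[["v"]] <- ek + 5
  expect_equal(compute_currents(s1, p)$i_k1, 0, tolerance = 1e-12)
  s1[["v"]] <- ek + 5 - 1
  below <- compute_currents(s1, p)$i_k1
  s1[["v"]] <- ek + 5 + 1
  above <- compute_currents(s1, p)$i_k1
  expect_lt(below, 0); expect_gt(above, 0)

  # I_CaL driving force vanishes at +65 mV regardless of the gates
  s2 <- s; s2[["v"]] <- 65; s2[["d"]] <- 0.9; s2[["f"]] <- 0.9; s2[["fca"]] <- 0.9
  expect_equal(compute_currents(s2, p)$i_cal, 0, tolerance = 1e-12)

  # closed gates kill I_Na and I_ClCa
  s3 <- s; s3[["m"]] <- 0
  expect_equal(compute_currents(s3, p)$i_na, 0)
  s4 <- s; s4[["qca"]] <- 0
  expect_equal(compute_currents(s4, p)$i_clca, 0)

  # I_ClCa vanishes at the chloride reversal potential
  s5 <- s; s5[["v"]] <- p$e_cl; s5[["qca"]] <- 0.5
  expect_equal(compute_currents(s5, p)$i_clca, 0, tolerance = 1e-12)
})

test_that("i_ion is the sum of the twelve membrane currents", {
  p <- pig_params()
  s <- fix_resting()
  for (v in c(-120, -80, -40, 0, 30)) {
    s[["v"]] <- v
    cur <- compute_currents(s, p)
    twelve <- cur$i_na + cur$i_k1 + cur$i_clca + cur$i_kur + cur$i_kr +
      cur$i_ks + cur$i_cal + cur$i_pca + cur$i_nak + cur$i_naca +
      cur$i_bna + cur$i_bca
    expect_identical(cur$i_ion, twelve)
  }
})

test_that("the voltage-dependent I_Kur conductance saturates at its limits", {
  p <- pig_params()
  lo <- cpp_vrates(-140, p)[["g_kur_v"]]
  hi <- cpp_vrates(180, p)[["g_kur_v"]]
  expect_equal(lo, 0.005 * p$g_kur_amp, tolerance = 1e-4)
  expect_equal(hi, 0.055 * p$g_kur_amp, tolerance = 1e-4)
})

test_that("rectifier currents match the closed-form expressions (dual route)", {
  # independent reimplementation of the current formulas in R, with gates
  # frozen at their steady states: the instantaneous-IV oracle
  p <- pig_params()
  s <- fix_resting()
  for (v in c(-60, -20, 10, 30)) {
    s[["v"]] <- v
    for (g in c("ua", "uif", "uis", "xr", "xs"))
      s[[g]] <- gate_kinetics(g, v = v)$steady_state
    cur <- compute_currents(s, p)
    ek <- nernst_potential(1, s[["ki"]], p$k_o, p$temperature)
    gkur <- p$g_kur_amp * (0.005 + 0.05 / (1 + exp(-(v - 15) / 13)))
    ua <- s[["ua"]]; ui <- s[["uif"]]
    expect_equal(cur$i_kur,
                 gkur * ua^3 * (0.25 * ui + 0.75 * ui) * (v - ek),
                 tolerance = 1e-9)
    expect_equal(cur$i_kr,
                 p$g_kr * s[["xr"]] * (v - ek) /
                   (1 + exp((v - 79.4825) / 8.2217)),
                 tolerance = 1e-9)
    expect_equal(cur$i_ks, p$g_ks * s[["xs"]]^2 * (v - ek), tolerance = 1e-9)
    expect_equal(cur$i_k1,
                 p$g_k1 * (v - ek - 5) / (1 + exp(0.063 * (v + 70))),
                 tolerance = 1e-9)
  }
})

test_that("F_n couples release, L-type and exchanger fluxes as specified", {
  p <- pig_params()
  s <- fix_resting()
  cur <- compute_currents(s, p)
  fn <- compute_fn_qca(s, p, currents = cur)
  # independent arithmetic from the recorded currents
  fn_oracle <- 1e-12 * 96.48 * cur$i_rel -
    (5e-13 / 96.4867) * (0.5 * cur$i_cal - 0.2 * cur$i_naca) * p$cm
  expect_equal(fn$f_n, fn_oracle, tolerance = 1e-15)
  expect_equal(fn$tau_qca, 2)
})
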