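# End-to-end reentry on the coarse desk-scale grid: the S1-S2 cross-field
# protocol, tip tracking, spectrum and phase-singularity census all run on
# the model's own output (quantitative tip metrics at this resolution are
# not comparable to the full-resolution study; see the methods vignette).

test_that("the cross-field protocol initiates a rotating spiral", {
  sim <- fix_mini_spiral()
  expect_true(attr(sim, "spiral_formed"))
  expect_gt(attr(sim, "s2_time"), 0)
  ps <- count_phase_singularities(sim)
  post <- ps[ps$time > attr(sim, "s2_time") + 100, ]
  # reentry persists: singularities present in most frames to the end
  expect_gt(mean(post$n_ps >= 1), 0.8)
  expect_gte(min(post$n_ps), 0)
})

test_that("the spiral tip meanders and yields a signed rotation spectrum", {
  sim <- fix_mini_spiral()
  traj <- tip_trajectory(sim)
  expect_gt(nrow(traj), 20)
  # displacement gate: the linked tip never jumps more than 1 cm per 10 ms
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  expect_true(all(step < 1))
  spec <- trajectory_spectrum(traj)
  pk <- attr(spec, "peaks")
  expect_gte(nrow(pk), 2)
  rot <- attr(spec, "rotation_period")
  expect_true(is.finite(rot) && rot > 0)
  # rotation is resolved well below the recorded window
  expect_lt(rot, diff(range(traj$time)))
})

test_that("S2 after full recovery yields a plane wave and no reentry", {
  p <- pig_params(); p$dx <- 0.088
  sim <- s1s2_crossfield(p, nx = 48, duration_after_s2 = 200,
                         s2_delay = 1200, snapshot_every = 10,
                         state = fix_resting())
  # by 1.2 s the S1 wave has left the domain and tissue is fully recovered:
  # the S2 half-plane stimulus launches a plane wave with zero singularities
  ps <- count_phase_singularities(sim)
  late <- ps[ps$time > 1200 + 60, ]
  expect_true(all(late$n_ps == 0))
  expect_false(attr(sim, "spiral_formed"))
})
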