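test_that("the signed spectrum resolves rotating phasors analytically", {
  # counterclockwise circle at +5 Hz: one peak at +5
  tr <- synth_phasor_trajectory(5, 1, duration_s = 2, fs = 100)
  pk <- attr(trajectory_spectrum(tr), "peaks")
  expect_equal(pk$frequency[1], 5, tolerance = 1e-9)
  expect_equal(pk$magnitude[1], 1, tolerance = 1e-9)
  # clockwise: the peak appears at -5
  tr2 <- synth_phasor_trajectory(-5, 1, duration_s = 2, fs = 100)
  expect_equal(attr(trajectory_spectrum(tr2), "peaks")$frequency[1], -5,
               tolerance = 1e-9)
  # two counter-rotating circles: peaks at the signed frequencies with
  # heights proportional to the radii
  tr3 <- synth_phasor_trajectory(c(5, -3), c(1, 0.5), duration_s = 2, fs = 100)
  pk3 <- attr(trajectory_spectrum(tr3), "peaks")
  expect_equal(sort(pk3$frequency[1:2]), c(-3, 5), tolerance = 1e-9)
  expect_equal(pk3$magnitude[pk3$frequency == 5] /
                 pk3$magnitude[pk3$frequency == -3], 2, tolerance = 1e-6)
  expect_error(trajectory_spectrum(tr[1:4, ]), "too short")
})

test_that("tip detection finds a synthetic spiral core and ignores planes", {
  dx <- 0.05
  sp <- synth_spiral_field(64, 64, dx = dx, times = seq(0, 100, 10))
  core <- c(63, 63) * dx / 2
  for (k in 2:5) {
    tips <- track_tip(sp$snapshots[[k]], sp$snapshots[[k - 1]], dx)
    expect_gte(nrow(tips), 1)
    d <- sqrt((tips$x - core[1])^2 + (tips$y - core[2])^2)
    expect_lt(min(d), 2 * dx)
  }
  pw <- synth_plane_wave_field(64, 64, dx = dx, times = c(0, 10))
  tips <- track_tip(pw$snapshots[[2]], pw$snapshots[[1]], dx)
  expect_equal(nrow(tips), 0)
})

test_that("tip localisation sharpens under grid refinement", {
  err_at <- function(nx, dx) {
    sp <- synth_spiral_field(nx, nx, dx = dx, times = c(0, 10),
                             core = c((nx - 1) * dx / 2, (nx - 1) * dx / 2))
    tips <- track_tip(sp$snapshots[[2]], sp$snapshots[[1]], dx)
    core <- (nx - 1) * dx / 2
    min(sqrt((tips$x - core)^2 + (tips$y - core)^2))
  }
  e_coarse <- err_at(32, 0.1)
  e_fine <- err_at(64, 0.05)
  expect_lte(e_fine, e_coarse + 1e-9)
})

test_that("phase singularities count one per spiral tip and none for planes", {
  sp <- synth_spiral_field(64, 64, dx = 0.05, times = seq(0, 50, 10))
  ps <- count_phase_singularities(sp)
  expect_true(all(ps$n_ps == 1))
  # opposite chirality still counts a single singularity
  sp2 <- synth_spiral_field(64, 64, dx = 0.05, times = seq(0, 50, 10),
                            sense = -1)
  expect_true(all(count_phase_singularities(sp2)$n_ps == 1))
  pw <- synth_plane_wave_field(64, 64, dx = 0.05, times = seq(0, 50, 10))
  expect_true(all(count_phase_singularities(pw)$n_ps == 0))
})

test_that("tip linking follows a moving synthetic core within the gate", {
  dx <- 0.05
  frames <- purrr::map(seq(0, 100, 10), function(t) {
    core <- c(1.5 + 0.002 * t, 1.5)    # slow drift
    synth_spiral_field(64, 64, dx = dx, times = t, core = core)$snapshots[[1]]
  })
  sim <- list(snapshots = frames, snap_times = seq(0, 100, 10),
              nx = 64, ny = 64, dx = dx)
  traj <- tip_trajectory(sim)
  expect_gte(nrow(traj), 8)
  expect_true(all(diff(traj$time) > 0))
  # consecutive displacement respects the 1 cm / 10 ms sanity gate
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  expect_true(all(step < 1))
  # recovered drift direction is rightward
  expect_gt(dplyr::last(traj$x), dplyr::first(traj$x))
})

test_that("APD mapping flags constructed alternans and not periodic trains", {
  # synthetic per-site voltage: square APs at CL 300, constant vs alternating
  times <- seq(0, 4800, by = 10)
  mk_site <- function(apds) {
    v <- rep(-80, length(times))
    for (b in seq_along(apds)) {
      t0 <- 100 + (b - 1) * 300
      v[times >= t0 & times < t0 + apds[b]] <- 10
    }
    v
  }
  nxy <- 5
  mk_sim <- function(apds) {
    vs <- mk_site(apds)
    snaps <- purrr::map(seq_along(times), function(k)
      matrix(vs[k], nxy, nxy))
    list(snapshots = snaps, snap_times = times, nx = nxy, ny = nxy, dx = 0.1)
  }
  per <- apd_map(mk_sim(rep(150, 15)), stride = 4, min_beats = 4)
  expect_true(all(!per$alternans))
  expect_true(all(abs(per$apd90[per$beat > 1] - 150) < 15))
  alt <- apd_map(mk_sim(rep(c(140, 160), 8)), stride = 4, min_beats = 4)
  expect_true(all(alt$alternans))
  # cycle lengths recovered
  expect_true(all(abs(stats::na.omit(per$cl) - 300) < 15))
})
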