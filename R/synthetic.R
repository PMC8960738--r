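#' Synthetic rotating-phasor trajectory
#'
#' Builds a trajectory as a sum of circular orbits
#' \eqn{z(t) = \sum_k r_k e^{2\pi i f_k t}} with signed frequencies (Hz):
#' positive = counterclockwise. Two counter-rotating components produce a
#' hypocycloidal "flower" — the closed-form oracle for the trajectory
#' spectrum.
#'
#' @param freqs signed frequencies, Hz.
#' @param radii orbit radii, cm (same length as `freqs`).
#' @param duration_s duration, s.
#' @param fs sampling frequency, Hz.
#' @param center trajectory centre `c(x, y)`, cm.
#' @return A `tip_trajectory` tibble (`time` ms, `x`, `y` cm).
#' @export
synth_phasor_trajectory <- function(freqs, radii, duration_s = 2, fs = 100,
                                    center = c(0, 0)) {
  stopifnot(length(freqs) == length(radii))
  t_s <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  z <- rowSums(vapply(seq_along(freqs), function(k)
    radii[k] * exp(2i * pi * freqs[k] * t_s), complex(length(t_s))))
  structure(tibble(time = t_s * 1000, x = Re(z) + center[1],
                   y = Im(z) + center[2]),
            interval = 1000 / fs,
            class = c("tip_trajectory", class(tibble())))
}

#' Synthetic rotating spiral voltage field
#'
#' An Archimedean spiral pattern
#' \eqn{V(r,\theta,t) = V^* + a(r)\cos(\theta - kr + \omega t)} with the
#' amplitude envelope \eqn{a(r) = a_0 (1 - e^{-r/r_0})} vanishing at the
#' core, so the V = V* and dV/dt = 0 contours intersect transversally
#' exactly at the core — the known-tip oracle for [track_tip()].
#'
#' @param nx,ny grid size; `dx` spacing (cm).
#' @param times frame times, ms.
#' @param period_ms rotation period, ms.
#' @param core core position `c(x, y)` in cm.
#' @param wavelength_cm radial wavelength of the arms, cm.
#' @param v_star offset (the isopotential level at the core), mV.
#' @param amplitude far-field amplitude a0, mV.
#' @param r0 core envelope radius, cm.
#' @param lag_ms lag used for the companion phase-embedding frames.
#' @param sense `+1` (counterclockwise) or `-1`.
#' @return A list shaped like a `pig_tissue_sim` (elements `snapshots`,
#'   `snapshots_lag`, `snap_times`, `nx`, `ny`, `dx`).
#' @export
synth_spiral_field <- function(nx = 64, ny = 64, dx = 0.05,
                               times = seq(0, 500, by = 10),
                               period_ms = 180, core = NULL,
                               wavelength_cm = 2, v_star = -35,
                               amplitude = 45, r0 = 0.15, lag_ms = 2,
                               sense = 1) {
  if (is.null(core)) core <- c((nx - 1) * dx / 2, (ny - 1) * dx / 2)
  xs <- (seq_len(nx) - 1) * dx
  ys <- (seq_len(ny) - 1) * dx
  gx <- matrix(xs, nx, ny) - core[1]
  gy <- matrix(ys, nx, ny, byrow = TRUE) - core[2]
  r <- sqrt(gx^2 + gy^2)
  th <- atan2(gy, gx)
  k <- 2 * pi / wavelength_cm
  a <- amplitude * (1 - exp(-r / r0))
  frame <- function(t)
    v_star + a * cos(th - k * r + sense * 2 * pi * t / period_ms)
  list(snapshots = purrr::map(times, frame),
       snapshots_lag = purrr::map(times, function(t) frame(t - lag_ms)),
       snap_times = times, nx = nx, ny = ny, dx = dx)
}

#' Synthetic plane-wave field
#'
#' A translating plane wave (no tip, no phase singularity): the negative
#' control for tip detection and the phase-singularity census.
#'
#' @inheritParams synth_spiral_field
#' @param speed_cm_ms front speed, cm/ms.
#' @export
synth_plane_wave_field <- function(nx = 64, ny = 64, dx = 0.05,
                                   times = seq(0, 200, by = 10),
                                   speed_cm_ms = 0.058, wavelength_cm = 2,
                                   v_star = -35, amplitude = 45,
                                   lag_ms = 2) {
  xs <- (seq_len(nx) - 1) * dx
  gx <- matrix(xs, nx, ny)
  k <- 2 * pi / wavelength_cm
  frame <- function(t) v_star + amplitude * cos(k * (gx - speed_cm_ms * t))
  list(snapshots = purrr::map(times, frame),
       snapshots_lag = purrr::map(times, function(t) frame(t - lag_ms)),
       snap_times = times, nx = nx, ny = ny, dx = dx)
}

#' Generate the packaged test fixtures
#'
#' Deterministic small artifacts used by the test-suite and examples:
#' \describe{
#'   \item{`resting_state`}{the equilibrated quiescent state (CSV).}
#'   \item{`clamp_traces`}{per-current IV curves from the simulated clamp
#'     protocols (CSV, 5 mV steps).}
#'   \item{`short_cable`}{probe traces of a single paced beat in a 3 cm
#'     cable (CSV).}
#'   \item{`mini_spiral`}{a coarse (reduced-resolution) S1-S2 spiral history
#'     for exercising the analysis pipeline (RDS).}
#' }
#'
#' @param kind fixture name (above).
#' @param dir output directory.
#' @param params a [pig_params()] object.
#' @return The path(s) of the file(s) written, invisibly.
#' @export
generate_fixtures <- function(kind = c("resting_state", "clamp_traces",
                                       "short_cable", "mini_spiral"),
                              dir = tempdir(), params = pig_params()) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(kind,
    resting_state = {
      s <- equilibrate_state(params)
      f <- file.path(dir, "resting_state.csv")
      write.csv(data.frame(variable = names(s), value = unname(s)), f,
                row.names = FALSE)
      f
    },
    clamp_traces = {
      specs <- list(
        i_cal = clamp_protocol("i_cal", cai_clamp = 1e-4),
        i_clca = clamp_protocol("i_clca"),
        i_kur = clamp_protocol("i_kur", measurement_rule = "steady")
      )
      purrr::imap_chr(specs, function(pr, nm) {
        iv <- run_voltage_clamp(pr, params)
        f <- file.path(dir, paste0("iv_", nm, ".csv"))
        write.csv(as.data.frame(iv), f, row.names = FALSE)
        f
      })
    },
    short_cable = {
      sim <- simulate_cable(3, params, stim_times = 0,
                            probe_pos_cm = c(1, 2), duration = 120)
      f <- file.path(dir, "short_cable_probes.csv")
      write.csv(data.frame(time = sim$probe_times,
                           v_probe1 = sim$probe_v[, 1],
                           v_probe2 = sim$probe_v[, 2]), f,
                row.names = FALSE)
      f
    },
    mini_spiral = {
      sim <- mini_spiral_sim(params)
      f <- file.path(dir, "mini_spiral.rds")
      saveRDS(sim, f)
      f
    })
  invisible(paths)
}

#' Coarse-grid S1-S2 spiral simulation
#'
#' A reduced-resolution cross-field run (coarser grid, smaller domain,
#' shorter time than the full-resolution study) that still produces a
#' rotating spiral — the desk-scale input for the analysis pipeline. The
#' coarse spacing shortens the numerically resolved wavelength, so the
#' domain supports a spiral despite being smaller than the full-model
#' minimum; quantitative tip metrics are not comparable to the
#' full-resolution run.
#'
#' @param params a [pig_params()] object.
#' @param nx grid side (default 72).
#' @param dx_cm coarse spacing (default 0.088 cm, 4x the default grid).
#' @param duration_after_s2 ms of spiral evolution recorded.
#' @return A `pig_tissue_sim`.
#' @export
mini_spiral_sim <- function(params = pig_params(), nx = 72, dx_cm = 0.088,
                            duration_after_s2 = 700) {
  p <- params
  p$dx <- dx_cm
  s1s2_crossfield(p, nx = nx, duration_after_s2 = duration_after_s2,
                  snapshot_every = 10)
}
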