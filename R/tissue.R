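#' Construct a tissue field
#'
#' A rectangular monodomain lattice of identical pig atrial cells (a cable
#' when `ny = 1`), with no-flux boundaries, grid spacing `dx = dy` and
#' diffusion coefficient `D` taken from the parameter set (defaults
#' 0.022 cm and 0.00126 cm^2/ms).
#'
#' @param nx,ny grid dimensions (number of nodes).
#' @param params a [pig_params()] object.
#' @param state per-cell initial state (one state recycled to all cells).
#' @return A `tissue_field` object.
#' @export
tissue_field <- function(nx, ny = 1, params = pig_params(),
                         state = pig_resting_state(params)) {
  state <- validate_state(state)
  ncell <- nx * ny
  states <- matrix(rep(unname(state), ncell), nrow = length(state))
  rownames(states) <- names(state)
  structure(list(states = states, nx = as.integer(nx), ny = as.integer(ny),
                 dx = params$dx, D = params$D, time = 0, params = params),
            class = "tissue_field")
}

#' @rdname tissue_field
#' @param length_cm cable length in cm (number of nodes is
#'   `round(length_cm / dx)`).
#' @export
cable_field <- function(length_cm, params = pig_params(),
                        state = pig_resting_state(params)) {
  tissue_field(nx = max(3L, as.integer(round(length_cm / params$dx))),
               ny = 1L, params = params, state = state)
}

#' @export
print.tissue_field <- function(x, ...) {
  cat(sprintf("<tissue_field> %d x %d nodes, dx %.3g cm (%.3g x %.3g cm), D %.4g cm^2/ms, t = %.6g ms\n",
              x$nx, x$ny, x$dx, x$nx * x$dx, x$ny * x$dx, x$D, x$time))
  invisible(x)
}

#' Stimulus regions
#'
#' Helpers building the spatial stimulus descriptions used by
#' [run_tissue()]: an explicit node set, a strip along the left edge (the S1
#' electrode), or the lower half-plane `y <= ny/2` (the S2 cross-field
#' electrode).
#'
#' @param idx 1-based node indices (column-major over the `nx` x `ny` grid).
#' @param nx,ny grid dimensions.
#' @param amplitude stimulus density, pA/pF (positive = depolarising).
#' @param start onset time, ms.
#' @param duration pulse duration, ms (> 0).
#' @return A list with entries `idx` (0-based, for the solver), `amplitude`,
#'   `start`, `duration`.
#' @export
stim_region_nodes <- function(idx, nx, ny, amplitude, start, duration) {
  idx <- as.integer(idx)
  if (length(idx) == 0) abort("stimulus mask must be non-empty")
  if (duration <= 0) abort("stimulus duration must be positive")
  if (any(idx < 1 | idx > nx * ny)) abort("stimulus node index out of range")
  list(idx = idx - 1L, amplitude = amplitude, start = start,
       duration = duration)
}

#' @rdname stim_region_nodes
#' @param field a [tissue_field()] object.
#' @param width strip width in nodes (default 5).
#' @export
stim_left_edge <- function(field, amplitude, start, duration, width = 5) {
  ix <- seq_len(min(width, field$nx))
  idx <- as.vector(outer(ix, (seq_len(field$ny) - 1) * field$nx, `+`))
  stim_region_nodes(idx, field$nx, field$ny, amplitude, start, duration)
}

#' @rdname stim_region_nodes
#' @export
stim_lower_half <- function(field, amplitude, start, duration) {
  iy <- seq_len(max(1L, field$ny %/% 2L))
  idx <- as.vector(outer(seq_len(field$nx), (iy - 1) * field$nx, `+`))
  stim_region_nodes(idx, field$nx, field$ny, amplitude, start, duration)
}

#' Run the monodomain solver
#'
#' Advances the field by forward-time centred-space (FTCS) integration of
#' the monodomain equation: the voltage diffuses through a 5-point Laplacian
#' with no-flux (mirrored ghost node) boundaries while every node's ionic
#' state advances by the single-cell stepper. Refuses to run if the
#' stability bound `D dt / dx^2 <= 0.25` is violated.
#'
#' @param field a [tissue_field()] object.
#' @param stimuli list of stimulus regions (see [stim_region_nodes()]).
#' @param duration simulated time, ms.
#' @param snapshot_every voltage-snapshot cadence in ms (0 = none).
#' @param probes 1-based node indices whose voltage is traced.
#' @param probe_every probe sampling interval, ms.
#' @param v_lag lag (ms) of the companion voltage field stored with each
#'   snapshot, used for phase embedding (default 2 ms).
#' @return A `pig_tissue_sim` list: `snap_times`, `snapshots` (list of
#'   nx x ny matrices), `snapshots_lag`, `probe_times`, `probe_v` (matrix,
#'   one column per probe), `states` (final state matrix), `nx`, `ny`, `dx`,
#'   `time` and `params`.
#' @export
run_tissue <- function(field, stimuli, duration, snapshot_every = 0,
                       probes = integer(0), probe_every = 0.5, v_lag = 2) {
  stopifnot(inherits(field, "tissue_field"))
  p <- field$params
  res <- cpp_simulate_tissue(field$states, p, field$nx, field$ny, field$dx,
                             field$D, stimuli, duration, p$dt,
                             snapshot_every, v_lag,
                             as.integer(probes) - 1L, probe_every,
                             isTRUE(p$rush_larsen), field$time)
  snaps <- purrr::map(res$snapshots, ~matrix(.x, field$nx, field$ny))
  snaps_lag <- purrr::map(res$snapshots_lag, ~matrix(.x, field$nx, field$ny))
  rownames(res$states) <- rownames(field$states)
  structure(list(snap_times = res$snap_times, snapshots = snaps,
                 snapshots_lag = snaps_lag,
                 probe_times = res$probe_times, probe_v = res$probe_v,
                 probes = as.integer(probes),
                 states = res$states, nx = field$nx, ny = field$ny,
                 dx = field$dx, time = res$time_end, params = p),
            class = "pig_tissue_sim")
}

#' @export
print.pig_tissue_sim <- function(x, ...) {
  cat(sprintf("<pig_tissue_sim> %d x %d nodes, t = %.6g ms, %d snapshots, %d probes\n",
              x$nx, x$ny, x$time, length(x$snapshots), length(x$probes)))
  invisible(x)
}

# updated field carrying the final states of a simulation
advance_field <- function(field, sim) {
  field$states <- sim$states
  field$time <- sim$time
  field
}

#' One FTCS step of the tissue field
#'
#' Convenience wrapper advancing the field by a single time step `dt`
#' (the parameter set's `dt`); mainly useful for stencil-level verification.
#'
#' @inheritParams run_tissue
#' @return The advanced `tissue_field`.
#' @export
step_tissue <- function(field, stimuli = list()) {
  sim <- run_tissue(field, stimuli, duration = field$params$dt)
  advance_field(field, sim)
}

#' Paced cable simulation
#'
#' Stimulates the left end of a 1D cable with a pacing train and records
#' voltage at probe positions, for conduction-velocity and wavelength
#' measurement.
#'
#' @param length_cm cable length, cm.
#' @param params a [pig_params()] object.
#' @param stim_times stimulus onset times, ms.
#' @param probe_pos_cm probe positions along the cable, cm.
#' @param duration total simulated time, ms (default covers the last beat).
#' @param state per-cell initial state.
#' @param probe_every probe sampling interval, ms.
#' @return A `pig_tissue_sim` with attribute `probe_pos_cm`.
#' @export
simulate_cable <- function(length_cm, params = pig_params(),
                           stim_times = 0, probe_pos_cm,
                           duration = max(stim_times) + 600,
                           state = pig_resting_state(params),
                           probe_every = 0.2) {
  field <- cable_field(length_cm, params, state)
  probes <- pmin(pmax(as.integer(round(probe_pos_cm / params$dx)) + 1L, 1L),
                 field$nx)
  stims <- purrr::map(stim_times, function(t0)
    stim_left_edge(field, stim_density(params), t0, params$stim_duration))
  sim <- run_tissue(field, stims, duration, probes = probes,
                    probe_every = probe_every)
  attr(sim, "probe_pos_cm") <- (probes - 1L) * params$dx
  attr(sim, "stim_times") <- stim_times
  sim
}

# upward threshold crossings (linearly interpolated times)
upcross_times <- function(t, v, level) {
  i <- which(v[-1] >= level & v[-length(v)] < level)
  t[i] + (level - v[i]) * (t[i + 1] - t[i]) / (v[i + 1] - v[i])
}
downcross_times <- function(t, v, level) {
  i <- which(v[-1] < level & v[-length(v)] >= level)
  t[i] + (level - v[i]) * (t[i + 1] - t[i]) / (v[i + 1] - v[i])
}

#' Conduction velocity from probe traces
#'
#' CV = probe separation / difference of wavefront arrival times, the
#' arrival being the upstroke crossing of the tip-tracking threshold
#' (-35 mV by default).
#'
#' @param sim a [simulate_cable()] result (or any `pig_tissue_sim` with at
#'   least two probes and `probe_pos_cm` attached).
#' @param beat which paced beat to measure (default the last complete one).
#' @param threshold front-detection threshold, mV.
#' @return CV in cm/s.
#' @export
measure_cv <- function(sim, beat = NULL, threshold = -35) {
  pos <- attr(sim, "probe_pos_cm")
  if (is.null(pos) || length(pos) < 2)
    abort("measure_cv needs two probes with known positions")
  arr <- purrr::map(seq_along(pos), function(q)
    upcross_times(sim$probe_times, sim$probe_v[, q], threshold))
  nb <- min(lengths(arr))
  if (nb == 0) abort("no wavefront crossing detected at a probe")
  if (is.null(beat)) beat <- nb
  if (beat > nb) abort("requested beat not observed at all probes")
  t1 <- arr[[1]][beat]; t2 <- arr[[length(pos)]][beat]
  dxp <- pos[length(pos)] - pos[1]
  1000 * dxp / (t2 - t1)
}

#' Wavelength from a probe trace
#'
#' WL = (time at which the waveback repolarises through -40 mV minus the
#' wavefront arrival time) x CV, evaluated at one probe.
#'
#' @param sim a [simulate_cable()] result.
#' @param cv conduction velocity in cm/s (e.g. from [measure_cv()]).
#' @param probe which probe to use (index into the probe list).
#' @param beat which paced beat (default the last complete one).
#' @param front_threshold wavefront threshold, mV (-35).
#' @param back_threshold waveback repolarisation threshold, mV (-40).
#' @return Wavelength in cm.
#' @export
measure_wavelength <- function(sim, cv, probe = 1, beat = NULL,
                               front_threshold = -35, back_threshold = -40) {
  t <- sim$probe_times; v <- sim$probe_v[, probe]
  fronts <- upcross_times(t, v, front_threshold)
  if (length(fronts) == 0) abort("no wavefront at the probe")
  if (is.null(beat)) beat <- length(fronts)
  t_front <- fronts[beat]
  backs <- downcross_times(t, v, back_threshold)
  backs <- backs[backs > t_front]
  if (length(backs) == 0) abort("waveback never repolarises through -40 mV")
  (backs[1] - t_front) * cv / 1000
}

#' S1-S2 cross-field spiral initiation
#'
#' Runs the cross-field protocol in a square sheet: a line stimulus (S1)
#' along the left edge launches a plane wave; when the S1 waveback (the
#' -40 mV repolarisation) has crossed the domain midline, a second stimulus
#' (S2) is applied over the lower half `y <= ny/2`, into the recovering
#' tail, creating a free wave end that curls into a spiral.
#'
#' @param params a [pig_params()] object.
#' @param nx side length in nodes (square domain); the physical side is
#'   `nx * dx` cm (512 nodes at 0.022 cm = 11.26 cm).
#' @param duration_after_s2 simulated time after S2, ms.
#' @param snapshot_every snapshot cadence, ms (default 10, the tip-tracking
#'   cadence).
#' @param s2_delay `"auto"` (waveback-triggered, default) or a fixed delay in
#'   ms after S1.
#' @param poll_every trigger-polling interval, ms.
#' @param state per-cell initial state.
#' @return A `pig_tissue_sim` spanning the whole protocol, with attributes
#'   `s2_time` (ms) and `spiral_formed` (logical; `FALSE` flags the outcome
#'   where S2 fails to induce reentry).
#' @export
s1s2_crossfield <- function(params = pig_params(), nx = 512,
                            duration_after_s2 = 1000, snapshot_every = 10,
                            s2_delay = "auto", poll_every = snapshot_every,
                            state = pig_resting_state(params)) {
  if (nx < 16) abort("domain too small for the cross-field protocol")
  field <- tissue_field(nx, nx, params, state)
  amp <- stim_density(params)
  s1 <- stim_left_edge(field, amp, 0, params$stim_duration)

  mid_col <- as.integer(nx %/% 2)
  mid_idx <- mid_col + 1L + (seq_len(nx) - 1L) * nx # node column at x ~ mid

  sims <- list()
  if (identical(s2_delay, "auto")) {
    # run in short chunks until the S1 waveback has crossed the midline
    excited <- FALSE
    t_max <- 4000
    repeat {
      sim <- run_tissue(field, list(s1), poll_every,
                        snapshot_every = snapshot_every)
      sims[[length(sims) + 1]] <- sim
      field <- advance_field(field, sim)
      vmid <- field$states["v", mid_idx]
      if (!excited && any(vmid > -35)) excited <- TRUE
      if (excited && all(vmid < -40)) break
      if (field$time > t_max)
        abort("S1 waveback never crossed the midline (no propagation?)")
    }
    s2_time <- field$time
  } else {
    s2_time <- as.numeric(s2_delay)
    sim <- run_tissue(field, list(s1), s2_time,
                      snapshot_every = snapshot_every)
    sims[[length(sims) + 1]] <- sim
    field <- advance_field(field, sim)
  }

  s2 <- stim_lower_half(field, amp, s2_time, params$stim_duration)
  sim <- run_tissue(field, list(s2), duration_after_s2,
                    snapshot_every = snapshot_every)
  sims[[length(sims) + 1]] <- sim

  out <- sims[[length(sims)]]
  out$snap_times <- unlist(purrr::map(sims, "snap_times"))
  out$snapshots <- purrr::flatten(purrr::map(sims, "snapshots"))
  out$snapshots_lag <- purrr::flatten(purrr::map(sims, "snapshots_lag"))
  # drop duplicated chunk-boundary frames
  keep <- !duplicated(out$snap_times)
  out$snap_times <- out$snap_times[keep]
  out$snapshots <- out$snapshots[keep]
  out$snapshots_lag <- out$snapshots_lag[keep]
  attr(out, "s2_time") <- s2_time
  ps <- tryCatch(count_phase_singularities(out), error = function(e) NULL)
  attr(out, "spiral_formed") <-
    !is.null(ps) && nrow(ps) > 0 && any(tail(ps$n_ps, 3) > 0)
  out
}
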