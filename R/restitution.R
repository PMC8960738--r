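#' Pacing restitution of AP features
#'
#' Paces the cell at each frequency, discards the conditioning beats and
#' averages the AP features over the last `last` beats (mirroring the
#' 10-consecutive-AP averaging of the characterisation experiments). Peak
#' I_ClCa magnitude and peak myoplasmic Ca2+ flux per beat are also
#' recorded, for the early-repolarisation restitution analysis.
#'
#' A frequency where any measured beat fails 1:1 capture is flagged
#' (`captured = FALSE`) and its averaged features are `NA`.
#'
#' @param params a [pig_params()] object.
#' @param frequencies pacing frequencies, Hz (default the experimental set
#'   0.25, 0.5, 1, 2, 3, 4 Hz).
#' @param n_beats total beats per frequency (conditioning + measured).
#' @param last number of final beats measured and averaged.
#' @param state starting state; defaults to the cell adapted to 1 Hz pacing
#'   ([paced_state()]), like a preparation at steady-state activity.
#' @return A tibble of class `pig_restitution`: one row per frequency with
#'   `frequency`, `cl`, `captured`, averaged `rmp`, `apa`, `dvdt_max`,
#'   `apd_10` .. `apd_90`, `peak_iclca` (pA/pF) and `peak_ca_flux` (the peak
#'   F_n). Per-beat features are attached as attribute `beats`.
#' @export
run_restitution <- function(params = pig_params(),
                            frequencies = c(0.25, 0.5, 1, 2, 3, 4),
                            n_beats = 20, last = 10,
                            state = paced_state(params)) {
  if (last >= n_beats) abort("n_beats must exceed last")
  state <- validate_state(state)
  beats_all <- list()
  rows <- purrr::map_dfr(frequencies, function(f) {
    cl <- 1000 / f
    n1 <- n_beats - last
    cond <- simulate_cell(params, duration = n1 * cl + 10,
                          stim_times = stim_train(n1, cl, start = 10),
                          state = state, record_every = n1 * cl + 10,
                          currents = FALSE)
    meas <- simulate_cell(params, duration = last * cl,
                          stim_times = stim_train(last, cl, start = 0),
                          state = attr(cond, "final_state"),
                          record_every = 0.25, currents = TRUE)
    feats <- extract_ap_features(meas)
    feats$frequency <- f
    # per-beat peak |I_ClCa| and peak Ca2+ flux
    peaks <- purrr::map_dfr(seq_len(last), function(b) {
      t0 <- (b - 1) * cl; t1 <- b * cl
      w <- meas$time >= t0 & meas$time < t1
      tibble(beat = b,
             peak_iclca = max(abs(meas$i_clca[w])),
             peak_ca_flux = max(meas$f_n[w]))
    })
    feats <- left_join(feats, peaks, by = "beat")
    beats_all[[as.character(f)]] <<- feats
    cap <- all(feats$captured)
    avg <- function(x) if (cap) mean(x) else NA_real_
    tibble(frequency = f, cl = cl, captured = cap,
           rmp = avg(feats$rmp), apa = avg(feats$apa),
           dvdt_max = avg(feats$dvdt_max),
           !!!setNames(lapply(paste0("apd_", seq(10, 90, 10)),
                              function(cn) avg(feats[[cn]])),
                       paste0("apd_", seq(10, 90, 10))),
           peak_iclca = avg(feats$peak_iclca),
           peak_ca_flux = avg(feats$peak_ca_flux))
  })
  structure(rows, beats = dplyr::bind_rows(beats_all),
            class = c("pig_restitution", class(rows)))
}

#' Effective refractory period by S1-S2 bisection
#'
#' Conditions the cell (or a short cable) with `s1_count` stimuli at
#' `s1_cl`, then bisects the S1-S2 coupling interval to `resolution` ms.
#' The ERP is the shortest coupling interval whose S2 still evokes a full
#' response (cell mode: APA above `capture_threshold`; cable mode: a
#' propagated upstroke through -35 mV at a distal probe).
#'
#' @param params a [pig_params()] object.
#' @param s1_count number of conditioning stimuli (>= 5).
#' @param s1_cl conditioning cycle length, ms.
#' @param mode `"cell"` (0D, default) or `"cable"`.
#' @param bounds search interval for the coupling interval, ms.
#' @param resolution bisection resolution, ms.
#' @param capture_threshold APA threshold (mV) defining a full AP.
#' @param cable_length_cm cable length for `mode = "cable"`.
#' @param state starting state before S1 conditioning; the default is the
#'   cell adapted to pacing at `s1_cl` (see [paced_state()]), mirroring a
#'   preparation measured after reaching steady-state activity.
#' @return The ERP in ms (scalar).
#' @export
measure_erp <- function(params = pig_params(), s1_count = 8, s1_cl = 1000,
                        mode = c("cell", "cable"), bounds = c(120, 500),
                        resolution = 1, capture_threshold = 60,
                        cable_length_cm = 1,
                        state = paced_state(params, cl = s1_cl)) {
  mode <- match.arg(mode)
  if (s1_count < 5) abort("s1_count must be at least 5 for conditioning")
  lo <- bounds[1]; hi <- bounds[2]
  if (mode == "cell") {
    cond <- simulate_cell(params, duration = (s1_count - 1) * s1_cl,
                          stim_times = stim_train(s1_count - 1, s1_cl, 0),
                          state = state,
                          record_every = (s1_count - 1) * s1_cl)
    s0 <- attr(cond, "final_state")
    trial <- function(ci) {
      sim <- simulate_cell(params, duration = ci + 450,
                           stim_times = c(0, ci), state = s0,
                           record_every = 0.2)
      f <- extract_ap_features(sim, stim_times = c(0, ci),
                               capture_threshold = capture_threshold)
      isTRUE(f$captured[2])
    }
  } else {
    field <- cable_field(cable_length_cm, params,
                         state = validate_state(state))
    stim <- stim_left_edge(field, stim_density(params), 0,
                           params$stim_duration)
    probe <- field$nx - 3L
    cond <- run_tissue(field, stimuli = purrr::map(
      stim_train(s1_count - 1, s1_cl, 0),
      function(t0) modifyList(stim, list(start = t0))),
      duration = (s1_count - 1) * s1_cl, probes = probe)
    s0 <- cond$states
    trial <- function(ci) {
      f2 <- field; f2$states <- s0
      sim <- run_tissue(f2, stimuli = list(
        modifyList(stim, list(start = 0)),
        modifyList(stim, list(start = ci))),
        duration = ci + 250, probes = probe, probe_every = 0.2)
      # capture = a new propagated upstroke at the distal probe after S2
      up <- upcross_times(sim$probe_times, sim$probe_v[, 1], -35)
      any(up > ci)
    }
  }
  if (trial(lo)) return(lo)
  if (!trial(hi)) abort("S2 fails to capture even at the upper bound")
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (trial(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Shortest sustained 1:1 pacing cycle length of a cable
#'
#' Up-titrates the pacing cycle length from `cl_start` in steps of
#' `cl_step` until a train of `n_beats` stimuli all propagate (1:1 capture
#' at a distal probe), and returns that cycle length with the simulation.
#' Pacing below the tissue's refractory period produces 2:1 block, so the
#' first sustaining cycle length is the high-rate end of the wavelength
#' restitution curve.
#'
#' @param params a [pig_params()] object.
#' @param length_cm cable length, cm.
#' @param cl_start first cycle length tried, ms.
#' @param cl_step titration step, ms.
#' @param n_beats beats per train.
#' @param probe_pos_cm probes for CV/WL measurement.
#' @param state starting state (default: adapted to 1 Hz pacing).
#' @return A list with `cl` (ms) and `sim` (the sustaining run).
#' @export
shortest_sustained_cl <- function(params = pig_params(), length_cm = 10,
                                  cl_start = 200, cl_step = 10,
                                  n_beats = 10, probe_pos_cm = c(4, 6),
                                  state = paced_state(params)) {
  cl <- cl_start
  repeat {
    sim <- simulate_cable(length_cm, params,
                          stim_times = stim_train(n_beats, cl, 0),
                          probe_pos_cm = probe_pos_cm,
                          duration = n_beats * cl + 450, state = state)
    up <- upcross_times(sim$probe_times, sim$probe_v[, 1], -35)
    if (length(up) == n_beats) return(list(cl = cl, sim = sim))
    cl <- cl + cl_step
    if (cl > 1000) abort("no sustained 1:1 capture found below CL 1000 ms")
  }
}
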