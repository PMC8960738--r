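.trace_current_cols <- c("i_na", "i_k1", "i_clca", "i_kur", "i_kr", "i_ks",
                         "i_cal", "i_pca", "i_nak", "i_naca", "i_bna", "i_bca",
                         "i_ion", "i_up", "i_rel", "i_tr", "i_up_leak", "f_n")
.trace_state_cols <- c("cai", "caup", "carel", "nai", "ki", "qca", "fca")

#' Stimulus train times
#'
#' Regularly spaced stimulus onset times, the usual pacing protocol input for
#' [simulate_cell()].
#'
#' @param n number of stimuli.
#' @param cl cycle length, ms (for frequency f in Hz, `cl = 1000 / f`).
#' @param start onset of the first stimulus, ms.
#' @return Numeric vector of onset times (ms).
#' @export
stim_train <- function(n, cl, start = 10) start + (seq_len(n) - 1) * cl

#' Simulate a single pig atrial cell
#'
#' Advances the full cell state by forward Euler at `dt` (optionally
#' Rush-Larsen for the Hodgkin-Huxley gates), applying square stimulus pulses
#' at the given onset times. The default isolated-cell stimulus is the
#' experimental-style 1 ms pulse at ~30% above threshold
#' (`params$stim_cell_amp`, `params$stim_cell_duration`); the stronger 7 nA,
#' 4 ms tissue pulse is only meaningful under a diffusive load and is used by
#' the tissue solver.
#'
#' @param params a [pig_params()] object; `params$dt`, `params$stim_na`,
#'   `params$stim_duration` and `params$rush_larsen` are honoured.
#' @param duration total simulated time, ms.
#' @param stim_times stimulus onset times, ms (e.g. [stim_train()]).
#' @param state starting state; defaults to the packaged resting state.
#' @param record_every trace sampling interval, ms.
#' @param currents if `TRUE`, record all currents, SR fluxes and F_n.
#' @param stim_amplitude stimulus density in pA/pF (positive = depolarising).
#' @param stim_duration stimulus pulse duration, ms.
#' @return A tibble of class `pig_cell_sim` with columns `time`, `v`, the
#'   Ca2+/ionic state columns, and (if requested) all currents. The final
#'   state, parameters and stimulus times are attached as attributes
#'   `final_state`, `params`, `stim_times`.
#' @examples
#' \donttest{
#' sim <- simulate_cell(pig_params(), duration = 600, stim_times = 10)
#' extract_ap_features(sim)
#' }
#' @export
simulate_cell <- function(params = pig_params(), duration = 1000,
                          stim_times = numeric(0),
                          state = pig_resting_state(params),
                          record_every = 0.1, currents = FALSE,
                          stim_amplitude = params$stim_cell_amp,
                          stim_duration = params$stim_cell_duration) {
  validate_params(params)
  state <- validate_state(state)
  if (duration <= 0) abort("duration must be positive")
  if (params$dt <= 0 || params$dt > 0.05)
    abort("dt must lie in (0, 0.05] ms")
  res <- cpp_simulate_cell(state, params, duration, as.numeric(stim_times),
                           stim_duration, stim_amplitude, params$dt,
                           record_every, currents,
                           isTRUE(params$rush_larsen), t0 = 0)
  cols <- c("time", "v", if (currents) .trace_current_cols, .trace_state_cols)
  tr <- as_tibble(as.data.frame(res$trace))
  names(tr) <- cols
  structure(tr,
            final_state = res$final_state,
            params = params,
            stim_times = as.numeric(stim_times),
            class = c("pig_cell_sim", class(tr)))
}

#' Advance one cell state by a single time step
#'
#' One forward-Euler (or Rush-Larsen) step of the full state under a constant
#' stimulus density, returning the new state. Useful for stepping-level tests
#' and custom integration loops; for whole protocols use [simulate_cell()].
#'
#' @param state named numeric cell state.
#' @param params a [pig_params()] object.
#' @param i_stim stimulus density, pA/pF (positive = depolarising).
#' @param dt time step, ms, in (0, 0.05].
#' @return The advanced named state vector.
#' @export
step_cell <- function(state, params = pig_params(), i_stim = 0,
                      dt = params$dt) {
  if (dt <= 0 || dt > 0.05) abort("dt must lie in (0, 0.05] ms")
  state <- validate_state(state)
  res <- cpp_simulate_cell(state, params, dt, if (i_stim != 0) 0 else numeric(0),
                           dt, i_stim, dt, record_every = dt,
                           record_currents = FALSE,
                           rush_larsen = isTRUE(params$rush_larsen), t0 = 0)
  res$final_state
}

#' @export
print.pig_cell_sim <- function(x, ...) {
  cat(sprintf("<pig_cell_sim> %.6g ms, %d samples, %d stimuli\n",
              max(x$time), nrow(x), length(attr(x, "stim_times"))))
  NextMethod()
}
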