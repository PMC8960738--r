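#' Voltage-clamp protocol description
#'
#' Defines a simulated patch-clamp experiment: the membrane is held at
#' `holding_potential`, stepped to each test potential in turn, and one
#' chosen current is measured. Between test pulses the cell re-equilibrates
#' at the holding potential (each pulse starts from the same conditioned
#' state, i.e. an effectively long interpulse interval).
#'
#' @param measured_current one of the model's current names (e.g. `"i_cal"`,
#'   `"i_clca"`, `"i_kur"`, `"i_kr"`, `"i_ks"`, `"i_na"`).
#' @param holding_potential holding potential, mV.
#' @param test_potentials strictly increasing test potentials, mV.
#' @param step_duration duration of the test step, ms.
#' @param interpulse_interval equilibration time at holding potential before
#'   each pulse, ms.
#' @param measurement_rule `"peak"` (value of largest magnitude during the
#'   step) or `"steady"` (value at the end of the step).
#' @param cai_clamp optional fixed intracellular Ca2+ (mM) during the whole
#'   protocol (e.g. 1e-4 for the L-type characterisation); `NA` leaves Ca2+
#'   dynamics free.
#' @return A `clamp_protocol` object.
#' @export
clamp_protocol <- function(measured_current,
                           holding_potential = -80,
                           test_potentials = seq(-40, 60, by = 5),
                           step_duration = 300,
                           interpulse_interval = 1000,
                           measurement_rule = c("peak", "steady"),
                           cai_clamp = NA_real_) {
  measurement_rule <- match.arg(measurement_rule)
  if (step_duration <= 0) abort("step_duration must be positive")
  if (length(test_potentials) == 0 || is.unsorted(test_potentials, strictly = TRUE))
    abort("test_potentials must be non-empty and strictly increasing")
  structure(list(measured_current = measured_current,
                 holding_potential = holding_potential,
                 test_potentials = as.numeric(test_potentials),
                 step_duration = step_duration,
                 interpulse_interval = interpulse_interval,
                 measurement_rule = measurement_rule,
                 cai_clamp = cai_clamp),
            class = "clamp_protocol")
}

#' Run a simulated voltage clamp and return the IV curve
#'
#' Holds the membrane potential on the protocol's schedule while gates and
#' Ca2+ dynamics evolve freely, and measures the selected current at each
#' test potential according to the protocol's measurement rule.
#'
#' @param protocol a [clamp_protocol()] object.
#' @param params a [pig_params()] object.
#' @param state starting state (defaults to the packaged resting state).
#' @param record_every current-trace sampling, ms.
#' @return A tibble of class `pig_iv_curve` with columns `v_test`, `current`
#'   (pA/pF) and `t_peak` (ms after step onset); the per-step traces are
#'   attached as attribute `traces` (list of tibbles).
#' @examples
#' \donttest{
#' iv <- run_voltage_clamp(
#'   clamp_protocol("i_cal", cai_clamp = 1e-4), pig_params())
#' max(abs(iv$current))
#' }
#' @export
run_voltage_clamp <- function(protocol, params = pig_params(),
                              state = pig_resting_state(params),
                              record_every = 0.5) {
  stopifnot(inherits(protocol, "clamp_protocol"))
  cur <- protocol$measured_current
  valid <- c(.current_names, "i_ion", "i_rel", "i_up", "f_n")
  if (!cur %in% valid)
    abort(paste0("unknown measured_current '", cur, "'"))
  state <- validate_state(state)
  cai <- if (is.na(protocol$cai_clamp)) -1 else protocol$cai_clamp

  cols <- c("time", "v", .trace_current_cols, .trace_state_cols)
  traces <- purrr::map(protocol$test_potentials, function(vt) {
    res <- cpp_voltage_clamp(state, params, protocol$holding_potential, vt,
                             protocol$interpulse_interval,
                             protocol$step_duration, params$dt, record_every,
                             cai, isTRUE(params$rush_larsen))
    tr <- as_tibble(as.data.frame(res$trace))
    names(tr) <- cols
    tr
  })
  iv <- purrr::map2_dfr(protocol$test_potentials, traces, function(vt, tr) {
    y <- tr[[cur]]
    if (protocol$measurement_rule == "peak") {
      i <- which.max(abs(y))
      tibble(v_test = vt, current = y[i], t_peak = tr$time[i])
    } else {
      tibble(v_test = vt, current = y[length(y)],
             t_peak = tr$time[length(y)])
    }
  })
  structure(iv, traces = traces, protocol = protocol,
            class = c("pig_iv_curve", class(iv)))
}
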