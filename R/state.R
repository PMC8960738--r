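.state_names <- c("v", "m", "h", "j", "d", "f", "fca", "ua", "uif", "uis",
                  "xr", "xs", "qca", "u", "v_rel", "w",
                  "nai", "ki", "cai", "caup", "carel")

.gate_names <- c("m", "h", "j", "d", "f", "fca", "ua", "uif", "uis",
                 "xr", "xs", "qca", "u", "v_rel", "w")

#' Initial cell state (source-model resting values)
#'
#' The 21-variable dynamical state of one cell, initialised at the resting
#' values of the CRN source model (the pig-specific equilibrium is obtained
#' from these by unstimulated relaxation; see [pig_resting_state()]).
#' Variables: membrane potential `v` (mV); Hodgkin-Huxley gates `m,h,j`
#' (I_Na), `d,f,fca` (I_CaL), `ua,uif,uis` (I_Kur), `xr` (I_Kr), `xs` (I_Ks),
#' `qca` (I_ClCa); SR release gates `u`, `v_rel`, `w`; intracellular
#' concentrations `nai,ki,cai` and SR compartments `caup,carel` (mM).
#'
#' @return A named numeric vector of length 21.
#' @export
pig_initial_state <- function() {
  setNames(c(
    -81.18,     # v
    0.002908,   # m
    0.9649,     # h
    0.9775,     # j
    1.367e-4,   # d
    0.9996,     # f
    0.7755,     # fca
    0.03043,    # ua
    0.9992,     # uif
    0.9992,     # uis
    3.296e-5,   # xr
    0.01869,    # xs
    0,          # qca
    0,          # u
    1,          # v_rel
    0.9992,     # w
    11.17,      # nai
    139.0,      # ki
    1.013e-4,   # cai
    1.488,      # caup
    1.488       # carel
  ), .state_names)
}

#' Equilibrated resting state of the pig atrial cell
#'
#' The packaged quiescent steady state: the initial state relaxed without
#' stimulation under default parameters. The packaged copy (300 s of
#' relaxation, after which every Ca2+ compartment drifts by less than 1% per
#' 10 s) is read from `inst/extdata`; with `recompute = TRUE`, or for
#' non-default parameters, it is recomputed by running the model.
#'
#' @param params a [pig_params()] object (default parameters use the cached
#'   copy).
#' @param recompute force recomputation by unstimulated relaxation.
#' @param duration relaxation time in ms when recomputing (default 300000).
#' @return A named numeric state vector (see [pig_initial_state()]).
#' @export
pig_resting_state <- function(params = pig_params(), recompute = FALSE,
                              duration = 300000) {
  default <- identical(unclass(params), unclass(pig_params()))
  if (default && !recompute) {
    f <- system.file("extdata", "resting_state.csv", package = "pigatria")
    if (nzchar(f)) {
      d <- read.csv(f, stringsAsFactors = FALSE)
      s <- setNames(d$value, d$variable)
      if (identical(names(s), .state_names)) return(s)
    }
  }
  equilibrate_state(params, duration = duration)
}

#' Relax a cell state to quiescence
#'
#' Runs the cell unstimulated for `duration` ms and returns the final state.
#'
#' @param params a [pig_params()] object.
#' @param state starting state (default [pig_initial_state()]).
#' @param duration relaxation time, ms.
#' @return A named numeric state vector.
#' @export
equilibrate_state <- function(params = pig_params(),
                              state = pig_initial_state(),
                              duration = 300000) {
  sim <- cpp_simulate_cell(validate_state(state), params, duration,
                           numeric(0), 0, 0, params$dt,
                           record_every = duration, record_currents = FALSE,
                           rush_larsen = isTRUE(params$rush_larsen), t0 = 0)
  sim$final_state
}

#' Validate a cell state
#'
#' Checks the state invariants: all 21 variables present and finite, gating
#' variables in \[0, 1\], concentrations strictly positive, and membrane
#' potential within the physiologically meaningful band \[-150, 100\] mV.
#'
#' @param state named numeric state vector.
#' @return `state` (invisibly reordered to the canonical layout) if valid.
#' @export
validate_state <- function(state) {
  if (!all(.state_names %in% names(state)))
    abort(paste0("state is missing variable(s): ",
                 paste(setdiff(.state_names, names(state)), collapse = ", ")))
  state <- state[.state_names]
  if (any(!is.finite(state))) abort("state contains non-finite values")
  g <- state[.gate_names]
  if (any(g < 0 | g > 1))
    abort(paste0("gating variable out of [0,1]: ",
                 paste(.gate_names[g < 0 | g > 1], collapse = ", ")))
  conc <- state[c("nai", "ki", "cai", "caup", "carel")]
  if (any(conc <= 0)) abort("all concentrations must be strictly positive")
  if (state["v"] < -150 || state["v"] > 100)
    abort("membrane potential outside [-150, 100] mV")
  state
}

#' Buffer occupancies implied by a state
#'
#' The rapid-buffering approximation makes calmodulin- and troponin-bound
#' Ca2+ in the myoplasm and calsequestrin-bound Ca2+ in the junctional SR
#' instantaneous functions of the free concentrations; this returns them (mM).
#'
#' @param state named numeric state vector.
#' @return A tibble with columns `ca_cmdn`, `ca_trpn`, `ca_csqn`.
#' @export
buffer_occupancies <- function(state) {
  state <- validate_state(state)
  tibble(
    ca_cmdn = 0.05 * state[["cai"]] / (state[["cai"]] + 0.00238),
    ca_trpn = 0.07 * state[["cai"]] / (state[["cai"]] + 0.0005),
    ca_csqn = 10 * state[["carel"]] / (state[["carel"]] + 0.8)
  )
}

# total Ca2+ content (amount per myoplasmic volume, mM) across myoplasm,
# buffers and SR compartments; conserved when transmembrane Ca2+ flux is zero
total_calcium <- function(state) {
  b <- buffer_occupancies(state)
  v_i <- 13668; v_up <- 1109.52; v_rel <- 96.48
  (v_i * (state[["cai"]] + b$ca_cmdn + b$ca_trpn) +
     v_up * state[["caup"]] +
     v_rel * (state[["carel"]] + b$ca_csqn)) / v_i
}
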