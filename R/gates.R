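.voltage_gates <- c("m", "h", "j", "d", "f", "ua", "uif", "uis",
                    "xr", "xs", "w")

#' Steady state and time constant of a gating variable
#'
#' Evaluates the Hodgkin-Huxley kinetics of one gate of the model. Voltage
#' gates (`m,h,j,d,f,ua,uif,uis,xr,xs,w`) are functions of the membrane
#' potential; `fca` is a function of intracellular Ca2+ and `qca` of the net
#' myoplasmic Ca2+ flux F_n, both with a fixed 2 ms time constant.
#'
#' @param gate gate identifier (one of the names above).
#' @param v membrane potential(s), mV, for voltage gates.
#' @param cai intracellular Ca2+ (mM) for `fca`.
#' @param fn net myoplasmic Ca2+ flux (CRN convention) for `qca`.
#' @param params a [pig_params()] object.
#' @return A tibble with columns `gate`, the driving variable (`v`, `cai` or
#'   `fn`), `steady_state` and `tau` (ms).
#' @examples
#' gate_kinetics("xr", v = 4.4451)        # half-activation point
#' gate_kinetics("fca", cai = 0.00035)    # half-saturation
#' @export
gate_kinetics <- function(gate, v = NULL, cai = NULL, fn = NULL,
                          params = pig_params()) {
  gate <- match.arg(gate, c(.voltage_gates, "fca", "qca"))
  if (gate == "fca") {
    if (is.null(cai)) abort("gate 'fca' requires `cai`")
    if (any(cai < 0)) abort("cai must be non-negative")
    return(tibble(gate = gate, cai = cai,
                  steady_state = 1 / (1 + cai / params$fca_half),
                  tau = params$tau_fca))
  }
  if (gate == "qca") {
    if (is.null(fn)) abort("gate 'qca' requires `fn`")
    ss <- ifelse(fn <= 0, 0, 1 - 1 / (1 + (fn / params$qca_half)^3))
    return(tibble(gate = gate, fn = fn, steady_state = ss,
                  tau = params$tau_qca))
  }
  if (is.null(v)) abort("voltage gates require `v`")
  if (any(!is.finite(v))) abort("v must be finite")
  nm_inf <- switch(gate, uif = "ui_inf", uis = "ui_inf",
                   paste0(gate, "_inf"))
  nm_tau <- switch(gate, uif = "tau_uif", uis = "tau_uif",
                   paste0("tau_", gate))
  out <- purrr::map_dfr(v, function(vv) {
    r <- cpp_vrates(vv, params)
    tau <- r[[nm_tau]]
    if (gate == "uis") tau <- tau * params$kur_slow_tau_factor
    tibble(gate = gate, v = vv, steady_state = r[[nm_inf]], tau = tau)
  })
  out
}
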