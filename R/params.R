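#' Model parameters for the pig atrial cardiomyocyte
#'
#' Builds the full parameter set of the pig atrial ionic model. Defaults are
#' the fitted maximal conductances and pump/exchanger maxima of the published
#' parameterisation, together with the pig-specific kinetic constants (gating
#' time-constant scale factors, voltage shifts, rectification constants) and
#' the formulation constants inherited from the Courtemanche-Ramirez-Nattel
#' (CRN) human atrial model and the Luo-Rudy sarcoplasmic-reticulum Ca2+
#' subsystem. Any entry can be overridden by name.
#'
#' Units: conductances in nS/pF, maximal pump currents in pA/pF (the
#' Na+/Ca2+ exchanger maximum is the CRN-style scaling constant), membrane
#' capacitance in pF, concentrations in mM, potentials in mV, time constants
#' in ms, diffusion coefficient in cm^2/ms.
#'
#' @param ... named parameter overrides, e.g. `pig_params(g_kr = 0.25 * 0.0173)`.
#' @return An object of class `pig_params`: a named list of model parameters.
#' @examples
#' p <- pig_params()
#' p$g_na
#' # 75% block of the rapid delayed rectifier (spiral-breakup regime)
#' p_kr <- scale_params(pig_params(), g_kr = 0.25)
#' @export
pig_params <- function(...) {
  p <- list(
    # fitted maximal conductances (nS/pF) and pump maxima (pA/pF)
    g_k1       = 0.08218,
    g_na       = 13.99,
    g_kur_amp  = 0.45539,
    g_clca     = 0.15731,
    g_kr       = 0.0173,
    g_ks       = 0.0594,
    g_cal      = 0.06574,
    i_nak_max  = 0.94935,
    i_naca_max = 2304,
    # background and pump values retained from CRN
    g_bna      = 0.0006744375,
    g_bca      = 0.001131,
    i_pca_max  = 0.275,
    # SR Ca2+ subsystem (Luo-Rudy via CRN)
    i_up_max   = 0.005,
    k_up       = 0.00092,
    ca_up_max  = 15,
    k_rel      = 30,
    tau_tr     = 180,
    # membrane / milieu
    cm          = 100,
    temperature = 310.15,
    na_o        = 140,
    k_o         = 5.4,
    ca_o        = 1.8,
    cl_o        = 132,
    cl_i        = 29.26,
    e_cl        = NA_real_, # derived from cl_i/cl_o below unless overridden
    # pig-specific I_Na kinetics: slowed activation and inactivation
    tau_m_scale = 1.7,
    tau_h_scale = 2,
    tau_j_scale = 2,
    # I_Kur bi-exponential inactivation weights (a + b = 1)
    a_kur = 0.25,
    b_kur = 0.75,
    kur_slow_tau_factor = 20,
    # I_Kr: activation half-rise/slope and rectification term
    xr_half        = 4.4451,
    xr_slope       = 9.3305,
    ikr_rect_half  = 79.4825,
    ikr_rect_slope = 8.2217,
    # I_K1: +5 mV reversal offset, reduced slope, shifted half-rise
    ik1_shift = 5,
    ik1_slope = 0.063,
    ik1_vhalf = 70,
    # I_Ks activation constants
    p1 = 18.802,
    p2 = 12.6475,
    # I_CaL activation shift (mV, rightward)
    d_shift = 5,
    # I_rel voltage inactivation: CRN half 40 mV shifted +40, steepened
    w_half  = 80,
    w_slope = 8.5,
    # Ca-driven gates
    fca_half = 0.00035,
    qca_half = 1.1e-10,
    tau_fca  = 2,
    tau_qca  = 2,
    # tissue-level defaults
    D  = 0.00126,
    dx = 0.022,
    dt = 0.02,
    stim_na       = 7,  # tissue stimulus amplitude, nA
    stim_duration = 4,  # tissue stimulus duration, ms
    # isolated-cell stimulus: experimental-style 1 ms pulse ~30% above
    # the 1 ms threshold (the tissue pulse has no diffusive load in 0D)
    stim_cell_amp      = 40, # pA/pF
    stim_cell_duration = 1,  # ms
    # integration switches
    dynamic_concentrations = TRUE,
    rush_larsen = FALSE
  )
  over <- list(...)
  if (length(over) > 0) {
    if (is.null(names(over)) || any(names(over) == ""))
      abort("all parameter overrides must be named")
    unknown <- setdiff(names(over), names(p))
    if (length(unknown) > 0)
      abort(paste0("unknown model parameter(s): ", paste(unknown, collapse = ", ")))
    p[names(over)] <- over
  }
  if (is.na(p$e_cl))
    p$e_cl <- nernst_potential(-1, p$cl_i, p$cl_o, p$temperature)
  structure(p, class = "pig_params")
}

#' Scale selected maximal conductances
#'
#' Multiplies named conductances or maximal currents by the given factors;
#' used for channel-block experiments such as 75% block of `g_kr`
#' (spiral-wave breakup) or 50/90% block of `g_clca` (alternans replay).
#'
#' @param params a [pig_params()] object.
#' @param ... named scale factors, e.g. `g_kr = 0.25`.
#' @return A modified `pig_params` object.
#' @export
scale_params <- function(params, ...) {
  sc <- list(...)
  unknown <- setdiff(names(sc), names(params))
  if (length(unknown) > 0)
    abort(paste0("unknown model parameter(s): ", paste(unknown, collapse = ", ")))
  for (nm in names(sc)) params[[nm]] <- params[[nm]] * sc[[nm]]
  validate_params(params)
  params
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the parameter set: strictly positive
#' conductances and maxima, inactivation weights summing to one, and a
#' positive membrane capacitance and temperature.
#'
#' @param params a [pig_params()] object.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  pos <- c("g_k1", "g_na", "g_kur_amp", "g_clca", "g_kr", "g_ks", "g_cal",
           "g_bna", "g_bca", "i_nak_max", "i_naca_max", "i_pca_max",
           "i_up_max", "k_rel", "cm", "temperature", "na_o", "k_o", "ca_o",
           "D", "dx", "dt")
  for (nm in pos)
    if (!is.numeric(params[[nm]]) || params[[nm]] <= 0)
      abort(paste0("parameter '", nm, "' must be strictly positive"))
  if (abs(params$a_kur + params$b_kur - 1) > .Machine$double.eps * 4)
    abort("I_Kur inactivation weights must satisfy a + b = 1")
  invisible(params)
}

#' @export
print.pig_params <- function(x, ...) {
  cat("<pig_params> pig atrial ionic model parameters\n")
  cat(sprintf("  g_Na %.4g  g_K1 %.4g  g_CaL %.4g  g_Kr %.4g  g_Ks %.4g nS/pF\n",
              x$g_na, x$g_k1, x$g_cal, x$g_kr, x$g_ks))
  cat(sprintf("  g_Kur,amp %.4g  g_ClCa %.4g nS/pF; I_NaK,max %.4g pA/pF; I_NaCa,max %.4g\n",
              x$g_kur_amp, x$g_clca, x$i_nak_max, x$i_naca_max))
  cat(sprintf("  Cm %.4g pF, T %.5g K, D %.4g cm^2/ms, dx %.3g cm, dt %.3g ms\n",
              x$cm, x$temperature, x$D, x$dx, x$dt))
  invisible(x)
}

# stimulus amplitude in pA/pF given the nA value and Cm
stim_density <- function(params) 1000 * params$stim_na / params$cm
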