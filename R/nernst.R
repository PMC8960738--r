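#' Nernst equilibrium potential
#'
#' Reversal potential of an ion across the membrane,
#' \eqn{E = (RT / zF)\,\ln([X]_o/[X]_i)}, in mV.
#'
#' @param valence integer ionic valence (non-zero); e.g. +1 for K+, +2 for
#'   Ca2+, -1 for Cl-.
#' @param conc_in,conc_out intracellular / extracellular concentration (mM),
#'   strictly positive.
#' @param temperature absolute temperature in K (default 310.15, i.e. 37 C).
#' @return The equilibrium potential in mV.
#' @examples
#' nernst_potential(1, 139, 5.4)   # E_K, approx -86.8 mV
#' @export
nernst_potential <- function(valence, conc_in, conc_out, temperature = 310.15) {
  if (any(conc_in <= 0) || any(conc_out <= 0))
    abort("concentrations must be strictly positive")
  if (any(valence == 0)) abort("valence must be non-zero")
  R <- 8.3143    # J mol^-1 K^-1
  F <- 96.4867   # C mmol^-1 (so that the result is in mV)
  (R * temperature / (valence * F)) * log(conc_out / conc_in)
}
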