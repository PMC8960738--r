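.current_names <- c("i_na", "i_k1", "i_clca", "i_kur", "i_kr", "i_ks",
                    "i_cal", "i_pca", "i_nak", "i_naca", "i_bna", "i_bca")

#' Evaluate all membrane currents and SR fluxes at one state
#'
#' Computes the 12 membrane current densities (pA/pF), their sum `i_ion`,
#' the SR Ca2+ fluxes (`i_up`, `i_rel`, `i_tr`, `i_up_leak`, mM/ms), the net
#' myoplasmic Ca2+ flux `f_n` and the reversal potentials, all evaluated at
#' the given state.
#'
#' @param state named numeric cell state (see [pig_initial_state()]).
#' @param params a [pig_params()] object.
#' @return A one-row tibble.
#' @export
compute_currents <- function(state, params = pig_params()) {
  state <- validate_state(state)
  v <- cpp_compute_currents(state, params)
  as_tibble(as.list(v))
}

#' Net myoplasmic Ca2+ flux and the I_ClCa gate target
#'
#' Computes F_n (the CRN-convention net flux of Ca2+ into the myoplasm,
#' dominated by SR release, with L-type and exchanger contributions) and the
#' corresponding steady state of the I_ClCa gate,
#' \eqn{q_{Ca,\infty} = 1 - 1/(1 + (F_n/1.1\times 10^{-10})^3)}, with its
#' fixed 2 ms time constant.
#'
#' @param state named numeric cell state.
#' @param params a [pig_params()] object.
#' @param currents optional precomputed result of [compute_currents()]; if
#'   supplied, `i_rel`, `i_cal` and `i_naca` are taken from it.
#' @return A one-row tibble with `f_n`, `qca_inf`, `tau_qca`.
#' @export
compute_fn_qca <- function(state, params = pig_params(), currents = NULL) {
  if (is.null(currents)) currents <- compute_currents(state, params)
  v_rel <- 96.48; fday <- 96.4867
  fn <- 1e-12 * v_rel * currents$i_rel -
    (5e-13 / fday) * (0.5 * currents$i_cal - 0.2 * currents$i_naca) * params$cm
  qca_inf <- if (fn <= 0) 0 else 1 - 1 / (1 + (fn / params$qca_half)^3)
  tibble(f_n = fn, qca_inf = qca_inf, tau_qca = params$tau_qca)
}
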