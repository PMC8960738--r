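#' Paced steady state of the cell
#'
#' The operating point of the model under sustained pacing. The slow
#' intracellular ion drift (minutes time scale) makes the quiescent
#' equilibrium a poor starting point for protocols that, like the
#' characterisation experiments, measure preparations "after reaching steady
#' state activity": this function paces the cell at the given cycle length
#' until the beat-to-beat state has adapted and returns the state at the
#' instant the next stimulus would fall.
#'
#' @param params a [pig_params()] object.
#' @param cl pacing cycle length, ms.
#' @param duration_s pacing time in seconds (default 200 s, after which the
#'   Na+ load has adapted to within a few percent of its asymptote).
#' @param state starting state.
#' @return A named numeric state vector.
#' @export
paced_state <- function(params = pig_params(), cl = 1000, duration_s = 200,
                        state = pig_resting_state(params)) {
  n <- max(1, floor(duration_s * 1000 / cl))
  sim <- simulate_cell(params, duration = n * cl,
                       stim_times = stim_train(n, cl, start = 0),
                       state = state, record_every = n * cl)
  attr(sim, "final_state")
}
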