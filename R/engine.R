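rule_code <- function(rule) {
  match(rule, c("additive", "multiplicative", "symmetric",
                "corticostriatal")) - 1L
}

#' Advance the plasticity engine over one cycle phase
#'
#' Simulates `n_bins` Euler steps of length `dt` with constant per-channel
#' input-rate multipliers (1 inside a spike-count window, `a_sel` or 0 during
#' silencing).  Within each bin the event order is: exponential decay,
#' presynaptic events, delivery of postsynaptic spikes whose synaptic delay
#' expires, dopamine release if scheduled, Euler weight step with clipping.
#' The compiled core uses R's RNG, so runs are reproducible under
#' [set.seed()].
#'
#' @param state A [synapse_state()] object.
#' @param n_bins Number of `dt` steps to simulate.
#' @param mult Numeric vector of rate multipliers, one per channel.
#' @param params A [sim_params()] object.
#' @param release_bin Bin (1-based) at which dopamine is released, or 0 for
#'   none.
#' @param release_amount Dopamine release amount `D_k`.
#' @return A list with the updated `state`, integer `post_counts` of
#'   postsynaptic spikes delivered per channel during the phase, and
#'   `D_integral`, the integral of the dopamine level over the phase (s).
#' @export
sim_phase <- function(state, n_bins, mult, params,
                      release_bin = 0L, release_amount = 0) {
  stopifnot(length(mult) == params$n_channels)
  res <- sim_phase_cpp(state$w, state$A_pre, state$A_post,
                       state$E_plus, state$E_minus, state$D, state$pending,
                       as.integer(n_bins), params$rates, as.numeric(mult),
                       params$dt, params$tau, params$tau_eli, params$tau_dop,
                       rule_code(params$rule), params$alpha, params$lambda,
                       as.integer(release_bin), release_amount)
  new_state <- state
  new_state$w <- res$w
  new_state$A_pre <- res$A_pre
  new_state$A_post <- res$A_post
  new_state$E_plus <- res$E_plus
  new_state$E_minus <- res$E_minus
  new_state$D <- res$D
  new_state$pending <- res$pending
  list(state = new_state, post_counts = res$post_counts,
       D_integral = res$D_integral)
}
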