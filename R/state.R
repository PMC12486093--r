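#' Synapse state
#'
#' Creates the full per-synapse state evolved by the plasticity engine:
#' weights `w`, spike traces `A_pre` and `A_post`, paired eligibility traces
#' `E_plus` (pre-before-post) and `E_minus` (post-before-pre), the global
#' dopamine level `D` (relative to baseline, so it may go negative), and a
#' small ring buffer of postsynaptic spikes already generated but not yet
#' delivered (in flight for the synaptic delay `epsilon`).
#'
#' Matrices are `n_inputs x n_channels`: action selection uses two channels,
#' value estimation one.
#'
#' @param params A [sim_params()] object.
#' @param w Optional initial weight matrix (or scalar, recycled); defaults to
#'   `params$w_init`.
#' @return An object of class `"dastdp_state"`.
#' @examples
#' st <- synapse_state(sim_params("value_estimation", "additive"))
#' st$w
#' @export
synapse_state <- function(params, w = NULL) {
  N <- params$n_inputs
  nch <- params$n_channels
  if (is.null(w)) w <- params$w_init
  w <- matrix(w, nrow = N, ncol = nch)
  if (any(w < 0 | w > 1)) stop("initial weights must lie in [0, 1]")
  delay_bins <- as.integer(round(params$epsilon / params$dt))
  st <- structure(list(
    w = w,
    A_pre = matrix(0, N, nch),
    A_post = numeric(nch),
    E_plus = matrix(0, N, nch),
    E_minus = matrix(0, N, nch),
    D = 0,
    pending = matrix(0L, delay_bins, nch)
  ), class = "dastdp_state")
  if (params$setting == "value_estimation") {
    # abstract action preference; p = plogis(beta * R_diff), so p_init = 0.5
    # corresponds to a zero preference difference
    st$R_diff <- stats::qlogis(params$p_init) / params$beta
    st$A_bar <- 1
  }
  st
}

#' @export
print.dastdp_state <- function(x, ...) {
  cat("<dastdp_state>\n  w:", format(as.vector(x$w), digits = 4),
      "\n  D:", format(x$D, digits = 4), "\n")
  invisible(x)
}

#' Exponential decay of traces, eligibility and dopamine
#'
#' Advances the decaying state variables by `delta_t` without any spike or
#' release events: spike traces decay with `tau`, eligibility traces with
#' `tau_eli`, dopamine with `tau_dop`.  Weights are unchanged.
#'
#' @param state A [synapse_state()] object.
#' @param delta_t Time interval (s), non-negative.
#' @param params A [sim_params()] object.
#' @return The decayed state.
#' @export
decay <- function(state, delta_t, params) {
  stopifnot(delta_t >= 0)
  state$A_pre <- state$A_pre * exp(-delta_t / params$tau)
  state$A_post <- state$A_post * exp(-delta_t / params$tau)
  state$E_plus <- state$E_plus * exp(-delta_t / params$tau_eli)
  state$E_minus <- state$E_minus * exp(-delta_t / params$tau_eli)
  state$D <- state$D * exp(-delta_t / params$tau_dop)
  state
}

#' Presynaptic spike event
#'
#' Applies the impulse of one presynaptic spike at input `i` of `channel`:
#' the presynaptic trace increments by one and the post-before-pre
#' eligibility trace picks up the current postsynaptic trace value.
#'
#' @param state A [synapse_state()] object.
#' @param i Input index in `1:n_inputs`.
#' @param channel Channel index.
#' @return The updated state.
#' @export
on_pre_spike <- function(state, i, channel = 1L) {
  if (i < 1 || i > nrow(state$w)) stop("synapse index out of range")
  state$E_minus[i, channel] <- state$E_minus[i, channel] +
    state$A_post[channel]
  state$A_pre[i, channel] <- state$A_pre[i, channel] + 1
  state
}

#' Postsynaptic spike event
#'
#' Applies the impulse of one postsynaptic spike in `channel`: the
#' postsynaptic trace increments by one and every pre-before-post eligibility
#' trace of that channel picks up its presynaptic trace value.
#'
#' @inheritParams on_pre_spike
#' @return The updated state.
#' @export
on_post_spike <- function(state, channel = 1L) {
  state$E_plus[, channel] <- state$E_plus[, channel] +
    state$A_pre[, channel]
  state$A_post[channel] <- state$A_post[channel] + 1
  state
}

#' Instantaneous dopamine release
#'
#' Adds the release amount `D_k` (a reward prediction error, possibly
#' negative) to the current dopamine level.
#'
#' @param state A [synapse_state()] object.
#' @param D_k Release amount.
#' @return The updated state.
#' @export
release_dopamine <- function(state, D_k) {
  state$D <- state$D + D_k
  state
}

#' Euler weight step with clipping
#'
#' Advances every weight by `delta_t * dw/dt` using [weight_derivative()] at
#' the pre-update weight, then clips to \[0, 1\].  Clipping after every step
#' is what produces the boundary accumulation points (clipped
#' pseudo-equilibria) seen in the task simulations.
#'
#' @param state A [synapse_state()] object.
#' @param delta_t Step length (s).
#' @param params A [sim_params()] object.
#' @return The updated state.
#' @export
step_weights <- function(state, delta_t, params) {
  dw <- weight_derivative(params$rule, state$w, state$E_plus, state$E_minus,
                          state$D, params$alpha, params$lambda)
  state$w[] <- pmin(1, pmax(0, state$w + delta_t * dw))
  state
}
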