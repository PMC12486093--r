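#' Simulation parameters
#'
#' Build a validated parameter set for a dopamine-modulated STDP simulation.
#' Defaults follow the standard configuration of the two task settings:
#' two-channel action selection (rewards 2 and 1, deterministic choice via a
#' very large inverse temperature, sustained activity at `a_sel = 0.7`,
#' dopamine every 21 s) and single-channel value estimation (rewards 7.5 and
#' 2.5, softmax with `beta = 1`, dopamine every 7 s).
#'
#' @param setting Task environment: `"action_selection"` or
#'   `"value_estimation"`.
#' @param rule Plasticity rule: one of `"additive"`, `"multiplicative"`,
#'   `"symmetric"`, `"corticostriatal"`.
#' @param n_inputs Number of presynaptic units per channel (N).
#' @param rates Vector of presynaptic firing rates (s^-1), length `n_inputs`.
#' @param lambda Learning rate for the synaptic weights.
#' @param lambda_bar Learning rate for the abstract action preference
#'   (value-estimation setting only).
#' @param alpha Asymmetry factor weighting depression relative to potentiation.
#' @param tau STDP time constant (s): decay of the pre/post spike traces.
#' @param tau_eli Eligibility-trace time constant (s).
#' @param tau_dop Dopamine decay time constant (s).
#' @param epsilon Synaptic delay (s) between a presynaptic spike and the
#'   postsynaptic spike it may cause.  Must be a multiple of `dt`.
#' @param T_win Spike-count window length (s).
#' @param T_del Delay (s) between the end of the count window and dopamine
#'   release.
#' @param r_dop Dopamine release rate (s^-1); one release per `1/r_dop` cycle.
#' @param beta Inverse temperature of the softmax action-selection function.
#' @param a_sel Sustained-activity fraction in the selected channel during
#'   the inter-window interval (action selection only), in (0, 1].
#' @param R1,R2 Rewards delivered for actions A1 and A2.
#' @param w_init Initial synaptic weight, in \[0, 1\].
#' @param p_init Initial probability of selecting action A1 (value
#'   estimation; realised as a zero initial preference difference when 0.5).
#' @param dt Integration step (s).
#' @param n_steps Number of dopamine release cycles to simulate.
#' @param switch_period Optional number of cycles between reward-contingency
#'   switches (`NULL` for none).
#' @param sustained Logical; keep `a_sel`-scaled activity in the selected
#'   channel between count windows (action selection only).
#'
#' @return An object of class `"dastdp_params"`: a named list with the fields
#'   above plus `n_channels` (2 for action selection, 1 for value estimation).
#' @examples
#' p <- sim_params("value_estimation", "additive")
#' p$r_dop          # one dopamine release every 7 s
#' @export
sim_params <- function(setting = c("action_selection", "value_estimation"),
                       rule = c("additive", "symmetric", "corticostriatal",
                                "multiplicative"),
                       n_inputs = 1L,
                       rates = NULL,
                       lambda = NULL,
                       lambda_bar = 0.0025,
                       alpha = 1,
                       tau = 0.02,
                       tau_eli = 1,
                       tau_dop = 1,
                       epsilon = 0.001,
                       T_win = 1,
                       T_del = NULL,
                       r_dop = NULL,
                       beta = NULL,
                       a_sel = 0.7,
                       R1 = NULL, R2 = NULL,
                       w_init = 0.5,
                       p_init = 0.5,
                       dt = 0.001,
                       n_steps = 1000L,
                       switch_period = NULL,
                       sustained = TRUE) {
  setting <- match.arg(setting)
  rule <- match.arg(rule)
  as <- setting == "action_selection"

  if (is.null(rates))  rates  <- if (n_inputs == 1L) 10 else rep(10, n_inputs)
  if (is.null(lambda)) lambda <- if (as) 0.01 else 0.001
  if (is.null(T_del))  T_del  <- if (as) 10 else 3
  if (is.null(r_dop))  r_dop  <- if (as) 1 / 21 else 1 / 7
  if (is.null(beta))   beta   <- if (as) 1e6 else 1
  if (is.null(R1))     R1     <- if (as) 2 else 7.5
  if (is.null(R2))     R2     <- if (as) 1 else 2.5

  n_inputs <- as.integer(n_inputs)
  if (n_inputs < 1L) stop("n_inputs must be a positive integer")
  if (length(rates) != n_inputs) stop("rates must have length n_inputs")
  if (any(rates < 0)) stop("rates must be non-negative")
  stopifnot(lambda >= 0, lambda_bar >= 0, alpha > 0,
            tau > 0, tau_eli > 0, tau_dop > 0,
            T_win > 0, T_del >= 0, r_dop > 0, dt > 0, epsilon > 0)
  if (w_init < 0 || w_init > 1) stop("w_init must lie in [0, 1]")
  if (p_init < 0 || p_init > 1) stop("p_init must lie in [0, 1]")
  if (a_sel <= 0 || a_sel > 1) stop("a_sel must lie in (0, 1]")
  if (1 / r_dop < T_win + T_del) {
    stop("cycle too short: 1/r_dop must be at least T_win + T_del")
  }
  eps_bins <- epsilon / dt
  if (abs(eps_bins - round(eps_bins)) > 1e-9 || round(eps_bins) < 1) {
    stop("epsilon must be a positive integer multiple of dt")
  }
  if (!is.null(switch_period) && switch_period < 1) {
    stop("switch_period must be a positive integer or NULL")
  }

  structure(list(
    setting = setting, rule = rule,
    n_inputs = n_inputs, n_channels = if (as) 2L else 1L,
    rates = as.numeric(rates),
    lambda = lambda, lambda_bar = lambda_bar, alpha = alpha,
    tau = tau, tau_eli = tau_eli, tau_dop = tau_dop,
    epsilon = epsilon, T_win = T_win, T_del = T_del, r_dop = r_dop,
    beta = beta, a_sel = a_sel, R1 = R1, R2 = R2,
    w_init = w_init, p_init = p_init,
    dt = dt, n_steps = as.integer(n_steps),
    switch_period = if (is.null(switch_period)) NULL
                    else as.integer(switch_period),
    sustained = isTRUE(sustained)
  ), class = "dastdp_params")
}

#' @export
print.dastdp_params <- function(x, ...) {
  cat("<dastdp_params>\n")
  cat(sprintf("  setting: %s   rule: %s\n", x$setting, x$rule))
  cat(sprintf("  N = %d input(s) per channel at rates (%s) /s\n",
              x$n_inputs, paste(format(x$rates), collapse = ", ")))
  cat(sprintf("  alpha = %g, lambda = %g, tau = %g s, tau_eli = %g s, tau_dop = %g s\n",
              x$alpha, x$lambda, x$tau, x$tau_eli, x$tau_dop))
  cat(sprintf("  cycle 1/r_dop = %g s (T_win = %g s, T_del = %g s), rewards (%g, %g)\n",
              1 / x$r_dop, x$T_win, x$T_del, x$R1, x$R2))
  invisible(x)
}

# Number of dt bins in one full dopamine cycle / in each cycle phase.
cycle_bins <- function(params) {
  total <- round(1 / params$r_dop / params$dt)
  win <- round(params$T_win / params$dt)
  del <- round(params$T_del / params$dt)
  list(total = total, window = win, delay = del, rest = total - win - del)
}

#' Dopamine time constant from a half-life
#'
#' Converts a measured exponential half-life into the corresponding decay
#' time constant, `tau = t_half / log(2)`.  Striatal dopamine clearance with
#' a half-life of about 0.72 s gives a time constant of about 1 s.
#'
#' @param t_half Half-life (s).
#' @return Exponential time constant (s).
#' @examples
#' tau_from_half_life(0.72)  # ~1.04 s
#' @export
tau_from_half_life <- function(t_half) {
  stopifnot(t_half > 0)
  t_half / log(2)
}

#' Causal-pair attenuation factor
#'
#' A postsynaptic spike caused by a presynaptic spike arrives `epsilon` later,
#' so the presynaptic trace it reads has decayed by `exp(-epsilon/tau)`.  The
#' idealised drift equations assume this factor is 1; it scales the
#' causal-pair term of the drift when the synaptic delay is not negligible.
#'
#' @param epsilon Synaptic delay (s).
#' @param tau STDP time constant (s).
#' @return The attenuation factor `exp(-epsilon/tau)` in (0, 1\].
#' @examples
#' epsilon_attenuation(0.001, 0.02)  # 0.95
#' epsilon_attenuation(0.005, 0.02)  # 0.78
#' @export
epsilon_attenuation <- function(epsilon, tau) {
  stopifnot(epsilon >= 0, tau > 0)
  exp(-epsilon / tau)
}
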