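# f+ and (f+ - f-) for the rules with factorable averaged dynamics
f_plus_fun <- function(rule, w) {
  switch(rule,
    additive = rep(1, length(w)),
    symmetric = w * (1 - w),
    stop("averaged drift is defined for the additive and symmetric rules")
  )
}
delta_f_fun <- function(rule, w, alpha) {
  switch(rule,
    additive = rep(1 - alpha, length(w)),
    symmetric = (1 - alpha) * w * (1 - w),
    stop("averaged drift is defined for the additive and symmetric rules")
  )
}

#' Averaged weight drift in the action-selection setting
#'
#' Evaluates the mean-field drift of the two channels' weights.  For the
#' additive and symmetric rules the drift factorises into the reward
#' contrast `(R1-R2) * E[p](1-E[p])`, the release-and-decay prefactor
#' `r_dop*tau_dop*tau_eli*lambda/N`, and a per-synapse bracket
#' `a_sel^2*tau*<w_j,r>*Delta_f(w_ij)*r_i + a_sel*f_plus(w_ij)*w_ij*r_i`
#' (independent spike pairs plus causal pairs, at the sustained rate).  The
#' corticostriatal rule has its own piecewise system whose channel forms
#' swap when the reward ordering is reversed.
#'
#' @param rule `"additive"`, `"symmetric"` or `"corticostriatal"`.
#' @param w1,w2 Weight vectors of the two channels.
#' @param params A [sim_params()] object (action-selection defaults).
#' @param attenuate Logical; multiply the causal-pair term by
#'   [epsilon_attenuation()] instead of assuming it is 1.  The idealised
#'   drift (default) matches the printed mean-field equations.
#' @return A list with numeric vectors `dw1` and `dw2` and the expected
#'   selection probability `E_p`.
#' @export
drift_action_selection <- function(rule, w1, w2, params, attenuate = FALSE) {
  if (rule == "multiplicative") {
    stop("the multiplicative rule is not supported by the averaged analysis")
  }
  r <- params$rates
  N <- params$n_inputs
  a <- params$a_sel
  katt <- if (attenuate) epsilon_attenuation(params$epsilon, params$tau) else 1
  E_p <- expected_p(w1, w2, r, N, params$T_win, params$beta)
  base <- E_p * (1 - E_p) * params$r_dop * params$tau_dop * params$tau_eli *
    params$lambda / N

  if (rule %in% c("additive", "symmetric")) {
    pref <- (params$R1 - params$R2) * base
    bracket <- function(wj) {
      a^2 * params$tau * sum(wj * r) * delta_f_fun(rule, wj, params$alpha) * r +
        katt * a * f_plus_fun(rule, wj) * wj * r
    }
    list(dw1 = pref * bracket(w1), dw2 = -pref * bracket(w2), E_p = E_p)
  } else {
    pref <- abs(params$R1 - params$R2) * base
    hi <- function(wj) { # channel mapped to the larger reward
      a^2 * params$tau * sum(wj * r) * (1 - (1 + params$alpha) * wj) * r +
        katt * a * (1 - wj) * wj * r
    }
    lo <- function(wj) { # channel mapped to the smaller reward
      a^2 * params$tau * sum(wj * r) * (1 - (1 + params$alpha) * wj) * r -
        katt * a * params$alpha * wj^2 * r
    }
    if (params$R1 >= params$R2) {
      list(dw1 = pref * hi(w1), dw2 = pref * lo(w2), E_p = E_p)
    } else {
      list(dw1 = pref * lo(w1), dw2 = pref * hi(w2), E_p = E_p)
    }
  }
}

#' Corticostriatal action-selection equilibrium
#'
#' Closed-form attracting equilibrium of the corticostriatal averaged system
#' in the action-selection setting: with `s = a_sel * tau * ||r||_1`,
#' `w1* = (s + 1) / (s * (1 + alpha) + 1)` for the channel mapped to the
#' larger reward and `w2* = s / (s * (1 + alpha) + alpha)` for the other, so
#' `w1* > w2*` always.
#'
#' @param params A [sim_params()] object.
#' @return A list with components `w1` and `w2`.
#' @examples
#' corticostriatal_equilibrium(sim_params("action_selection",
#'                                        "corticostriatal"))
#' @export
corticostriatal_equilibrium <- function(params) {
  s <- params$a_sel * params$tau * sum(params$rates)
  list(w1 = (s + 1) / (s * (1 + params$alpha) + 1),
       w2 = s / (s * (1 + params$alpha) + params$alpha))
}

#' Critical asymmetry factor
#'
#' Returns the critical value of `alpha` at which the drift condition for
#' learning the correct action (action selection,
#' `a_sel*tau*(alpha-1) < 1/||r||_1`) or for stability of the accurate
#' value-estimation equilibria (`tau*(alpha-1) < 1/||r||_1`) becomes an
#' equality.  Below the returned value the additive and symmetric models
#' flow toward the task-appropriate weights; above it they do not.
#'
#' @param setting `"action_selection"` or `"value_estimation"`.
#' @param params A [sim_params()] object supplying `a_sel`, `tau` and
#'   `rates`.
#' @return The critical alpha.
#' @examples
#' threshold_alpha("action_selection",
#'                 sim_params("action_selection", "additive"))  # ~8.14
#' @export
threshold_alpha <- function(setting = c("action_selection",
                                        "value_estimation"),
                            params) {
  setting <- match.arg(setting)
  r1 <- sum(params$rates)
  if (setting == "action_selection") {
    1 + 1 / (params$a_sel * params$tau * r1)
  } else {
    1 + 1 / (params$tau * r1)
  }
}

#' Averaged drift in the value-estimation setting
#'
#' Evaluates the mean-field drift of the weights and of the action
#' probability.  The weight drift factorises into the mean dopamine level
#' `p*R1 + (1-p)*R2 - <w,r>/N` times the per-synapse bracket
#' `tau*<w,r>*Delta_f(w_i)*r_i + f_plus(w_i)*w_i*r_i`; the probability
#' drift is `lambda_bar*beta*r_dop*tau_dop * p(1-p) *
#' [p*(R1 - <w,r>/N) - (1-p)*(R2 - <w,r>/N)]`.  Only the additive and
#' symmetric rules admit this factorised form; for the corticostriatal rule
#' use [monte_carlo_drift()].
#'
#' @param rule `"additive"` or `"symmetric"`.
#' @param w Weight vector.
#' @param p Probability of selecting action A1, in \[0, 1\].
#' @param params A [sim_params()] object (value-estimation defaults).
#' @param attenuate Logical; apply [epsilon_attenuation()] to the
#'   causal-pair term.
#' @return A list with numeric vector `dw` and scalar `dp`.
#' @export
drift_value_estimation <- function(rule, w, p, params, attenuate = FALSE) {
  if (!rule %in% c("additive", "symmetric")) {
    stop("averaged value-estimation drift is defined for the additive and ",
         "symmetric rules; use monte_carlo_drift() for the corticostriatal ",
         "rule")
  }
  stopifnot(p >= 0, p <= 1)
  r <- params$rates
  N <- params$n_inputs
  katt <- if (attenuate) epsilon_attenuation(params$epsilon, params$tau) else 1
  v <- sum(w * r) / N
  dopf <- p * params$R1 + (1 - p) * params$R2 - v
  pref <- dopf * params$r_dop * params$tau_dop * params$tau_eli *
    params$lambda / N
  dw <- pref * (params$tau * sum(w * r) * delta_f_fun(rule, w, params$alpha) * r +
                  katt * f_plus_fun(rule, w) * w * r)
  dp <- params$lambda_bar * params$beta * params$r_dop * params$tau_dop *
    p * (1 - p) * (p * (params$R1 - v) - (1 - p) * (params$R2 - v))
  list(dw = dw, dp = dp)
}

#' Stability of the accurate value-estimation equilibria
#'
#' Evaluates the single nonzero-eigenvalue condition at a point on one of
#' the `<w,r>/N = R*` equilibrium hyperplanes:
#' `S = sum(r_i^2 * (tau*N*R* * Delta_f(w_i) + f_plus(w_i)*w_i))`.  The
#' equilibrium is attracting in the weight directions iff `S > 0`.  For the
#' additive rule with N = 1 the sign of `S` flips exactly at
#' `alpha = 1 + 1/(tau*||r||_1)` (see [threshold_alpha()]).
#'
#' @param w Weight vector on the equilibrium hyperplane.
#' @param R_star The reward (`R1` or `R2`) defining the hyperplane.
#' @param params A [sim_params()] object.
#' @param rule `"additive"` or `"symmetric"` (defaults to `params$rule`).
#' @return A list with logical `stable` and the numeric condition `value`.
#' @export
stability_condition <- function(w, R_star, params, rule = params$rule) {
  r <- params$rates
  N <- params$n_inputs
  S <- sum(r^2 * (params$tau * N * R_star * delta_f_fun(rule, w, params$alpha) +
                    f_plus_fun(rule, w) * w))
  list(stable = S > 0, value = S)
}

#' Monte-Carlo single-release weight drift
#'
#' Estimates the mean weight change produced by one dopamine release by
#' running independent single-cycle simulations from a fixed weight vector
#' (and, in the value-estimation setting, a fixed action probability).  In
#' the value-estimation protocol the traces are first equilibrated under
#' constant input for `burn_in` seconds (the weights cannot move during
#' burn-in because the dopamine level is exactly zero), then a spike-count
#' window, the delay, the release, and a post-release tail long enough for
#' the dopamine impulse to decay away are simulated.  In the
#' action-selection protocol one full cycle is simulated, with the choice
#' taken from the windowed spike counts as in [run_cycle()].
#'
#' @param params A [sim_params()] object; `params$rule` selects the
#'   plasticity rule.
#' @param w Initial weight (vector of length `n_inputs`, or an
#'   `n_inputs x 2` matrix in the action-selection setting; scalars are
#'   recycled).
#' @param p Fixed probability of choosing action A1 (value estimation only).
#' @param n_samples Number of independent single-cycle samples.
#' @param burn_in Trace-equilibration time (s) before the count window
#'   (value estimation only).
#' @return A list with `mean` (mean weight change per synapse), `se`
#'   (standard error), `sd`, and `n_samples`.  For action selection the
#'   entries are `n_inputs x 2` matrices.
#' @export
monte_carlo_drift <- function(params, w, p = 0.5, n_samples = 1000,
                              burn_in = 5 * params$tau_eli) {
  bins <- cycle_bins(params)
  if (params$setting == "value_estimation") {
    burn_bins <- round(burn_in / params$dt)
    tail_bins <- max(bins$rest, round(6 * params$tau_dop / params$dt))
    w0 <- matrix(w, params$n_inputs, 1)
    dws <- matrix(NA_real_, n_samples, params$n_inputs)
    for (s in seq_len(n_samples)) {
      st <- synapse_state(params, w0)
      ph0 <- sim_phase(st, burn_bins, 1, params)
      ph1 <- sim_phase(ph0$state, bins$window, 1, params)
      choice <- if (stats::runif(1) < p) 1L else 2L
      R_star <- if (choice == 1L) params$R1 else params$R2
      D_k <- R_star - ph1$post_counts[1] / params$T_win
      ph2 <- sim_phase(ph1$state, bins$delay, 1, params)
      ph3 <- sim_phase(ph2$state, tail_bins, 1, params,
                       release_bin = 1L, release_amount = D_k)
      dws[s, ] <- ph3$state$w[, 1] - w0[, 1]
    }
  } else {
    w0 <- matrix(w, params$n_inputs, 2)
    dws <- matrix(NA_real_, n_samples, 2 * params$n_inputs)
    for (s in seq_len(n_samples)) {
      st <- synapse_state(params, w0)
      out <- run_cycle_action_selection(st, params, step = 0)
      dws[s, ] <- as.vector(out$state$w - w0)
    }
  }
  m <- colMeans(dws)
  sdv <- apply(dws, 2, stats::sd)
  se <- sdv / sqrt(n_samples)
  if (params$setting == "action_selection") {
    m <- matrix(m, params$n_inputs, 2)
    se <- matrix(se, params$n_inputs, 2)
    sdv <- matrix(sdv, params$n_inputs, 2)
  }
  list(mean = m, se = se, sd = sdv, n_samples = n_samples)
}
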