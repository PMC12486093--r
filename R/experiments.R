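#' Phase-portrait experiment
#'
#' Runs an ensemble of stochastic trials and pairs it with the averaged-model
#' reference: the deterministic trajectory from the same initial condition,
#' the equilibrium catalogue, and the vector-field grid (the latter two only
#' for N = 1, where the system is 2-D).
#'
#' @param params A [sim_params()] object.
#' @param n_trials Number of stochastic trials.
#' @param seed Master seed for the ensemble.
#' @return A list with components `ensemble` (stacked trajectories),
#'   `averaged` (ODE reference), `equilibria`, and `field`.
#' @export
run_phase_portrait <- function(params, n_trials = 20, seed = 1) {
  ens <- run_ensemble(params, n_trials, seed = seed)
  avg <- if (params$n_inputs == 1L &&
             !(params$setting == "value_estimation" &&
               params$rule == "corticostriatal") &&
             params$rule != "multiplicative") {
    averaged_trajectory(params)
  } else NULL
  eq <- if (params$n_inputs == 1L && params$rule != "multiplicative") {
    find_equilibria(params)
  } else NULL
  fld <- if (!is.null(avg)) vector_field(params) else NULL
  list(ensemble = ens, averaged = avg, equilibria = eq, field = fld,
       params = params)
}

#' Contingency-switching experiment
#'
#' Runs an ensemble with periodic reward swaps and summarises performance as
#' the per-step proportion of trials choosing the currently-higher-rewarded
#' action, plus the recovery time after each switch (steps until that
#' proportion first reaches `threshold`).
#'
#' @param params A [sim_params()] object with `switch_period` set.
#' @param n_trials Number of trials.
#' @param seed Master seed.
#' @param threshold Proportion-correct defining recovery (midpoint between
#'   chance and ceiling by default).
#' @return A list with `accuracy` (data frame: step, prop_correct) and
#'   `recovery` (data frame: switch step, recovery time in steps, NA if the
#'   threshold is never reached before the next switch).
#' @export
run_contingency <- function(params, n_trials = 20, seed = 1,
                            threshold = 0.75) {
  ens <- run_ensemble(params, n_trials, seed = seed)
  correct <- ifelse(ens$R1_eff >= ens$R2_eff, ens$choice == 1L,
                    ens$choice == 2L)
  acc <- stats::aggregate(correct, by = list(step = ens$step), FUN = mean)
  names(acc)[2] <- "prop_correct"
  acc <- acc[order(acc$step), ]

  recovery <- NULL
  if (!is.null(params$switch_period)) {
    switches <- seq(params$switch_period, params$n_steps - 1,
                    by = params$switch_period)
    rec <- vapply(switches, function(s0) {
      blk <- acc[acc$step >= s0 &
                   acc$step < min(s0 + params$switch_period,
                                  params$n_steps), ]
      hit <- which(blk$prop_correct >= threshold)
      if (length(hit) == 0) NA_real_ else blk$step[hit[1]] - s0
    }, numeric(1))
    recovery <- data.frame(switch_step = switches, recovery_steps = rec)
  }
  list(accuracy = acc, recovery = recovery, ensemble = ens, params = params)
}

#' Delay-sweep experiment
#'
#' Final-weight summary in the action-selection setting as the dopamine
#' delay is varied, with and without sustained activity in the selected
#' channel.  Reveals that sustained activity solves temporal credit
#' assignment: without it, eligibility decays before release and learning
#' fails at long delays.
#'
#' @param params An action-selection [sim_params()] object (its `T_del` and
#'   `sustained` fields are overridden per condition).
#' @param T_del_grid Delays to test (s); the cycle must still fit, i.e.
#'   `T_win + T_del <= 1/r_dop`.
#' @param sustained Logical vector of sustained-activity conditions.
#' @param n_trials Trials per condition.
#' @param seed Master seed.
#' @return A data frame with one row per condition: T_del, sustained, mean
#'   and SD of the terminal w1 and w2, and of their difference.
#' @export
run_delay_sweep <- function(params, T_del_grid = c(0, 2.5, 5, 10),
                            sustained = c(TRUE, FALSE), n_trials = 20,
                            seed = 1) {
  stopifnot(params$setting == "action_selection", params$n_inputs == 1L)
  rows <- list()
  for (sus in sustained) for (td in T_del_grid) {
    p <- params
    p$T_del <- td
    p$sustained <- sus
    if (1 / p$r_dop < p$T_win + td) {
      stop("T_del = ", td, " does not fit in the dopamine cycle")
    }
    ens <- run_ensemble(p, n_trials, seed = seed)
    fin <- ens[ens$step == max(ens$step), ]
    rows[[length(rows) + 1]] <- data.frame(
      T_del = td, sustained = sus,
      w1_mean = mean(fin$w1), w1_sd = stats::sd(fin$w1),
      w2_mean = mean(fin$w2), w2_sd = stats::sd(fin$w2),
      dw_mean = mean(fin$w1 - fin$w2), dw_sd = stats::sd(fin$w1 - fin$w2))
  }
  do.call(rbind, rows)
}

#' Single-release drift probe
#'
#' Monte-Carlo mean weight change after one dopamine release as a function
#' of the initial weight, in the value-estimation setting with the action
#' probability held fixed, overlaid with the averaged-model prediction
#' (drift divided by the release rate; causal-pair term attenuated by
#' `exp(-epsilon/tau)`).  The zero crossing of the mean drift sits where the
#' predicted value `w * r` equals the mean delivered reward.
#'
#' @param params A value-estimation [sim_params()] object.
#' @param w_grid Initial weights to probe.
#' @param p Fixed action probability.
#' @param n_samples Single-cycle samples per grid point.
#' @param seed Master seed (one stream per grid point).
#' @return A data frame with columns `w`, `mean_dw`, `se`, `sd`, and
#'   `predicted` (NA for the corticostriatal rule, which has no closed-form
#'   averaged weight drift).
#' @export
run_single_release_probe <- function(params, w_grid = seq(0, 1, by = 0.1),
                                     p = 0.5, n_samples = 1000, seed = 1) {
  stopifnot(params$setting == "value_estimation", params$n_inputs == 1L)
  analytic <- params$rule %in% c("additive", "symmetric")
  rows <- lapply(seq_along(w_grid), function(k) {
    set.seed(seed + k - 1)
    w <- w_grid[k]
    mc <- monte_carlo_drift(params, w, p = p, n_samples = n_samples)
    pred <- if (analytic) {
      drift_value_estimation(params$rule, w, p, params,
                             attenuate = TRUE)$dw / params$r_dop
    } else NA_real_
    data.frame(w = w, mean_dw = mc$mean, se = mc$se, sd = mc$sd,
               predicted = pred)
  })
  do.call(rbind, rows)
}

#' Zero crossing of a drift curve
#'
#' Linear interpolation of the first sign change of `mean_dw` over `w` in a
#' [run_single_release_probe()] result.
#'
#' @param probe Data frame with columns `w` and `mean_dw`.
#' @return The interpolated crossing, or NA if the curve does not change
#'   sign.
#' @export
drift_zero_crossing <- function(probe) {
  probe <- probe[order(probe$w), ]
  s <- sign(probe$mean_dw)
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (length(idx) == 0) return(NA_real_)
  k <- idx[1]
  w0 <- probe$w[k]; w1 <- probe$w[k + 1]
  y0 <- probe$mean_dw[k]; y1 <- probe$mean_dw[k + 1]
  w0 - y0 * (w1 - w0) / (y1 - y0)
}
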