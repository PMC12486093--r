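#' Update the abstract action preference
#'
#' Integrates the preference difference between the two abstract action
#' variables over one dopamine cycle: the difference moves by
#' `lambda_bar * A_bar * integral(D dt)`, where `A_bar` is +1 if the last
#' action was A1 and -1 if it was A2.  A single dopamine impulse `D_k`
#' followed by full decay therefore shifts the preference by approximately
#' `lambda_bar * D_k * tau_dop`.
#'
#' @param R_diff Current preference difference.
#' @param D_integral Integral of the dopamine level over the cycle (s).
#' @param A_bar +1 or -1, encoding the previous action.
#' @param lambda_bar Preference learning rate.
#' @return The updated preference difference.
#' @export
preference_update <- function(R_diff, D_integral, A_bar, lambda_bar) {
  R_diff + lambda_bar * A_bar * D_integral
}

run_cycle_value_estimation <- function(state, params, step = 0) {
  bins <- cycle_bins(params)

  # spike-count window; input stays on for the entire cycle in this setting
  ph1 <- sim_phase(state, bins$window, 1, params)
  count <- ph1$post_counts[1]
  R_bar <- count / params$T_win

  # action sampled once per cycle, at the end of the count window
  p <- stats::plogis(params$beta * state$R_diff)
  choice <- if (stats::runif(1) < p) 1L else 2L
  A_cur <- if (choice == 1L) 1 else -1

  rw <- contingency_schedule(step, params$switch_period, params$R1, params$R2)
  R_star <- rw[choice]
  D_k <- R_star - R_bar

  ph2 <- sim_phase(ph1$state, bins$delay, 1, params)
  ph3 <- sim_phase(ph2$state, bins$rest, 1, params,
                   release_bin = 1L, release_amount = D_k)

  # continuous preference integration: residual dopamine during the window
  # still carries the previous action's sign
  new_state <- ph3$state
  R_diff <- preference_update(state$R_diff, ph1$D_integral, state$A_bar,
                              params$lambda_bar)
  R_diff <- preference_update(R_diff, ph2$D_integral + ph3$D_integral,
                              A_cur, params$lambda_bar)
  new_state$R_diff <- R_diff
  new_state$A_bar <- A_cur

  record <- c(list(step = step, count = count, R_bar = R_bar, p = p,
                   choice = choice, reward = R_star, D_k = D_k,
                   R_diff = R_diff, R1_eff = rw[1], R2_eff = rw[2]),
              as.list(stats::setNames(as.vector(new_state$w),
                                      weight_names(params))))
  list(state = new_state, record = record)
}

#' Run one dopamine cycle
#'
#' Simulates one full cycle of length `1/r_dop` in the configured task
#' setting: spike-count window, action choice, reward, delayed
#' reward-prediction-error dopamine release, and continuous plasticity
#' throughout.  See [run_trial()] for whole-trial simulation.
#'
#' @param state A [synapse_state()] object.
#' @param params A [sim_params()] object.
#' @param step Cycle index (0-based), used by the contingency schedule.
#' @return A list with the updated `state` and a named-list `record` of the
#'   cycle (counts, choice, reward, dopamine increment, weight snapshot).
#' @export
run_cycle <- function(state, params, step = 0) {
  if (params$setting == "action_selection") {
    run_cycle_action_selection(state, params, step)
  } else {
    run_cycle_value_estimation(state, params, step)
  }
}

#' Simulate a full trial
#'
#' Runs `params$n_steps` dopamine cycles from a fresh [synapse_state()] and
#' collects the per-cycle records.
#'
#' @param params A [sim_params()] object.
#' @param state Optional initial state (defaults to a fresh one).
#' @return A data frame with one row per cycle; class `"dastdp_trajectory"`,
#'   carrying the parameters in `attr(, "params")`.
#' @examples
#' \donttest{
#' p <- sim_params("value_estimation", "additive", n_steps = 20)
#' set.seed(1)
#' traj <- run_trial(p)
#' tail(traj$w, 1)
#' }
#' @export
run_trial <- function(params, state = NULL) {
  if (is.null(state)) state <- synapse_state(params)
  records <- vector("list", params$n_steps)
  for (k in seq_len(params$n_steps)) {
    out <- run_cycle(state, params, step = k - 1)
    state <- out$state
    records[[k]] <- out$record
  }
  traj <- do.call(rbind, lapply(records, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  attr(traj, "params") <- params
  class(traj) <- c("dastdp_trajectory", class(traj))
  traj
}

#' Simulate an ensemble of trials
#'
#' Runs independent trials with per-trial RNG streams derived from a master
#' seed (`seed + trial - 1`), so ensembles are exactly reproducible and each
#' trial can be regenerated in isolation.
#'
#' @param params A [sim_params()] object.
#' @param n_trials Number of independent trials.
#' @param seed Master seed, or `NULL` to continue the current RNG stream.
#' @return A data frame of stacked trajectories with a leading `trial`
#'   column.
#' @export
run_ensemble <- function(params, n_trials, seed = NULL) {
  out <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    if (!is.null(seed)) set.seed(seed + t - 1)
    traj <- run_trial(params)
    traj <- cbind(trial = t, as.data.frame(traj))
    out[[t]] <- traj
  }
  res <- do.call(rbind, out)
  attr(res, "params") <- params
  res
}

#' Write a trajectory to CSV
#'
#' @param traj A trajectory data frame from [run_trial()] or
#'   [run_ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
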