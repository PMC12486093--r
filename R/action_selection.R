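#' Expected probability of selecting action A1
#'
#' Averages the softmax choice probability over the Poisson distributions of
#' the two channels' windowed postsynaptic spike counts.  The double sum is
#' truncated at `mean + 12*sqrt(mean) + 20` counts per channel, giving a
#' truncation error far below 1e-10 at the rates used here.  At very large
#' `beta` the kernel reduces to an indicator of which count is larger, with
#' weight 1/2 on ties.
#'
#' @param w1,w2 Weight vectors of the two channels.
#' @param rates Input firing rates (s^-1).
#' @param N Number of inputs per channel.
#' @param T_win Spike-count window (s).
#' @param beta Inverse temperature.
#' @return The expected selection probability, in \[0, 1\].
#' @examples
#' p <- sim_params("action_selection", "additive")
#' expected_p(0.5, 0.5, p$rates, 1, p$T_win, p$beta)  # 0.5 by symmetry
#' @export
expected_p <- function(w1, w2, rates, N, T_win, beta) {
  n1 <- T_win * sum(w1 * rates) / N
  n2 <- T_win * sum(w2 * rates) / N
  stopifnot(is.finite(n1), is.finite(n2), n1 >= 0, n2 >= 0)
  i <- 0:ceiling(n1 + 12 * sqrt(n1) + 20)
  j <- 0:ceiling(n2 + 12 * sqrt(n2) + 20)
  K <- stats::plogis(beta / T_win * outer(i, j, "-"))
  drop(stats::dpois(i, n1) %*% K %*% stats::dpois(j, n2))
}

#' Reward contingency schedule
#'
#' Swaps the two rewards every `switch_period` cycles: the pair is returned
#' unswapped while `floor(step / switch_period)` is even and swapped while
#' it is odd.  Steps are counted from zero.
#'
#' @param step Cycle index (0-based).
#' @param switch_period Cycles between switches, or `NULL` for a fixed
#'   contingency.
#' @param R1,R2 Baseline rewards for actions A1 and A2.
#' @return Numeric vector `c(R1, R2)` for the current contingency.
#' @examples
#' contingency_schedule(1000, 1000, 2, 1)  # c(1, 2)
#' @export
contingency_schedule <- function(step, switch_period, R1, R2) {
  if (is.null(switch_period) || (step %/% switch_period) %% 2 == 0) {
    c(R1, R2)
  } else {
    c(R2, R1)
  }
}

run_cycle_action_selection <- function(state, params, step = 0) {
  bins <- cycle_bins(params)
  E_p <- expected_p(state$w[, 1], state$w[, 2], params$rates,
                    params$n_inputs, params$T_win, params$beta)

  # spike-count window: both channels at full rate
  ph1 <- sim_phase(state, bins$window, c(1, 1), params)
  n1 <- ph1$post_counts[1]
  n2 <- ph1$post_counts[2]

  # softmax choice on windowed counts; beta = 1e6 reduces to an exact count
  # comparison with uniform tie-break
  p_choice <- stats::plogis(params$beta * (n1 - n2) / params$T_win)
  choice <- if (stats::runif(1) < p_choice) 1L else 2L

  rw <- contingency_schedule(step, params$switch_period, params$R1, params$R2)
  R_star <- rw[choice]
  D_k <- R_star - (rw[1] * E_p + rw[2] * (1 - E_p))

  # inter-window interval: sustained activity a_sel*r in the selected
  # channel, silence in the other (or both silenced)
  mult <- c(0, 0)
  if (params$sustained) mult[choice] <- params$a_sel
  ph2 <- sim_phase(ph1$state, bins$delay, mult, params)
  ph3 <- sim_phase(ph2$state, bins$rest, mult, params,
                   release_bin = 1L, release_amount = D_k)

  record <- c(list(step = step, n1 = n1, n2 = n2, choice = choice,
                   reward = R_star, E_p = E_p, D_k = D_k,
                   R1_eff = rw[1], R2_eff = rw[2]),
              as.list(stats::setNames(as.vector(ph3$state$w),
                                      weight_names(params))))
  list(state = ph3$state, record = record)
}

weight_names <- function(params) {
  if (params$n_channels == 1L) {
    if (params$n_inputs == 1L) "w" else paste0("w", seq_len(params$n_inputs))
  } else if (params$n_inputs == 1L) {
    c("w1", "w2")
  } else {
    as.vector(outer(seq_len(params$n_inputs), 1:2,
                    function(i, j) paste0("w", i, "_", j)))
  }
}
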