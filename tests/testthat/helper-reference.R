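# Pure-R mirror of the compiled phase loop, consuming the RNG in exactly the
# same order, used as an independent oracle for the engine semantics.
sim_phase_reference <- function(state, n_bins, mult, params,
                                release_bin = 0L, release_amount = 0) {
  N <- params$n_inputs
  nch <- params$n_channels
  db <- nrow(state$pending)
  d_tau <- exp(-params$dt / params$tau)
  d_eli <- exp(-params$dt / params$tau_eli)
  d_dop <- exp(-params$dt / params$tau_dop)
  w <- state$w; A_pre <- state$A_pre; A_post <- state$A_post
  E_plus <- state$E_plus; E_minus <- state$E_minus; D <- state$D
  pending <- state$pending
  post_counts <- integer(nch)
  D_int <- 0
  for (b in seq_len(n_bins) - 1L) {
    A_pre <- A_pre * d_tau; A_post <- A_post * d_tau
    E_plus <- E_plus * d_eli; E_minus <- E_minus * d_eli
    D <- D * d_dop
    slot <- b %% db + 1L
    due <- pending[slot, ]
    pending[slot, ] <- 0L
    for (c in seq_len(nch)) {
      if (mult[c] <= 0) next
      for (i in seq_len(N)) {
        mu <- params$rates[i] * mult[c] * params$dt
        if (mu <= 0) next
        np <- stats::rpois(1, mu)
        if (np == 0) next
        E_minus[i, c] <- E_minus[i, c] + np * A_post[c]
        A_pre[i, c] <- A_pre[i, c] + np
        nsucc <- sum(stats::runif(np) < w[i, c] / N)
        pending[slot, c] <- pending[slot, c] + nsucc
      }
    }
    for (c in seq_len(nch)) {
      m <- due[c]
      if (m == 0) next
      E_plus[, c] <- E_plus[, c] + m * A_pre[, c]
      A_post[c] <- A_post[c] + m
      post_counts[c] <- post_counts[c] + m
    }
    if (b + 1L == release_bin) D <- D + release_amount
    dw <- weight_derivative(params$rule, w, E_plus, E_minus, D,
                            params$alpha, params$lambda)
    w[] <- pmin(1, pmax(0, w + params$dt * dw))
    D_int <- D_int + D * params$dt
  }
  off <- n_bins %% db
  if (off != 0) {
    pending <- pending[c((off + 1):db, 1:off), , drop = FALSE]
  }
  st <- state
  st$w <- w; st$A_pre <- A_pre; st$A_post <- A_post
  st$E_plus <- E_plus; st$E_minus <- E_minus; st$D <- D
  st$pending <- pending
  list(state = st, post_counts = post_counts, D_integral = D_int)
}
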