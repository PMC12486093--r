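#' Generate presynaptic Poisson spike trains
#'
#' Draws independent Poisson spike counts on a fixed time grid for each
#' input unit.  A piecewise-constant schedule of rate multipliers models
#' silencing (multiplier 0) and sustained activity (multiplier `a_sel`)
#' between spike-count windows.
#'
#' @param rates Vector of baseline firing rates (s^-1), one per unit.
#' @param duration Total simulated time (s).
#' @param dt Bin width (s).
#' @param schedule Rate multiplier: a scalar, or a vector with one entry per
#'   bin.
#' @return An integer matrix of spike counts, `n_bins x length(rates)`, with
#'   attribute `dt`.  Multiple spikes per bin are allowed.
#' @examples
#' set.seed(1)
#' counts <- generate_presyn(10, duration = 100, dt = 0.001)
#' sum(counts)  # ~1000
#' @export
generate_presyn <- function(rates, duration, dt = 0.001, schedule = 1) {
  if (any(rates < 0)) stop("rates must be non-negative")
  n_bins <- round(duration / dt)
  if (length(schedule) == 1) schedule <- rep(schedule, n_bins)
  if (length(schedule) != n_bins) {
    stop("schedule must be a scalar or have one entry per bin")
  }
  counts <- vapply(rates, function(r) {
    stats::rpois(n_bins, r * schedule * dt)
  }, integer(n_bins))
  counts <- matrix(counts, nrow = n_bins)
  attr(counts, "dt") <- dt
  counts
}

#' Generate the linear-Poisson postsynaptic spike train
#'
#' Thins the presynaptic trains: each presynaptic spike from unit `i`
#' triggers a postsynaptic spike with probability `w_i / N`, delivered one
#' synaptic delay `epsilon` later.  The postsynaptic train is therefore a
#' Poisson process with instantaneous rate `sum(w * rates) / N`.
#'
#' @param pre Presynaptic count matrix from [generate_presyn()].
#' @param w Weight vector in \[0, 1\], one per unit.
#' @param epsilon Synaptic delay (s); must be a multiple of the bin width.
#' @return An integer vector of postsynaptic counts per bin (same number of
#'   bins as `pre`; spikes shifted past the end are dropped).
#' @export
generate_postsyn <- function(pre, w, epsilon = 0.001) {
  dt <- attr(pre, "dt")
  if (is.null(dt)) stop("pre must carry a dt attribute (see generate_presyn)")
  N <- ncol(pre)
  if (length(w) != N) stop("w must have one entry per input unit")
  if (any(w < 0 | w > 1)) stop("w must lie in [0, 1]")
  shift <- round(epsilon / dt)
  n_bins <- nrow(pre)
  post <- integer(n_bins)
  for (i in seq_len(N)) {
    hits <- stats::rbinom(n_bins, pre[, i], w[i] / N)
    idx <- which(hits > 0)
    idx <- idx[idx + shift <= n_bins]
    if (length(idx)) {
      post[idx + shift] <- post[idx + shift] + hits[idx]
    }
  }
  post
}
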