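#include <Rcpp.h>
using namespace Rcpp;

// Rule codes shared with R (see engine.R): 0 additive, 1 multiplicative,
// 2 symmetric, 3 corticostriatal.
static inline double wderiv(int rule, double w, double Ep, double Em,
                            double D, double alpha, double lambda) {
  double fp, fm;
  switch (rule) {
  case 0: fp = 1.0;           fm = alpha;               break;
  case 1: fp = 1.0 - w;       fm = alpha * w;           break;
  case 2: fp = w * (1.0 - w); fm = alpha * w * (1.0 - w); break;
  default:
    if (D >= 0.0) { fp = 1.0 - w;   fm = alpha * w; }
    else          { fp = alpha * w; fm = 1.0 - w;   }
  }
  return lambda * D * (fp * Ep - fm * Em);
}

// Advance the synapse state over n_bins Euler steps of length dt with
// constant per-channel input-rate multipliers.  Within each bin the event
// order is fixed: decay, presynaptic events, postsynaptic events (those
// whose synaptic delay expires this bin), dopamine release (if scheduled),
// explicit Euler weight step with clipping.  Postsynaptic spikes are
// generated by thinning: each presynaptic spike at input i yields a
// postsynaptic spike with probability w_i/N, delivered delay_bins later.
// The ring buffer `pending` carries in-flight postsynaptic spikes across
// phase boundaries; on entry row 1 is due in the first bin, and the buffer
// is returned re-rotated to the same convention.
// [[Rcpp::export]]
List sim_phase_cpp(NumericMatrix w_, NumericMatrix A_pre_,
                   NumericVector A_post_, NumericMatrix E_plus_,
                   NumericMatrix E_minus_, double D,
                   IntegerMatrix pending_, int n_bins,
                   NumericVector rates, NumericVector mult,
                   double dt, double tau, double tau_eli, double tau_dop,
                   int rule, double alpha, double lambda,
                   int release_bin, double release_amount) {
  NumericMatrix w = clone(w_), A_pre = clone(A_pre_);
  NumericMatrix E_plus = clone(E_plus_), E_minus = clone(E_minus_);
  NumericVector A_post = clone(A_post_);
  IntegerMatrix pending = clone(pending_);

  const int N = w.nrow(), nch = w.ncol();
  const int db = pending.nrow();
  const double d_tau = std::exp(-dt / tau);
  const double d_eli = std::exp(-dt / tau_eli);
  const double d_dop = std::exp(-dt / tau_dop);

  IntegerVector post_counts(nch);
  double D_integral = 0.0;

  for (int b = 0; b < n_bins; ++b) {
    // decay
    for (int c = 0; c < nch; ++c) {
      A_post[c] *= d_tau;
      for (int i = 0; i < N; ++i) {
        A_pre(i, c) *= d_tau;
        E_plus(i, c) *= d_eli;
        E_minus(i, c) *= d_eli;
      }
    }
    D *= d_dop;

    const int slot = b % db;

    // postsynaptic spikes due this bin (generated delay_bins ago); read and
    // clear before this bin's presynaptic spikes reuse the slot
    std::vector<int> due(nch);
    for (int c = 0; c < nch; ++c) { due[c] = pending(slot, c); pending(slot, c) = 0; }

    // presynaptic events: trace/eligibility impulses, then thinning
    for (int c = 0; c < nch; ++c) {
      if (mult[c] <= 0.0) continue;
      for (int i = 0; i < N; ++i) {
        double mu = rates[i] * mult[c] * dt;
        if (mu <= 0.0) continue;
        int np = (int) R::rpois(mu);
        if (np == 0) continue;
        E_minus(i, c) += np * A_post[c];
        A_pre(i, c) += np;
        double pth = w(i, c) / N;
        int nsucc = 0;
        for (int s = 0; s < np; ++s) if (unif_rand() < pth) ++nsucc;
        if (nsucc > 0) pending(slot, c) += nsucc;
      }
    }

    // deliver due postsynaptic spikes
    for (int c = 0; c < nch; ++c) {
      int m = due[c];
      if (m == 0) continue;
      for (int i = 0; i < N; ++i) E_plus(i, c) += m * A_pre(i, c);
      A_post[c] += m;
      post_counts[c] += m;
    }

    // dopamine release aligned to the grid; the weight step below sees the
    // post-release level so the impulse integrates from this bin onward
    if (b + 1 == release_bin) D += release_amount;

    // Euler weight step, factors at the pre-update weight, then clip
    for (int c = 0; c < nch; ++c)
      for (int i = 0; i < N; ++i) {
        double wn = w(i, c) + dt * wderiv(rule, w(i, c), E_plus(i, c),
                                          E_minus(i, c), D, alpha, lambda);
        w(i, c) = wn < 0.0 ? 0.0 : (wn > 1.0 ? 1.0 : wn);
      }

    D_integral += D * dt;
  }

  // rotate pending so row 1 is due in the first bin of the next phase
  if (n_bins % db != 0) {
    IntegerMatrix rot(db, nch);
    int off = n_bins % db;
    for (int r = 0; r < db; ++r)
      for (int c = 0; c < nch; ++c)
        rot(r, c) = pending((r + off) % db, c);
    pending = rot;
  }

  return List::create(_["w"] = w, _["A_pre"] = A_pre, _["A_post"] = A_post,
                      _["E_plus"] = E_plus, _["E_minus"] = E_minus,
                      _["D"] = D, _["pending"] = pending,
                      _["post_counts"] = post_counts,
                      _["D_integral"] = D_integral);
}
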