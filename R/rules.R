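#' Weight-dependent scaling factors of the plasticity rules
#'
#' Returns the multipliers `f_plus` and `f_minus` applied to the positive
#' (pre-before-post) and negative (post-before-pre) eligibility traces in the
#' weight update.  The additive rule uses constants (1, alpha); the
#' multiplicative rule (1-w, alpha*w); the symmetric rule scales both traces
#' by w(1-w) so that updates vanish at the weight bounds; the corticostriatal
#' rule ties the factors to the direction of the weight change, using 1-w for
#' increases and alpha*w for decreases, so the factor assignment swaps with
#' the sign of the dopamine signal.
#'
#' @param rule One of `"additive"`, `"multiplicative"`, `"symmetric"`,
#'   `"corticostriatal"`.
#' @param w Weight(s) in \[0, 1\]; vectorised.
#' @param alpha Asymmetry factor.
#' @param dopamine_sign `+1` or `-1`; only consulted by the corticostriatal
#'   rule (zero dopamine is treated as the non-negative branch).
#' @return A list with numeric components `f_plus` and `f_minus`, the same
#'   length as `w`.
#' @examples
#' scaling_factors("additive", 0.3, alpha = 2)          # (1, 2)
#' scaling_factors("corticostriatal", 0.25, 1, -1)      # (0.25, 0.75)
#' @export
scaling_factors <- function(rule, w, alpha, dopamine_sign = 1) {
  if (any(w < 0 | w > 1)) stop("w must lie in [0, 1]")
  switch(rule,
    additive = list(f_plus = rep(1, length(w)),
                    f_minus = rep(alpha, length(w))),
    multiplicative = list(f_plus = 1 - w, f_minus = alpha * w),
    symmetric = list(f_plus = w * (1 - w), f_minus = alpha * w * (1 - w)),
    corticostriatal = if (dopamine_sign >= 0) {
      list(f_plus = 1 - w, f_minus = alpha * w)
    } else {
      list(f_plus = alpha * w, f_minus = 1 - w)
    },
    stop("unknown plasticity rule: ", rule)
  )
}

#' Instantaneous weight derivative
#'
#' Evaluates `dw/dt = lambda * D * (f_plus * E_plus - f_minus * E_minus)`
#' with the scaling factors of the chosen rule.  For the corticostriatal rule
#' the factor assignment is chosen by the sign of the dopamine signal `D`.
#'
#' @param rule Plasticity rule id.
#' @param w Weight(s) in \[0, 1\].
#' @param E_plus,E_minus Non-negative eligibility traces.
#' @param D Dopamine level relative to baseline (may be negative).
#' @param alpha Asymmetry factor.
#' @param lambda Learning rate.
#' @return Numeric derivative(s) of the weight(s).
#' @examples
#' weight_derivative("corticostriatal", 0.5, E_plus = 2, E_minus = 0,
#'                   D = 1, alpha = 1, lambda = 0.01)  # 0.01
#' @export
weight_derivative <- function(rule, w, E_plus, E_minus, D, alpha, lambda) {
  if (any(E_plus < 0) || any(E_minus < 0)) {
    stop("eligibility traces must be non-negative")
  }
  f <- scaling_factors(rule, w, alpha, dopamine_sign = sign(D) + (D == 0))
  lambda * D * (f$f_plus * E_plus - f$f_minus * E_minus)
}
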