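---
title: "Dopamine-modulated STDP rules in action-selection and value-estimation tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dopamine-modulated STDP rules in action-selection and value-estimation tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dastdp)
```

## The model

`dastdp` simulates plasticity at corticostriatal synapses onto D1-receptor
spiny projection neurons, where synaptic change depends on three factors:
presynaptic spike timing, postsynaptic spike timing, and a dopamine signal
carrying a reward prediction error (RPE).

N presynaptic units fire as independent Poisson processes with rates
$r_i$.  The postsynaptic unit is a linear Poisson neuron: each presynaptic
spike at time $t$ triggers a postsynaptic spike at $t + \epsilon$ with
probability $w_i/N$, so the postsynaptic rate is
$R(t) = \langle w, \rho^{pre}(t - \epsilon)\rangle / N$.  Spike timing is
tracked by exponentially decaying traces $A^{pre}_i$ and $A^{post}$ (time
constant $\tau$).  Spike *pairs* feed two independent eligibility traces
per synapse (time constant $\tau_{eli}$): $E^+_i$ accumulates
$A^{pre}_i$ at postsynaptic spikes (pre-before-post pairings) and $E^-_i$
accumulates $A^{post}$ at presynaptic spikes (post-before-pre).  Because
the traces are independent and linear, non-interacting spike pairs
contribute additively — a property the test suite checks directly on
constructed spike trains.

Dopamine is released periodically (rate $r_{dop}$) as an impulse $D_k$ on a
level $D(t)$ that decays with $\tau_{dop}$ and is interpreted relative to
baseline, so $D$ can be negative.  Weights evolve as

$$\dot w_i = \lambda\, D(t)\,\bigl[f_+(w_i)\,E^+_i(t) - f_-(w_i)\,E^-_i(t)\bigr],$$

clipped to $[0,1]$ after every step.  The rules differ only in the scaling
factors:

| rule            | $f_+$    | $f_-$          | note |
|-----------------|----------|----------------|------|
| additive        | $1$      | $\alpha$       | unbounded without clipping |
| multiplicative  | $1-w$    | $\alpha w$     | fails to bound weights once $D$ can change sign; kept for completeness, excluded from analysis |
| symmetric       | $w(1-w)$ | $\alpha w(1-w)$| bounds weights; can freeze near 0 and 1 |
| corticostriatal | $1-w$ or $\alpha w$ | the other | factor tied to the *direction* of change, i.e. to $\mathrm{sign}(D)$ |

## Task settings

**Action selection.** Two channels with identical input rates compete.
Postsynaptic spikes are counted in a window $T_{win}$; the action with the
larger count wins ($\beta = 10^6$ acts as an exact count comparison with a
uniform tie-break, implemented through the logistic kernel, which
saturates exactly at this $\beta$).  The dopamine impulse is the RPE
$D = R^* - (R_1^* E[p] + R_2^*(1 - E[p]))$, released $T_{del}$ after the
window; $E[p]$ is the analytic expectation of the choice probability over
the Poisson count distributions (`expected_p()`, a truncated double sum
with truncation at mean $+ 12\sqrt{\text{mean}} + 20$, error far below
1e-10).  Between windows the selected channel keeps a fraction
$a_{sel}$ of its input rate while the other is silenced — this sustained
activity is what carries eligibility across the delay and solves temporal
credit assignment.  The cycle length is $1/r_{dop}$ and must fit
$T_{win} + T_{del}$; `sim_params()` enforces this.

**Value estimation.** A single channel with constant input.  The windowed
count estimates the delivered value, $\bar R = \hat n / T_{win}$, and
$D = R^* - \bar R$.  Action choice is abstract: a preference difference
$\bar R_{diff}$ integrates $\dot{\bar R}_{diff} = \bar\lambda D(t) \bar A(t)$
continuously ($\bar A = \pm 1$ for the previous action), and
$p = \mathrm{logit}^{-1}(\beta \bar R_{diff})$.  `p_init = 0.5` is realised
as $\bar R_{diff} = 0$.  The action is sampled once per cycle, at the end
of the count window, before dopamine arrives.

## Default parameters

Defaults are set per task (action selection / value estimation):
$\lambda = 0.01/0.001$, $\bar\lambda = 0.0025$, $\alpha = 1$,
$\tau = 0.02$ s (STDP window; intermediate between measured LTP and LTD
decay constants), $\tau_{eli} = 1$ s (experimentally derived eligibility
persistence), $\tau_{dop} = 1$ s (a 0.72 s striatal dopamine half-life
converted to an exponential time constant, `tau_from_half_life(0.72)`),
$T_{win} = 1$ s, $T_{del} = 10/3$ s, $r_{dop} = 1/21$ and $1/7$ s$^{-1}$,
$r = 10$ s$^{-1}$ (cortical input to striatum), rewards $(2, 1)$ and
$(7.5, 2.5)$, $\beta = 10^6/1$, $a_{sel} = 0.7$, $w_{init} = p_{init} =
0.5$ (unbiased midpoints).  $1/r_{dop}$ is long enough that successive
dopamine impulses interact negligibly (residual $e^{-7}$ per cycle).

## Averaged (mean-field) systems

For the additive and symmetric rules the dopamine factor can be averaged
out when $T_{del} \gg \tau_{eli}$, giving closed drift systems
(`drift_action_selection()`, `drift_value_estimation()`) whose per-synapse
bracket splits into an independent-pairs term
$\tau \langle w, r\rangle\, \Delta f(w_i)\, r_i$ and a causal-pair term
$f_+(w_i) w_i r_i$.  The corticostriatal rule admits a closed system only
in the action-selection setting; in value estimation its weight drift is
estimated by `monte_carlo_drift()` (independent single-cycle simulations
from a fixed state).

Key closed forms exposed by the package:

* `threshold_alpha()` — the critical asymmetry:
  $1 + 1/(a_{sel}\tau\|r\|_1)$ for action selection (8.14 at defaults,
  4.57 for $r = (15, 5)$) and $1 + 1/(\tau\|r\|_1)$ for value estimation
  (6 at defaults).  Above it, the additive/symmetric flow reverses and the
  task is learned incorrectly.
* `corticostriatal_equilibrium()` — the attracting pair
  $w_1^* = (s+1)/(s(1+\alpha)+1)$, $w_2^* = s/(s(1+\alpha)+\alpha)$ with
  $s = a_{sel}\tau\|r\|_1$; always $w_1^* > w_2^*$, so the better action
  is preferred for every $\alpha$.
* `stability_condition()` — the single nonzero eigenvalue on the accurate
  value-estimation hyperplanes $\langle w,r\rangle/N = R^*$ is negative
  iff $\sum_i r_i^2(\tau N R^* \Delta f(w_i) + f_+(w_i) w_i) > 0$.

`find_equilibria()` assembles the catalogue for $N = 1$ (both settings are
then 2-D fields): closed-form points, Newton-polished numeric zeros
(21-point grid seeding per axis, drift norm below 1e-10, deduplication at
1e-4), and *clipped pseudo-equilibria* — boundary points that are not
zeros of the drift but accumulate trajectories because weights are
clipped.  These are detected as face zeros of the tangential flow with
attracting slope and outward normal drift, plus corners whose inset flow
points into the corner (needed because the clipped corner of the additive
action-selection system lies on an invariant axis where one component
vanishes identically).  Points are classified by central-difference
Jacobians (step 1e-6, one-sided at the boundary); an eigenvalue below
1e-3 of the spectral scale is treated as a center direction.  Degenerate
(quadratically flat) symmetric-rule corners are labelled
`center-manifold`/`degenerate` rather than forced into a hyperbolic class.

## Numerical scheme

The engine advances on a fixed grid, `dt = 1 ms` by default, with *exact*
exponential decay factors per step (all time constants are at least 20 ms,
so `dt/tau <= 0.05`).  Within a bin the order is fixed: decay →
presynaptic events → delivery of postsynaptic spikes whose synaptic delay
expires → dopamine release (the Euler weight step in that bin already sees
the post-release level, so the impulse integrates from the release bin
onward) → Euler weight step at the pre-update weight, then clipping.
Poisson bin counts may exceed one; each presynaptic spike is thinned
independently, and in-flight postsynaptic spikes ride a ring buffer so the
delay $\epsilon$ (an exact multiple of `dt`) is preserved across phase
boundaries.  A causal pre→post pair therefore credits $E^+$ with
$e^{-\epsilon/\tau}$ of the presynaptic trace (0.95 at defaults, 0.78 at
$\epsilon = 5$ ms); the drift functions expose `attenuate = TRUE` to carry
this factor on the causal-pair term, and the printed idealised forms
(attenuation 1) remain the default.  The compiled core consumes R's RNG,
so every run is bit-reproducible from `set.seed()`; ensembles derive one
stream per trial (`seed + trial - 1`).  A pure-R re-implementation of the
loop, consuming the RNG in the same order, serves as an exactness oracle
in the tests.

Averaged ODE trajectories use an adaptive integrator (relative tolerance
1e-8) with the flow projected onto the unit box to mimic clipping.

## Monte-Carlo drift probes

`monte_carlo_drift()` measures the mean weight change caused by a single
dopamine release from a fixed state.  In the value-estimation protocol the
traces are first equilibrated under constant input for $5\tau_{eli}$
(weights cannot move during burn-in because $D$ is exactly zero) and the
post-release tail extends to at least $6\tau_{dop}$, so the full impulse
integral is captured within the sample; in the periodic task simulation
the residual is instead carried into the next cycle.  The zero crossing of
the mean drift sits where $w r$ equals the mean delivered reward —
$w \approx 0.5$ at defaults with $p$ held at 0.5.

Two systematic effects matter when comparing the probe against the
averaged drift, and both are properties of the comparison rather than of
either object alone.  First, the averaged expressions are continuous-time
first-order (linear-response) formulas: the weight-dependent symmetric
rule acquires a second-order-in-$\lambda$ feedback because $f(w)$ moves
with $w$ within a release (about +3% at $w = 0.8$ at the default
$\lambda$), and the Euler binning contributes an $O(dt)$ trace bias of
order 1%, which is further amplified wherever the net eligibility
$E^+ - \alpha E^-$ is a fine cancellation (large $\alpha$).  The
equivalence tests therefore run at a finer step (`dt = 0.5 ms`), at the
default $\alpha = 1$, and at a reduced $\lambda$ for the symmetric rule,
i.e. in the regime the mean-field derivation describes; task simulations
keep the standard parameters.  Second, at $T_{del}$ comparable to
$\tau_{eli}$ a residual negative correlation between the dopamine value
and the eligibility survives ($e^{-T_{del}/\tau_{eli}}$), which is the
undershoot visible when the delay is removed entirely.

## What the tests show — and what they cannot

All inputs are synthetic by construction (the generator *is* the model's
environment): homogeneous Poisson inputs, deterministic rewards, periodic
dopamine timing independent of spiking.  Conclusions therefore concern
the model, not biological recordings: no correlated presynaptic input, no
D2-type (sign-reversed) plasticity, no ramping dopamine time courses, no
probabilistic rewards.  Within that scope the suite verifies the engine
against a pure-R oracle, the analytic drift against Monte-Carlo
simulation, the equilibrium catalogue and stability classes against the
closed forms, and the task-level phenomena: threshold reversal of the
additive/symmetric flow, corticostriatal convergence to
$(w_1^*, w_2^*)$, fast corticostriatal recovery after contingency
switches versus symmetric freezing, the sustained-activity rescue of
learning at long delays, and corticostriatal misestimation of value.

Problem sizes in the test suite are chosen to keep the full run in a few
minutes on one core: ensembles of 5–20 trials, 150–1000 cycles,
800–2000 Monte-Carlo samples per probe point; the full-scale protocols
(100 trials; 10000 samples for drift curves) are available by raising the
corresponding arguments.

## Known limitations

* The approach of $p$ to 1 in the value-estimation task is algebraic
  (center-manifold flow, $\dot p \propto (1-p)^2$), so at the default
  1000-cycle horizon the ensemble sits near $p \approx 0.95$ and the
  stationary predicted value tracks $pR_1^* + (1-p)R_2^*$, a few percent
  below $R_1^*$.  This is a property of the model at that horizon, not a
  simulator artefact; longer runs close the gap slowly.
* Equilibrium search and classification are restricted to $N = 1$; for
  $N > 1$ the accurate-estimation equilibria form hyperplanes and only
  representative closed-form points are meaningful.
* The corticostriatal value-estimation drift has no closed form here; its
  interior equilibria can be located only statistically through
  `monte_carlo_drift()`.
* Euler integration at `dt = 1 ms` carries ~1% trace bias; halve `dt`
  where precision matters more than speed.
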