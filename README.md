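# dastdp

Simulation and mean-field analysis of dopamine-modulated
spike-timing-dependent plasticity (STDP) at corticostriatal synapses.

Reward learning in the basal ganglia is thought to rely on three-factor
plasticity: changes at cortex→striatum synapses depend on pre/post spike
timing *and* on dopamine, which carries a reward prediction error (RPE).
This package implements three candidate plasticity rules — **additive**
(f₊ = 1, f₋ = α), **symmetric** (f₊ = w(1−w), f₋ = αw(1−w)) and
**corticostriatal** (f₊ = 1−w when the weight increases, αw when it
decreases, the branch set by sign(D)) — on linear Poisson neurons with
paired eligibility traces E⁺/E⁻ and weight dynamics

    dw/dt = λ · D(t) · [ f₊(w) E⁺(t) − f₋(w) E⁻(t) ],   w clipped to [0, 1].

Two task environments exercise the rules in the roles striatal neurons are
believed to play:

* **action selection** — two competing channels; windowed spike counts
  pick the action, dopamine is the RPE against an analytic expected
  reward, and sustained activity (a_sel) in the selected channel bridges
  the release delay;
* **value estimation** — one channel whose windowed output rate *is* the
  predicted value, D = R* − R̄, with an abstract softmax action
  preference.

Alongside the stochastic simulator, the package provides the averaged
(mean-field) drift systems for both settings, closed-form equilibria and
stability thresholds, a numerical equilibrium catalogue with Jacobian
classification (including the clipped pseudo-equilibria created by weight
clipping), Monte-Carlo single-release drift probes, and the figure-level
experiments (phase portraits, contingency switching, delay sweeps).

For whom: computational neuroscientists studying reinforcement learning
in cortico-basal-ganglia circuits, and anyone needing a carefully tested
reference implementation of three-factor STDP with eligibility traces.

## Worked example

```r
library(dastdp)

p <- sim_params("action_selection", "corticostriatal")
p
#> <dastdp_params>
#>   setting: action_selection   rule: corticostriatal
#>   N = 1 input(s) per channel at rates (10) /s
#>   alpha = 1, lambda = 0.01, tau = 0.02 s, tau_eli = 1 s, tau_dop = 1 s
#>   cycle 1/r_dop = 21 s (T_win = 1 s, T_del = 10 s), rewards (2, 1)

# critical asymmetry above which additive/symmetric learning reverses
threshold_alpha("action_selection", sim_params("action_selection", "additive"))
#> [1] 8.142857

# the corticostriatal attractor: the rewarded channel ends high, the other
# low, for every alpha
unlist(corticostriatal_equilibrium(p))
#>       w1       w2
#> 0.890625 0.109375

# value estimation with the additive rule: the predicted value w*r climbs
# toward the larger reward (7.5) as the preference p approaches 1
pv <- sim_params("value_estimation", "additive", n_steps = 300)
ens <- run_ensemble(pv, 5, seed = 1)
fin <- ens[ens$step == 299, ]
round(c(mean_w = mean(fin$w), sd_w = sd(fin$w), mean_p = mean(fin$p)), 3)
#> mean_w   sd_w mean_p
#>  0.658  0.020  0.827

# the equilibrium catalogue for that system
find_equilibria(pv)[, c("w", "p", "kind", "classification")]
#>      w    p     kind  classification
#> 1 0.75 1.00 analytic center-manifold
#> 2 0.25 0.00 analytic center-manifold
#> 3 0.00 0.00 analytic          saddle
#> 4 0.00 0.25 analytic        unstable
#> 5 0.00 1.00 analytic          saddle
```

After 300 of 1000 cycles the ensemble is en route to the accurate
equilibrium (w, p) = (0.75, 1): the weight has climbed from 0.5 to ~0.66
with small across-trial spread while p rises toward 1.  The catalogue
shows why: the accurate-estimation points are attracting in the weight
direction with a slow center-manifold flow carrying p toward 1, while the
w = 0 line repels.

A thin command-line front end over the same functions is installed at
`inst/scripts/dastdp.R` (`run`, `analyze`, `field`, `probe` subcommands).

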