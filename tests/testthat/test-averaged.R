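p_as <- sim_params("action_selection", "additive")
p_ve <- sim_params("value_estimation", "additive")

test_that("action-selection drift has the expected structure", {
  # all-zero weights are an equilibrium for every rule
  for (rule in c("additive", "symmetric", "corticostriatal")) {
    d <- drift_action_selection(rule, 0, 0, p_as)
    expect_equal(c(d$dw1, d$dw2), c(0, 0))
  }
  # symmetric rule: w = 1 is an equilibrium too
  d <- drift_action_selection("symmetric", 1, 1, p_as)
  expect_equal(c(d$dw1, d$dw2), c(0, 0))
  # from the unbiased start the rewarded channel grows, the other shrinks
  d <- drift_action_selection("additive", 0.5, 0.5, p_as)
  expect_gt(d$dw1, 0)
  expect_lt(d$dw2, 0)
  expect_error(drift_action_selection("multiplicative", 0.5, 0.5, p_as),
               "multiplicative")
})

test_that("corticostriatal equilibrium matches the closed forms and limits", {
  p <- sim_params("action_selection", "corticostriatal")
  eq <- corticostriatal_equilibrium(p)
  expect_equal(eq$w1, 1.14 / 1.28)   # 0.890625 at the defaults
  expect_equal(eq$w2, 0.14 / 1.28)   # 0.109375
  expect_gt(eq$w1, eq$w2)
  # it is a zero of the averaged drift
  d <- drift_action_selection("corticostriatal", eq$w1, eq$w2, p)
  expect_equal(c(d$dw1, d$dw2), c(0, 0), tolerance = 1e-12)
  # alpha -> infinity: both components collapse to 0
  p_big <- sim_params("action_selection", "corticostriatal", alpha = 1e9)
  eq_big <- corticostriatal_equilibrium(p_big)
  expect_lt(max(eq_big$w1, eq_big$w2), 1e-6)
  # a_sel*tau*||r||_1 -> 0 limit: (1, 0)
  p_small <- sim_params("action_selection", "corticostriatal",
                        rates = 1e-9)
  eq_small <- corticostriatal_equilibrium(p_small)
  expect_equal(c(eq_small$w1, eq_small$w2), c(1, 0), tolerance = 1e-6)
})

test_that("critical alpha values match the analytic conditions", {
  expect_equal(threshold_alpha("action_selection", p_as), 1 + 1 / 0.14)
  p2 <- sim_params("action_selection", "additive", n_inputs = 2,
                   rates = c(15, 5))
  expect_equal(threshold_alpha("action_selection", p2), 1 + 1 / 0.28)
  expect_equal(threshold_alpha("value_estimation", p_ve), 6)
})

test_that("value-estimation drift vanishes on the equilibrium families", {
  # zero mean dopamine: <w,r>/N = p*R1 + (1-p)*R2
  for (p_act in c(0.2, 0.6)) {
    w <- (p_act * 7.5 + (1 - p_act) * 2.5) / 10
    d <- drift_value_estimation("additive", w, p_act, p_ve)
    expect_equal(d$dw, 0)
  }
  # p in {0, 1} freezes the probability
  expect_equal(drift_value_estimation("additive", 0.4, 1, p_ve)$dp, 0)
  expect_equal(drift_value_estimation("additive", 0.4, 0, p_ve)$dp, 0)
  # the accurate-estimation point is a full equilibrium
  d <- drift_value_estimation("additive", 0.75, 1, p_ve)
  expect_equal(c(d$dw, d$dp), c(0, 0))
  expect_error(drift_value_estimation("corticostriatal", 0.5, 0.5, p_ve),
               "monte_carlo_drift")
})

test_that("the stability condition reproduces the known sign pattern", {
  # additive, alpha = 1, w = R1/r: S = r^2 * w > 0, stable
  s <- stability_condition(0.75, 7.5, p_ve, rule = "additive")
  expect_true(s$stable)
  expect_equal(s$value, 100 * 0.75)
  # alpha = 7: S = r^2*(tau*R1*(1-7) + 0.75) = -15 < 0, unstable
  p7 <- sim_params("value_estimation", "additive", alpha = 7)
  s7 <- stability_condition(0.75, 7.5, p7, rule = "additive")
  expect_false(s7$stable)
  expect_equal(s7$value, 100 * (0.02 * 7.5 * (1 - 7) + 0.75))
  # at w = 0 the sign flips exactly at alpha = 1
  for (a in c(0.5, 2)) {
    pa <- sim_params("value_estimation", "additive", alpha = a)
    expect_identical(stability_condition(0, 7.5, pa, "additive")$stable,
                     a < 1)
  }
  # consistency with threshold_alpha: flip at 1 + 1/(tau*r) = 6
  for (a in c(5.99, 6.01)) {
    pa <- sim_params("value_estimation", "additive", alpha = a)
    expect_identical(stability_condition(0.75, 7.5, pa, "additive")$stable,
                     a < threshold_alpha("value_estimation", pa))
  }
})

test_that("the action-selection origin is a saddle aligned with the rewards", {
  f <- dastdp:::drift_field_fn(p_as)
  J <- dastdp:::numerical_jacobian(f, c(0, 0))
  # repelling along w1, attracting along w2 when R1 > R2
  expect_gt(J[1, 1], 0)
  expect_lt(J[2, 2], 0)
  # reversed rewards reverse the roles
  p_swap <- sim_params("action_selection", "additive", R1 = 1, R2 = 2)
  J2 <- dastdp:::numerical_jacobian(dastdp:::drift_field_fn(p_swap), c(0, 0))
  expect_lt(J2[1, 1], 0)
  expect_gt(J2[2, 2], 0)
  # symmetric rule: degenerate (quadratic) but with the same one-sided signs
  p_sym <- sim_params("action_selection", "symmetric")
  f_sym <- dastdp:::drift_field_fn(p_sym)
  h <- 1e-3
  expect_gt(f_sym(c(h, 0))[1], 0)
  expect_lt(f_sym(c(0, h))[2], 0)
})

test_that("flow along the center manifold points toward the rewarded p", {
  # on the p = 1, <w,r>/N = R1 family, displacing p inward gives dp > 0
  # when R1 > R2, and dp < 0 when rewards are swapped
  delta <- 1e-3
  d <- drift_value_estimation("additive", 0.75, 1 - delta, p_ve)
  expect_gt(d$dp, 0)
  p_swap <- sim_params("value_estimation", "additive", R1 = 2.5, R2 = 7.5)
  d2 <- drift_value_estimation("additive", 0.25, 1 - delta, p_swap)
  expect_lt(d2$dp, 0)
  # and away from p = 0 when R1 > R2
  d3 <- drift_value_estimation("additive", 0.25, delta, p_ve)
  expect_gt(d3$dp, 0)
})

test_that("monte carlo drift is exact at zero learning rate and scales as CLT", {
  p0 <- sim_params("value_estimation", "additive", lambda = 0)
  set.seed(91)
  mc <- monte_carlo_drift(p0, 0.4, n_samples = 30)
  expect_identical(as.numeric(mc$mean), 0)
  # standard error halves (up to noise) when samples quadruple
  p <- sim_params("value_estimation", "additive")
  set.seed(92)
  mc1 <- monte_carlo_drift(p, 0.4, n_samples = 250)
  set.seed(92)
  mc2 <- monte_carlo_drift(p, 0.4, n_samples = 1000)
  expect_equal(mc2$se / mc1$se, 0.5, tolerance = 0.25)
})

test_that("averaged trajectory tracks the stochastic ensemble", {
  p <- sim_params("value_estimation", "additive", n_steps = 250)
  ens <- run_ensemble(p, 16, seed = 7)
  avg <- averaged_trajectory(p, times = seq(0, 250 / p$r_dop, by = 1 / p$r_dop))
  checkpoints <- c(50, 100, 150, 200, 250)
  for (s in checkpoints) {
    ws <- ens$w[ens$step == s - 1]
    band <- quantile(ws, c(0.25, 0.75))
    w_ode <- avg$w[which.min(abs(avg$time - s / p$r_dop))]
    expect_gte(w_ode, band[[1]] - 0.02)
    expect_lte(w_ode, band[[2]] + 0.02)
  }
})
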