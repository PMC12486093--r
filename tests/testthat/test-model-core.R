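test_that("scaling factors match the rule definitions", {
  f <- scaling_factors("additive", 0.3, alpha = 2, dopamine_sign = 1)
  expect_equal(c(f$f_plus, f$f_minus), c(1, 2))

  f <- scaling_factors("multiplicative", 0.4, alpha = 1, dopamine_sign = 1)
  expect_equal(c(f$f_plus, f$f_minus), c(0.6, 0.4))

  f <- scaling_factors("symmetric", 0, alpha = 5, dopamine_sign = -1)
  expect_equal(c(f$f_plus, f$f_minus), c(0, 0))

  # corticostriatal swaps the factor assignment with the dopamine sign
  f_pos <- scaling_factors("corticostriatal", 0.25, 1, dopamine_sign = 1)
  expect_equal(c(f_pos$f_plus, f_pos$f_minus), c(0.75, 0.25))
  f_neg <- scaling_factors("corticostriatal", 0.25, 1, dopamine_sign = -1)
  expect_equal(c(f_neg$f_plus, f_neg$f_minus), c(0.25, 0.75))

  # the other rules ignore the dopamine sign
  for (rule in c("additive", "multiplicative", "symmetric")) {
    expect_identical(scaling_factors(rule, 0.37, 2.5, 1),
                     scaling_factors(rule, 0.37, 2.5, -1))
  }

  expect_error(scaling_factors("hebbian", 0.5, 1), "unknown")
  expect_error(scaling_factors("additive", 1.2, 1), "\\[0, 1\\]")
})

test_that("weight derivative evaluates lambda*D*(f+E+ - f-E-)", {
  # zero dopamine kills every rule
  for (rule in c("additive", "multiplicative", "symmetric",
                 "corticostriatal")) {
    expect_identical(weight_derivative(rule, 0.4, 1.7, 0.3, D = 0,
                                       alpha = 3, lambda = 0.01), 0)
  }
  # additive with alpha = 1 and equal traces cancels
  expect_equal(weight_derivative("additive", 0.8, 2.3, 2.3, D = 1.5,
                                 alpha = 1, lambda = 0.01), 0)
  # corticostriatal, non-negative dopamine branch
  expect_equal(weight_derivative("corticostriatal", 0.5, 2, 0, D = 1,
                                 alpha = 1, lambda = 0.01), 0.01)
  expect_error(weight_derivative("additive", 0.5, -1, 0, 1, 1, 0.01),
               "non-negative")
})

test_that("derivative is odd in D except for the corticostriatal rule", {
  grid <- expand.grid(w = c(0.1, 0.25, 0.5, 0.9), Ep = c(0, 0.7, 2.1),
                      Em = c(0, 1.3), D = c(0.5, 2))
  for (rule in c("additive", "multiplicative", "symmetric")) {
    for (k in seq_len(nrow(grid))) {
      g <- grid[k, ]
      expect_equal(
        weight_derivative(rule, g$w, g$Ep, g$Em, -g$D, 2, 0.01),
        -weight_derivative(rule, g$w, g$Ep, g$Em, g$D, 2, 0.01))
    }
  }
  # corticostriatal: the branch swap breaks oddness away from the point
  # where 1-w = alpha*w
  odd_fails <- vapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    a <- weight_derivative("corticostriatal", g$w, g$Ep, g$Em, -g$D, 2, 0.01)
    b <- -weight_derivative("corticostriatal", g$w, g$Ep, g$Em, g$D, 2, 0.01)
    abs(a - b) > 1e-12
  }, logical(1))
  expect_true(any(odd_fails))
})

test_that("symmetric rule freezes weights at the bounds", {
  for (w in c(0, 1)) for (D in c(-2, 3)) {
    expect_identical(weight_derivative("symmetric", w, 1.2, 3.4, D, 5, 0.1),
                     0)
  }
})

test_that("sign of the update matches the factor table in every quadrant", {
  set.seed(42)
  for (rep in 1:20) {
    w <- runif(1, 0.05, 0.95)
    alpha <- runif(1, 0.5, 6)
    E <- runif(1, 0.1, 3)
    for (D in c(-1.3, 1.3)) {
      s <- sign(D)
      f <- scaling_factors("corticostriatal", w, alpha, s)
      # positive eligibility only: weight moves with sign(D) under every
      # rule; corticostriatal uses 1-w when increasing, alpha*w when
      # decreasing
      expect_equal(sign(weight_derivative("corticostriatal", w, E, 0,
                                          D, alpha, 0.01)), s)
      expect_equal(weight_derivative("corticostriatal", w, E, 0, D,
                                     alpha, 0.01),
                   0.01 * D * (if (s > 0) 1 - w else alpha * w) * E)
      # negative eligibility only: weight moves against sign(D)
      expect_equal(sign(weight_derivative("corticostriatal", w, 0, E,
                                          D, alpha, 0.01)), -s)
      expect_equal(weight_derivative("corticostriatal", w, 0, E, D,
                                     alpha, 0.01),
                   -0.01 * D * (if (s > 0) alpha * w else 1 - w) * E)
      for (rule in c("additive", "multiplicative", "symmetric")) {
        expect_equal(sign(weight_derivative(rule, w, E, 0, D, alpha, 0.01)),
                     s)
        expect_equal(sign(weight_derivative(rule, w, 0, E, D, alpha, 0.01)),
                     -s)
      }
    }
  }
})

test_that("parameter validation enforces the cycle and domain invariants", {
  expect_error(sim_params("value_estimation", "additive", T_del = 7),
               "cycle too short")
  expect_error(sim_params("value_estimation", "additive", epsilon = 0.0005),
               "multiple of dt")
  expect_error(sim_params("value_estimation", "additive", w_init = 1.5),
               "w_init")
  expect_error(sim_params("value_estimation", "additive", rates = c(5, 5)),
               "length")
  expect_error(sim_params("action_selection", "additive", a_sel = 0),
               "a_sel")
  p <- sim_params("action_selection", "corticostriatal")
  expect_identical(p$n_channels, 2L)
  expect_equal(1 / p$r_dop, 21)
  expect_equal(p$beta, 1e6)
})
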