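# Deterministic drift field as a plain function of the 2-D state.
# Value estimation: x = (w, p); action selection: x = (w1, w2).  N = 1 only.
drift_field_fn <- function(params, rule = params$rule, attenuate = FALSE) {
  if (params$n_inputs != 1L) {
    stop("the 2-D drift field requires a single input per channel (N = 1)")
  }
  if (params$setting == "value_estimation") {
    function(x) {
      d <- drift_value_estimation(rule, x[1], min(1, max(0, x[2])), params,
                                  attenuate = attenuate)
      c(d$dw, d$dp)
    }
  } else {
    function(x) {
      d <- drift_action_selection(rule, x[1], x[2], params,
                                  attenuate = attenuate)
      c(d$dw1, d$dw2)
    }
  }
}

# Central-difference Jacobian on the clipped unit box; one-sided at the
# boundary so the field is never evaluated outside the domain.
numerical_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(NA_real_, n, n)
  for (k in seq_len(n)) {
    lo <- x[k] - h >= 0
    hi <- x[k] + h <= 1
    xp <- x; xm <- x
    if (lo && hi) {
      xp[k] <- x[k] + h; xm[k] <- x[k] - h
      J[, k] <- (f(xp) - f(xm)) / (2 * h)
    } else if (hi) {
      xp[k] <- x[k] + h
      J[, k] <- (f(xp) - f(x)) / h
    } else {
      xm[k] <- x[k] - h
      J[, k] <- (f(x) - f(xm)) / h
    }
  }
  J
}

classify_eigenvalues <- function(eigs) {
  re <- Re(eigs)
  scale <- max(abs(re))
  if (scale < 1e-14) return("degenerate")
  tol <- 1e-3 * scale
  n_pos <- sum(re > tol)
  n_neg <- sum(re < -tol)
  n_zero <- length(re) - n_pos - n_neg
  if (n_zero > 0) "center-manifold"
  else if (n_neg == length(re)) "stable"
  else if (n_pos == length(re)) "unstable"
  else "saddle"
}

newton_root <- function(f, x0, max_iter = 60, tol_step = 1e-13) {
  x <- pmin(1, pmax(0, x0))
  for (it in seq_len(max_iter)) {
    Fx <- f(x)
    J <- numerical_jacobian(f, x)
    step <- tryCatch(solve(J, Fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    x_new <- pmin(1, pmax(0, x - step))
    if (max(abs(x_new - x)) < tol_step) return(x_new)
    x <- x_new
  }
  NULL
}

#' Catalogue the equilibria of an averaged system
#'
#' Assembles the closed-form equilibria of the averaged drift system,
#' augments them with numerically found zeros (Newton iteration seeded on a
#' 21 x 21 grid, polished until the drift norm is below 1e-10, deduplicated),
#' detects clipped pseudo-equilibria -- boundary points that are not zeros of
#' the drift but accumulate trajectories because the weights are clipped to
#' \[0, 1\] -- and classifies every point by the eigenvalues of a
#' central-difference Jacobian.
#'
#' A clipped pseudo-equilibrium is reported at a boundary point where the
#' drift component normal to the face points outward while the tangential
#' flow is attracting (a face zero with negative tangential slope, or a
#' corner with all components outward).
#'
#' Implemented for a single input per channel (N = 1), where both settings
#' reduce to 2-D fields: (w, p) for value estimation and (w1, w2) for action
#' selection.  For the corticostriatal rule in the value-estimation setting
#' the weight drift has no closed form; only the analytic `w = 0` points are
#' returned (their weight-direction dynamics are left unresolved), and
#' [monte_carlo_drift()] can be used to probe the interior.
#'
#' @param params A [sim_params()] object with `n_inputs = 1`.
#' @param rule Plasticity rule (defaults to `params$rule`).
#' @param attenuate Passed to the drift functions.
#' @return A data frame with columns `x1`, `x2` (the state coordinates:
#'   `w, p` or `w1, w2`), `kind` (`analytic`, `numeric`, `clipped-pseudo`),
#'   `classification`, `eig1`, `eig2` (real parts), `drift_norm`.
#' @examples
#' eq <- find_equilibria(sim_params("action_selection", "corticostriatal"))
#' subset(eq, classification == "stable")
#' @export
find_equilibria <- function(params, rule = params$rule, attenuate = FALSE) {
  ve <- params$setting == "value_estimation"
  r1 <- sum(params$rates)
  N <- params$n_inputs
  R1 <- params$R1; R2 <- params$R2

  analytic <- list()
  add_pt <- function(lst, x1, x2) {
    if (x1 >= 0 && x1 <= 1 && x2 >= 0 && x2 <= 1) c(lst, list(c(x1, x2)))
    else lst
  }

  if (ve && rule %in% c("additive", "symmetric")) {
    analytic <- add_pt(analytic, N * R1 / r1, 1)
    analytic <- add_pt(analytic, N * R2 / r1, 0)
    for (pp in c(0, R2 / (R1 + R2), 1)) analytic <- add_pt(analytic, 0, pp)
    if (rule == "symmetric") {
      den <- R1 + R2 - 2 * r1 / N
      if (abs(den) > 1e-12) {
        analytic <- add_pt(analytic, 1, (R2 - r1 / N) / den)
      }
      analytic <- add_pt(analytic, 1, 0)
      analytic <- add_pt(analytic, 1, 1)
    }
  } else if (ve) { # corticostriatal value estimation
    for (pp in c(0, R2 / (R1 + R2), 1)) analytic <- add_pt(analytic, 0, pp)
  } else if (rule %in% c("additive", "symmetric")) {
    analytic <- add_pt(analytic, 0, 0)
    if (rule == "symmetric") {
      analytic <- add_pt(analytic, 1, 0)
      analytic <- add_pt(analytic, 0, 1)
      analytic <- add_pt(analytic, 1, 1)
    }
  } else { # corticostriatal action selection
    ws <- corticostriatal_equilibrium(params)
    analytic <- add_pt(analytic, 0, 0)
    analytic <- add_pt(analytic, ws$w1, ws$w2)
    analytic <- add_pt(analytic, ws$w1, 0)
    analytic <- add_pt(analytic, 0, ws$w2)
  }

  cs_ve <- ve && !rule %in% c("additive", "symmetric")
  f <- if (cs_ve) NULL else drift_field_fn(params, rule, attenuate)

  rows <- list()
  push <- function(x, kind, classification = NULL, eigs = NULL, dn = NA) {
    if (is.null(classification)) {
      J <- numerical_jacobian(f, x)
      eigs <- eigen(J, only.values = TRUE)$values
      classification <- classify_eigenvalues(eigs)
    }
    rows[[length(rows) + 1]] <<- data.frame(
      x1 = x[1], x2 = x[2], kind = kind, classification = classification,
      eig1 = if (is.null(eigs)) NA_real_ else Re(eigs[1]),
      eig2 = if (is.null(eigs)) NA_real_ else Re(eigs[2]),
      drift_norm = dn, stringsAsFactors = FALSE)
  }

  seen <- function(x, tol = 1e-4) {
    any(vapply(rows, function(r) max(abs(c(r$x1, r$x2) - x)) < tol,
               logical(1)))
  }

  for (pt in analytic) {
    if (cs_ve) {
      push(pt, "analytic", classification = "unresolved")
    } else {
      push(pt, "analytic", dn = sqrt(sum(f(pt)^2)))
    }
  }
  if (cs_ve) {
    out <- do.call(rbind, rows)
    names(out)[1:2] <- c("w", "p")
    return(out)
  }

  # grid-seeded Newton search for zeros missed by the catalogue
  grid <- seq(0.05, 0.95, length.out = 19)
  for (g1 in grid) for (g2 in grid) {
    root <- newton_root(f, c(g1, g2))
    if (is.null(root)) next
    dn <- sqrt(sum(f(root)^2))
    if (dn < 1e-10 && !seen(root)) push(root, "numeric", dn = dn)
  }

  # clipped pseudo-equilibria on the four faces and corners
  out_dir <- function(x) { # outward drift components at the boundary
    d <- f(x)
    (x <= 0 & d < 0) | (x >= 1 & d > 0)
  }
  faces <- list(list(fix = 1, val = 0), list(fix = 1, val = 1),
                list(fix = 2, val = 0), list(fix = 2, val = 1))
  tgrid <- seq(0.02, 0.98, length.out = 49)
  for (fc in faces) {
    tang <- 3 - fc$fix
    g <- function(t) {
      x <- numeric(2); x[fc$fix] <- fc$val; x[tang] <- t
      f(x)[tang]
    }
    vals <- vapply(tgrid, g, numeric(1))
    sgn <- sign(vals)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (k in idx) {
      rt <- tryCatch(stats::uniroot(g, c(tgrid[k], tgrid[k + 1]),
                                    tol = 1e-12),
                     error = function(e) NULL)
      if (is.null(rt)) next
      # attracting along the face, outward across it
      slope <- (g(min(1, rt$root + 1e-6)) - g(max(0, rt$root - 1e-6))) /
        (min(1, rt$root + 1e-6) - max(0, rt$root - 1e-6))
      x <- numeric(2); x[fc$fix] <- fc$val; x[tang] <- rt$root
      dn <- sqrt(sum(f(x)^2))
      if (slope < 0 && out_dir(x)[fc$fix] && dn > 1e-10 && !seen(x)) {
        push(x, "clipped-pseudo", classification = "attracting-boundary",
             dn = dn)
      }
    }
  }
  # corners: clipped accumulation points where the flow just inside points
  # into the corner in every coordinate (the corner itself may sit on an
  # invariant axis where one drift component vanishes identically)
  for (c1 in c(0, 1)) for (c2 in c(0, 1)) {
    x <- c(c1, c2)
    dn <- sqrt(sum(f(x)^2))
    if (dn <= 1e-10 || seen(x)) next
    delta <- 1e-3
    inset <- ifelse(x > 0.5, x - delta, x + delta)
    d_in <- f(inset)
    toward <- ifelse(x > 0.5, d_in > 0, d_in < 0)
    if (all(toward)) {
      push(x, "clipped-pseudo", classification = "attracting-boundary",
           dn = dn)
    }
  }

  out <- do.call(rbind, rows)
  names(out)[1:2] <- if (ve) c("w", "p") else c("w1", "w2")
  out
}

#' Integrate the averaged drift system
#'
#' Solves the mean-field ODE with an adaptive integrator (relative tolerance
#' 1e-8), projecting the flow onto the unit box so boundary clipping is
#' respected.  These deterministic trajectories are the grey reference
#' curves overlaid on the stochastic phase portraits.
#'
#' @param params A [sim_params()] object with `n_inputs = 1`.
#' @param init Initial state `c(w, p)` (value estimation) or `c(w1, w2)`
#'   (action selection); defaults to the configured initial values.
#' @param times Output times (s); defaults to 200 points spanning
#'   `n_steps / r_dop` seconds.
#' @param rule,attenuate Passed to the drift functions.
#' @return A data frame with a `time` column and the two state coordinates.
#' @export
averaged_trajectory <- function(params, init = NULL, times = NULL,
                                rule = params$rule, attenuate = FALSE) {
  f <- drift_field_fn(params, rule, attenuate)
  ve <- params$setting == "value_estimation"
  if (is.null(init)) {
    init <- if (ve) c(params$w_init, params$p_init)
            else c(params$w_init, params$w_init)
  }
  if (is.null(times)) {
    times <- seq(0, params$n_steps / params$r_dop, length.out = 200)
  }
  deriv <- function(t, y, parms) {
    y <- pmin(1, pmax(0, y))
    d <- f(y)
    d[y <= 0 & d < 0] <- 0
    d[y >= 1 & d > 0] <- 0
    list(d)
  }
  sol <- deSolve::ode(y = init, times = times, func = deriv, parms = NULL,
                      rtol = 1e-8, atol = 1e-12)
  out <- as.data.frame(sol)
  names(out) <- c("time", if (ve) c("w", "p") else c("w1", "w2"))
  out
}

#' Evaluate the averaged drift on a grid
#'
#' @param params A [sim_params()] object with `n_inputs = 1`.
#' @param n_grid Grid points per axis.
#' @param rule,attenuate Passed to the drift functions.
#' @return A data frame with the grid coordinates and the two drift
#'   components `d1`, `d2`.
#' @export
vector_field <- function(params, n_grid = 21, rule = params$rule,
                         attenuate = FALSE) {
  f <- drift_field_fn(params, rule, attenuate)
  g <- seq(0, 1, length.out = n_grid)
  pts <- expand.grid(x1 = g, x2 = g)
  d <- t(apply(pts, 1, f))
  out <- cbind(pts, d1 = d[, 1], d2 = d[, 2])
  ve <- params$setting == "value_estimation"
  names(out)[1:2] <- if (ve) c("w", "p") else c("w1", "w2")
  out
}
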