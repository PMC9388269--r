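# Shared fixtures and independent numerical oracles.

# Minimal racism-only toy set: R_r = 2, endemic point (5, 3.3333, 1.6667).
toy_racism <- function() {
  coex_parameters(Lambda = 1, mu = 0.1, alpha = 0.04, beta = 0,
                  gamma2 = 0.1, theta2 = 0.1,
                  gamma1 = 0, gamma3 = 0, sigma1 = 0, sigma2 = 0,
                  theta1 = 0, theta3 = 0, eta = 1, xi = 1)
}

# Corruption-only mirror: R_c = 2.
toy_corruption <- function() {
  coex_parameters(Lambda = 1, mu = 0.1, beta = 0.4, alpha = 0,
                  gamma1 = 0.1, theta1 = 0.1,
                  gamma2 = 0, gamma3 = 0, sigma1 = 0, sigma2 = 0,
                  theta2 = 0, theta3 = 0, eta = 1, xi = 1)
}

# Random valid parameter draw; rates on scales spanning the reference set.
rand_params <- function() {
  coex_parameters(
    Lambda = runif(1, 0.5, 100), mu = runif(1, 0.005, 0.5),
    alpha = 10^runif(1, -7, -2), beta = runif(1, 0, 2),
    omega1 = runif(1, 1, 3), omega2 = runif(1, 1, 3),
    eta = runif(1, 0.5, 2), xi = runif(1, 0.5, 2),
    sigma1 = runif(1, 0, 1), sigma2 = runif(1, 0, 1),
    gamma1 = runif(1, 0, 0.5), gamma2 = runif(1, 0, 0.5),
    gamma3 = runif(1, 0, 0.5),
    theta1 = runif(1, 0, 0.5), theta2 = runif(1, 0, 0.5),
    theta3 = runif(1, 0, 0.5))
}

rand_state <- function(scale = 100) {
  coex_state(S = runif(1, 0, scale), C = runif(1, 0, scale),
             R = runif(1, 0, scale), C1 = runif(1, 0, scale),
             R1 = runif(1, 0, scale), R2 = runif(1, 0, scale),
             R3 = runif(1, 0, scale))
}

# Central-difference Jacobian oracle, step h = 1e-6 * max(1, |x_j|).
fd_jacobian <- function(model, state, params) {
  idx <- match(model_compartments(model), names(state))
  cols <- lapply(idx, function(j) {
    h <- 1e-6 * max(1, abs(state[j]))
    xp <- state; xm <- state
    xp[j] <- state[j] + h
    xm[j] <- state[j] - h
    d <- (coex_rhs(model, xp, params) - coex_rhs(model, xm, params)) / (2 * h)
    d[idx]
  })
  do.call(cbind, cols)
}

# Independent scalar oracle for the submodel endemic force of infection:
# for a fixed force lambda the equilibrium conditions of the three active
# compartments are linear; solve them with solve() and return the
# self-consistency gap g(lambda) = (force implied by the state) - lambda.
# Endemic equilibria are the positive roots of g.
submodel_force_gap <- function(model, params) {
  p <- params
  if (model == "racism") {
    function(lam) {
      A <- rbind(c(-(lam + p[["mu"]]), 0, p[["theta2"]]),
                 c(lam, -(p[["gamma2"]] + p[["mu"]]), 0),
                 c(0, p[["gamma2"]], -(p[["theta2"]] + p[["mu"]])))
      st <- solve(A, c(-p[["Lambda"]], 0, 0))   # (S, R, R2)
      p[["alpha"]] * st[2] - lam
    }
  } else {
    function(lam) {
      A <- rbind(c(-(lam + p[["mu"]]), 0, p[["theta1"]]),
                 c(lam, -(p[["gamma1"]] + p[["mu"]]), 0),
                 c(0, p[["gamma1"]], -(p[["theta1"]] + p[["mu"]])))
      st <- solve(A, c(-p[["Lambda"]], 0, 0))   # (S, C, R1)
      p[["beta"]] * st[2] / sum(st) - lam
    }
  }
}

# Grid + bisection root search for the oracle above; returns all positive
# roots found on (0, lam_max].
force_gap_roots <- function(gap, lam_max, n_grid = 4000) {
  grid <- seq(lam_max / n_grid, lam_max, length.out = n_grid)
  vals <- vapply(grid, gap, numeric(1))
  roots <- c()
  for (i in seq_len(n_grid - 1)) {
    if (is.finite(vals[i]) && is.finite(vals[i + 1]) &&
        sign(vals[i]) != sign(vals[i + 1]) && vals[i] != 0) {
      r <- uniroot(gap, c(grid[i], grid[i + 1]), tol = 1e-14)$root
      roots <- c(roots, r)
    }
  }
  roots
}
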