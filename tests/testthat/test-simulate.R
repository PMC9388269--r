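test_that("pure demographic decay follows the closed form", {
  p <- coex_parameters(Lambda = 1e-9, mu = 0.05, alpha = 0, beta = 0,
                       eta = 1, xi = 1, gamma1 = 0.1, gamma2 = 0.1,
                       gamma3 = 0.1, sigma1 = 0.2, sigma2 = 0.2,
                       theta1 = 0.1, theta2 = 0.1, theta3 = 0.1)
  init <- coex_state(1, 1, 1, 1, 1, 1, 1)
  tr <- coex_integrate("full", p, init = init, t_end = 40, n_out = 80)
  N <- rowSums(tr$states)
  expect_equal(N, 7 * exp(-0.05 * tr$times), tolerance = 1e-6)
})

test_that("subthreshold contagion dies out and the population stays in Omega", {
  p <- reference_parameters(alpha = 1e-6, beta = 0.005)  # R_rc < 1
  tr <- coex_integrate("full", p, t_end = 2000, n_out = 200)
  term <- tr$states[nrow(tr$states), ]
  expect_lt(max(term[c("C", "R", "C1")]), 1e-6)
  cap <- p[["Lambda"]] / p[["mu"]]
  N <- rowSums(tr$states)
  expect_true(all(N <= max(N[1], cap) * (1 + 1e-6)))
  expect_true(all(tr$states >= 0))
  expect_gte(tr$diagnostics$min_pre_clip, -1e-9)
})

test_that("a population starting at carrying capacity stays there", {
  p <- reference_parameters(alpha = 1e-6, beta = 0.01)
  tr <- coex_integrate("full", p, t_end = 500, n_out = 100)
  N <- rowSums(tr$states)
  expect_equal(N, rep(5000, length(N)), tolerance = 1e-6)
})

test_that("supercritical dynamics settle on the root-found coexistence equilibrium", {
  sc <- scenario(3, "supercritical")
  tr <- coex_integrate("full", sc$params, init = sc$init, t_end = 20000, n_out = 200)
  term <- tr$states[nrow(tr$states), ]
  expect_gt(min(term[c("C", "R", "C1")]), 1e-3)  # persistence above threshold
  res <- coexistence_endemic_equilibrium(sc$params, guess = term, seed = 3)
  expect_true(res$found)
  expect_lt(max(abs(term - res$point$state) / pmax(abs(res$point$state), 1e-8)),
            1e-4)
})

test_that("tightening solver tolerances leaves the terminal state unchanged", {
  sc <- scenario(9, "supercritical")
  t1 <- coex_integrate("full", sc$params, init = sc$init, t_end = 500, n_out = 50)
  t2 <- coex_integrate("full", sc$params, init = sc$init, t_end = 500, n_out = 50,
                       rtol = 1e-9, atol = 1e-11)
  a <- t1$states[nrow(t1$states), ]
  b <- t2$states[nrow(t2$states), ]
  expect_lt(max(abs(a - b) / pmax(abs(b), 1)), 1e-6)
})

test_that("steady-state detection accepts constants, converged decay, and rejects oscillations", {
  p <- reference_parameters(alpha = 0, beta = 0)
  cap <- p[["Lambda"]] / p[["mu"]]
  tr <- coex_integrate("full", p, init = coex_state(S = cap), t_end = 100, n_out = 50)
  ss <- steady_state(tr, window = 20, tol = 1e-6)
  expect_true(ss$converged)
  expect_equal(ss$state[["S"]], cap, tolerance = 1e-8)

  # exponential decay at rate mu = 1: converged once the window tail is tiny
  pd <- coex_parameters(Lambda = 1e-12, mu = 1, alpha = 0, beta = 0, eta = 1, xi = 1,
                        gamma1 = 0, gamma2 = 0, gamma3 = 0, sigma1 = 0, sigma2 = 0,
                        theta1 = 0, theta2 = 0, theta3 = 0)
  trd <- coex_integrate("full", pd, init = coex_state(1, 1, 1, 1, 1, 1, 1),
                        t_end = 40, n_out = 200)
  ssd <- steady_state(trd, window = 10, tol = 1e-6)
  expect_true(ssd$converged)
  expect_lt(max(ssd$state), 1e-10)

  # synthetic oscillation injected into the trajectory object
  tro <- trd
  tro$states[, "S"] <- 1 + 0.5 * sin(trd$times)
  sso <- steady_state(tro, window = 10, tol = 1e-6)
  expect_false(sso$converged)

  expect_error(steady_state(trd, window = 100), "window")
})

test_that("scenarios are deterministic in the seed and honor their regime", {
  a <- scenario(1, "subcritical")
  b <- scenario(1, "subcritical")
  expect_identical(a$params, b$params)
  expect_identical(a$init, b$init)
  expect_lt(max(a$R_r, a$R_c), 0.9)

  s <- scenario(5, "supercritical")
  expect_gt(max(s$R_r, s$R_c), 1.1)

  r <- scenario(7, "racism_only")
  expect_identical(r$params[["beta"]], 0)
  expect_gt(r$R_r, 1.1)

  c2 <- scenario(8, "corruption_only")
  expect_identical(c2$params[["alpha"]], 0)
  expect_gt(c2$R_c, 1.1)

  # regime draws do not disturb the global RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(scenario(2, "supercritical")); after <- runif(1)
  expect_identical(before, after)
})

test_that("raising the coexistence recovery rate lowers the settled co-affected class", {
  sc <- scenario(12, "supercritical")
  sw <- gamma3_sweep(sc$params, values = c(0.54, 0.635, 0.73),
                     t_end = 3000, init = sc$init)
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$C1) <= 0))
  expect_lt(sw$C1[3], sw$C1[1])

  # single value: one row; no transmissions: empty co-affected class
  p0 <- reference_parameters(alpha = 0, beta = 0)
  sw0 <- gamma3_sweep(p0, values = 0.6, t_end = 200)
  expect_equal(nrow(sw0), 1)
  expect_lt(sw0$C1, 1e-8)
})
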