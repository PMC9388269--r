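test_that("the full-model Jacobian at the contagion-free point has the closed-form spectrum", {
  p <- reference_parameters(alpha = 1e-6, beta = 0.005)
  dfe <- disease_free_equilibrium("full", p)$state
  ev <- sort(Re(eigen(coex_jacobian("full", dfe, p), only.values = TRUE)$values))
  expect_equal(ev, sort(c(-0.01, -0.012, -0.011, -1.318, -0.31, -0.26, -0.21)),
               tolerance = 1e-10)

  # racism submodel: {-mu, alpha*Lambda/mu - (gamma2+mu), -(theta2+mu)}
  q <- toy_racism()
  dfe_r <- disease_free_equilibrium("racism", q)$state
  evr <- sort(Re(eigen(coex_jacobian("racism", dfe_r, q), only.values = TRUE)$values))
  expect_equal(evr, sort(c(-0.1, 0.04 * 10 - 0.2, -0.2)), tolerance = 1e-12)
})

test_that("the analytic Jacobian agrees with central differences at random states", {
  set.seed(41)
  for (i in 1:40) {
    p <- rand_params()
    st <- rand_state(scale = p[["Lambda"]] / p[["mu"]])
    st <- st + 0.1   # keep away from the clipping region
    for (m in c("full", "racism", "corruption")) {
      J <- coex_jacobian(m, st, p)
      Jfd <- fd_jacobian(m, st, p)
      expect_lt(max(abs(J - Jfd)) / max(1, max(abs(J))), 1e-6)
    }
  }
})

test_that("spectra are classified by the sign pattern of their real parts", {
  expect_identical(classify_local(c(-1, -2, -3)), "asymptotically_stable")
  expect_identical(classify_local(c(-1, 0.5)), "unstable")
  expect_identical(classify_local(complex(real = c(-1, 0), imaginary = c(2, 1)),
                                  zero_tolerance = 1e-8), "marginal")
  expect_error(classify_local(numeric(0)), "empty")
})

test_that("the Routh-Hurwitz cubic verdict matches known root locations", {
  rh <- routh_hurwitz_cubic(1, 6, 11, 6)   # roots -1, -2, -3
  expect_identical(rh$verdict, "stable")
  expect_equal(rh$b1, (6 * 11 - 6) / 6)
  expect_equal(rh$c1, 6)
  expect_true(all(rh$first_column_signs == 1))

  expect_identical(routh_hurwitz_cubic(1, 1, 1, 2)$verdict, "unstable")
  expect_identical(routh_hurwitz_cubic(1, 0, 1, 1)$verdict, "indeterminate")
  expect_error(routh_hurwitz_cubic(0, 1, 1, 1), "a0")
})

test_that("Routh-Hurwitz on the racism-endemic cubic matches the eigenvalue verdict", {
  rep <- stability_report("racism", toy_racism(), point = "endemic")
  expect_identical(rep$classification, "asymptotically_stable")
  expect_identical(rep$routh_hurwitz$verdict, "stable")

  set.seed(42)
  n <- 0
  while (n < 60) {
    p <- rand_params()
    if (reproduction_number("racism", p)$closed_form <= 1.01) next
    n <- n + 1
    er <- racism_endemic_equilibrium(p)
    J <- coex_jacobian("racism", er$state, p)
    cc <- characteristic_cubic(J)
    rh <- routh_hurwitz_cubic(cc[["a0"]], cc[["a1"]], cc[["a2"]], cc[["a3"]])
    ev_stable <- all(Re(eigen(J, only.values = TRUE)$values) < 0)
    expect_identical(rh$verdict, if (ev_stable) "stable" else "unstable")
  }
})

test_that("contagion-free stability is concordant with the reproduction threshold", {
  p_lo <- reference_parameters(alpha = 1e-7, beta = 0.005)
  p_hi <- reference_parameters(alpha = 1e-7, beta = 0.05)
  expect_identical(dfe_stability("corruption", p_lo)$classification,
                   "asymptotically_stable")
  expect_identical(dfe_stability("corruption", p_hi)$classification, "unstable")
  expect_identical(dfe_stability("full", p_lo)$classification,
                   "asymptotically_stable")

  set.seed(43)
  for (i in 1:60) {
    p <- rand_params()
    for (m in c("full", "racism", "corruption")) {
      rn <- reproduction_number(m, p)$closed_form
      if (abs(rn - 1) < 1e-3) next
      verdict <- dfe_stability(m, p)$classification
      expect_identical(verdict,
                       if (rn < 1) "asymptotically_stable" else "unstable",
                       label = sprintf("model %s, R = %g -> %s", m, rn, verdict))
    }
  }
})

test_that("the sampled Lyapunov decay certificate behaves across the threshold", {
  p_sub <- toy_racism(); p_sub[["alpha"]] <- 0.01   # R_r = 0.5
  chk <- lyapunov_gas_check("racism", validate_parameters(p_sub),
                            n_samples = 5000, seed = 1)
  expect_true(chk$pass)
  expect_lte(chk$worst_margin, 1e-10)
  expect_lte(chk$bound_margin, 1e-10)

  q <- toy_corruption(); q[["beta"]] <- 0.18        # R_c = 0.9
  chk2 <- lyapunov_gas_check("corruption", validate_parameters(q),
                             n_samples = 5000, seed = 2)
  expect_true(chk2$pass)
  expect_lte(chk2$bound_margin, 1e-10)

  chk3 <- lyapunov_gas_check("racism", toy_racism(), n_samples = 2000, seed = 3)
  expect_false(chk3$pass)                            # R_r = 2: decay fails
  expect_gt(chk3$worst_margin, 0)
  expect_lte(chk3$bound_margin, 1e-10)               # structural bound still holds

  expect_error(lyapunov_gas_check("full", toy_racism()), "submodel")
})

test_that("subcritical trajectories from random starts in Omega reach the contagion-free point", {
  sc <- scenario(7, "subcritical")
  cap <- sc$params[["Lambda"]] / sc$params[["mu"]]
  set.seed(44)
  for (k in 1:5) {
    g <- rexp(8)
    init <- coex_state(); init[1:7] <- cap * g[1:7] / sum(g)
    tr <- coex_integrate("full", sc$params, init = init, t_end = 20000, n_out = 100)
    term <- tr$states[nrow(tr$states), ]
    expect_lt(max(term[c("C", "R", "C1")]), 1e-5 * cap)
  }
})
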