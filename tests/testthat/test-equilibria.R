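test_that("the contagion-free equilibrium is Lambda/mu susceptibles and a root", {
  eq <- disease_free_equilibrium("full", reference_parameters(alpha = 0.3, beta = 0.9))
  expect_equal(eq$state[["S"]], 5000)
  expect_equal(sum(eq$state[-1]), 0)
  expect_equal(eq$residual, 0)
  eq2 <- disease_free_equilibrium("racism", toy_racism())
  expect_equal(eq2$state[["S"]], 10)
})

test_that("submodel endemic closed forms match the toy values and are roots", {
  er <- racism_endemic_equilibrium(toy_racism())
  expect_equal(er$force_of_infection[["lambda_R"]], 0.1333333, tolerance = 1e-6)
  expect_equal(er$state[["S"]], 5, tolerance = 1e-10)
  expect_equal(er$state[["R"]], 10 / 3, tolerance = 1e-10)
  expect_equal(er$state[["R2"]], 5 / 3, tolerance = 1e-10)
  expect_lt(er$residual, 1e-9)

  ec <- corruption_endemic_equilibrium(toy_corruption())
  expect_equal(ec$force_of_infection[["lambda_C"]], 0.1333333, tolerance = 1e-6)
  expect_equal(ec$state[["S"]], 5, tolerance = 1e-10)
  expect_equal(ec$state[["C"]], 10 / 3, tolerance = 1e-10)
  expect_equal(ec$state[["R1"]], 5 / 3, tolerance = 1e-10)
  expect_lt(ec$residual, 1e-9)
})

test_that("endemic equilibria exist iff the reproduction number exceeds 1", {
  p <- toy_racism(); p[["alpha"]] <- 0.01   # R_r = 0.5
  expect_error(racism_endemic_equilibrium(validate_parameters(p)), "no endemic")
  q <- toy_corruption(); q[["beta"]] <- 0.4; q[["gamma1"]] <- 0.5  # R_c < 1
  expect_error(corruption_endemic_equilibrium(validate_parameters(q)), "no endemic")
})

test_that("the endemic branch is continuous at the threshold", {
  p <- toy_racism()
  p[["alpha"]] <- 0.02 * (1 + 1e-8)   # R_r = 1 + 1e-8
  er <- racism_endemic_equilibrium(validate_parameters(p))
  dfe <- disease_free_equilibrium("racism", p)
  expect_lt(er$force_of_infection[["lambda_R"]], 1e-8)
  expect_equal(er$state, dfe$state, tolerance = 1e-6)
})

test_that("random endemic points are roots, sum to Lambda/mu, and agree with a bisection oracle", {
  set.seed(31)
  n_checked <- 0
  while (n_checked < 40) {
    p <- rand_params()
    rn <- reproduction_number("full", p)
    cap <- p[["Lambda"]] / p[["mu"]]
    if (rn$R_r > 1.01) {
      er <- racism_endemic_equilibrium(p)
      expect_lt(er$residual, 1e-9 * max(1, cap))
      expect_equal(sum(er$state), cap, tolerance = 1e-10)
      roots <- force_gap_roots(submodel_force_gap("racism", p),
                               lam_max = 1.05 * p[["alpha"]] * cap)
      expect_length(roots, 1)
      expect_equal(roots, er$force_of_infection[["lambda_R"]], tolerance = 1e-6)
      n_checked <- n_checked + 1
    }
    if (rn$R_c > 1.01) {
      ec <- corruption_endemic_equilibrium(p)
      expect_lt(ec$residual, 1e-9 * max(1, cap))
      expect_equal(sum(ec$state), cap, tolerance = 1e-10)
      roots <- force_gap_roots(submodel_force_gap("corruption", p),
                               lam_max = 1.05 * p[["beta"]])
      expect_length(roots, 1)
      expect_equal(roots, ec$force_of_infection[["lambda_C"]], tolerance = 1e-6)
      n_checked <- n_checked + 1
    }
    if (rn$closed_form < 0.99) {
      expect_length(force_gap_roots(submodel_force_gap("racism", p),
                                    lam_max = 1.05 * p[["alpha"]] * cap + 1e-9), 0)
      expect_length(force_gap_roots(submodel_force_gap("corruption", p),
                                    lam_max = 1.05 * p[["beta"]] + 1e-9), 0)
      n_checked <- n_checked + 1
    }
  }
})

test_that("the theta1 -> infinity limit of the corruption force is (gamma1+mu)(R_c-1)", {
  p <- toy_corruption()
  p[["theta1"]] <- 1e9
  ec <- corruption_endemic_equilibrium(validate_parameters(p))
  Rc <- reproduction_number("corruption", p)$closed_form
  expect_equal(ec$force_of_infection[["lambda_C"]],
               (p[["gamma1"]] + p[["mu"]]) * (Rc - 1), tolerance = 1e-6)
})

test_that("coexistence root-finding converges on a supercritical scenario", {
  sc <- scenario(42, "supercritical")
  res <- coexistence_endemic_equilibrium(sc$params, seed = 42, t_probe = 3000)
  cap <- sc$params[["Lambda"]] / sc$params[["mu"]]
  expect_true(res$found)
  expect_lt(res$residual, 1e-8 * max(1, cap))
  expect_true(all(res$point$state > 0))
  # independent re-evaluation of the residual
  expect_lt(max(abs(coex_rhs("full", res$point$state, sc$params))),
            1e-8 * max(1, cap))
  expect_false(is.null(res$E1))
  expect_false(is.null(res$E2))
})

test_that("decoupled limits fall back to the boundary equilibria", {
  # no racism: interior root impossible, corruption boundary reported
  p <- reference_parameters(alpha = 0, beta = 0.1)   # R_c ~ 5.9
  res <- suppressWarnings(coexistence_endemic_equilibrium(p, t_probe = 2000))
  expect_false(res$found)
  expect_null(res$E1)
  ec <- corruption_endemic_equilibrium(p)
  expect_equal(res$E2$state, ec$state)
  # no corruption: racism boundary reported
  q <- reference_parameters(alpha = 1e-5, beta = 0)  # R_r ~ 31
  res2 <- suppressWarnings(coexistence_endemic_equilibrium(q, t_probe = 2000))
  expect_false(res2$found)
  expect_null(res2$E2)
  expect_equal(res2$E1$state, racism_endemic_equilibrium(q)$state)
})
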