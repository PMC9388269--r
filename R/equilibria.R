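## Equilibria: closed forms for the submodels, damped Newton for the full
## coexistence system.

.equilibrium_point <- function(model, kind, state, params) {
  state <- .as_state(state)
  resid <- max(abs(coex_rhs(model, state, params)))
  structure(list(model = model, kind = kind, state = state,
                 residual = resid,
                 force_of_infection = forces_of_infection(state, params)),
            class = "coex_equilibrium")
}

#' @export
print.coex_equilibrium <- function(x, ...) {
  cat(sprintf("<coex_equilibrium> %s (%s), residual = %.3g\n",
              x$kind, x$model, x$residual))
  print(x$state)
  invisible(x)
}

#' Contagion-free equilibrium
#'
#' The equilibrium with every affected class empty: `S = Lambda/mu`, all
#' other compartments 0.
#'
#' @inheritParams ngm_matrices
#' @return A `"coex_equilibrium"` (kind `"dfe"`).
#' @export
disease_free_equilibrium <- function(model, params) {
  model <- .match_model(model)
  p <- validate_parameters(params)
  st <- coex_state(S = p[["Lambda"]] / p[["mu"]])
  .equilibrium_point(model, "dfe", st, p)
}

#' Endemic equilibrium of the racism submodel
#'
#' Closed form: the endemic force of infection is
#' `lambda_R* = (gamma2+mu)(theta2+mu)(R_r - 1)/(gamma2+theta2+mu)`, positive
#' iff `R_r > 1`; then with
#' `D = (lambda_R+mu)(theta2+mu)(gamma2+mu) - theta2 gamma2 lambda_R`,
#' `S* = Lambda (theta2+mu)(gamma2+mu)/D`,
#' `R* = Lambda lambda_R (theta2+mu)/D`, and by the flow balance of the
#' recovered class `R2* = gamma2 R*/(theta2+mu)`. The components sum to
#' `Lambda/mu`.
#'
#' @param params Validated parameters with `R_r > 1`.
#' @return A `"coex_equilibrium"` (kind `"racism_endemic"`), embedded in the
#'   full 7-compartment state.
#' @export
racism_endemic_equilibrium <- function(params) {
  p <- validate_parameters(params)
  Rr <- reproduction_number("racism", p)$closed_form
  if (Rr <= 1) {
    stop("no endemic equilibrium: R_r = ", signif(Rr, 6), " <= 1", call. = FALSE)
  }
  g2 <- p[["gamma2"]]; t2 <- p[["theta2"]]; mu <- p[["mu"]]; L <- p[["Lambda"]]
  lamR <- (g2 + mu) * (t2 + mu) * (Rr - 1) / (g2 + t2 + mu)
  D <- (lamR + mu) * (t2 + mu) * (g2 + mu) - t2 * g2 * lamR
  S <- L * (t2 + mu) * (g2 + mu) / D
  R <- L * lamR * (t2 + mu) / D
  R2 <- g2 * R / (t2 + mu)
  .equilibrium_point("racism", "racism_endemic",
                     coex_state(S = S, R = R, R2 = R2), p)
}

#' Endemic equilibrium of the corruption submodel
#'
#' From the equilibrium balance `beta = (gamma1+mu) +
#' lambda_C (1 + gamma1/(theta1+mu))` (standard incidence with `N = Lambda/mu`
#' at equilibrium) the endemic force of infection is
#' `lambda_C* = (gamma1+mu)(theta1+mu)(R_c - 1)/(gamma1+theta1+mu)`, positive
#' iff `R_c > 1`; then `C* = (Lambda/mu) / ((gamma1+mu)/lambda_C + 1 +
#' gamma1/(theta1+mu))`, `S* = (gamma1+mu) C*/lambda_C`,
#' `R1* = gamma1 C*/(theta1+mu)`, and `S*+C*+R1* = Lambda/mu`.
#'
#' @param params Validated parameters with `R_c > 1`.
#' @return A `"coex_equilibrium"` (kind `"corruption_endemic"`).
#' @export
corruption_endemic_equilibrium <- function(params) {
  p <- validate_parameters(params)
  Rc <- reproduction_number("corruption", p)$closed_form
  if (Rc <= 1) {
    stop("no endemic equilibrium: R_c = ", signif(Rc, 6), " <= 1", call. = FALSE)
  }
  g1 <- p[["gamma1"]]; t1 <- p[["theta1"]]; mu <- p[["mu"]]; L <- p[["Lambda"]]
  lamC <- (g1 + mu) * (t1 + mu) * (Rc - 1) / (g1 + t1 + mu)
  C <- (L / mu) / ((g1 + mu) / lamC + 1 + g1 / (t1 + mu))
  S <- (g1 + mu) * C / lamC
  R1 <- g1 * C / (t1 + mu)
  .equilibrium_point("corruption", "corruption_endemic",
                     coex_state(S = S, C = C, R1 = R1), p)
}

## Damped Newton iteration on the full system from one starting point.
.newton_full <- function(x0, params, tol_abs, max_iter = 200L) {
  x <- pmax(x0, 0)
  f <- coex_rhs("full", x, params)
  best <- list(state = x, residual = max(abs(f)))
  for (it in seq_len(max_iter)) {
    nf <- max(abs(f))
    if (nf <= tol_abs) break
    J <- tryCatch(coex_jacobian("full", x, params), error = function(e) NULL)
    if (is.null(J)) break
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    improved <- FALSE
    for (k in 1:25) {
      xn <- pmax(x + lam * step, 0)
      fn <- coex_rhs("full", xn, params)
      if (max(abs(fn)) < nf) { x <- xn; f <- fn; improved <- TRUE; break }
      lam <- lam / 2
    }
    if (!improved) break
    if (max(abs(f)) < best$residual) best <- list(state = x, residual = max(abs(f)))
  }
  if (max(abs(f)) < best$residual) best <- list(state = x, residual = max(abs(f)))
  best
}

#' Coexistence endemic equilibrium of the full model
#'
#' Numeric root of the full 7-compartment system, located by damped Newton
#' iteration with the analytic Jacobian. Starting points are (i) a supplied
#' guess, (ii) the long-time state of the integrated system, (iii)
#' superpositions of the embedded submodel endemic equilibria, and (iv) a
#' seeded schedule of multiplicative perturbations of the best seed. The
#' result is labelled `coexistence_endemic` only when every compartment is
#' strictly positive; otherwise the best root found (typically a boundary
#' equilibrium) is returned with `found = FALSE`. The boundary equilibria
#' (racism-only and corruption-only persistence, each an equilibrium of the
#' full system) are reported alongside whenever they exist.
#'
#' @param params Validated parameters; a warning is issued when
#'   `R_rc <= 1` (no persistence expected).
#' @param guess Optional starting state.
#' @param seed Seed for the perturbation restarts.
#' @param t_probe Horizon of the probing integration used as a Newton seed.
#' @param n_restarts Number of perturbed restarts.
#' @return List with `found`, `point` (a `"coex_equilibrium"`), `residual`,
#'   `E1` (racism-only boundary equilibrium or `NULL`), `E2`
#'   (corruption-only boundary or `NULL`), and `seeds_used`.
#' @export
coexistence_endemic_equilibrium <- function(params, guess = NULL, seed = 1L,
                                            t_probe = 4000, n_restarts = 10L) {
  p <- validate_parameters(params)
  rn <- reproduction_number("full", p)
  if (rn$closed_form <= 1) {
    warning("R_rc = ", signif(rn$closed_form, 6),
            " <= 1: no coexistence equilibrium expected", call. = FALSE)
  }
  cap <- p[["Lambda"]] / p[["mu"]]
  tol_abs <- 1e-11 * max(1, cap)
  tol_accept <- 1e-8 * max(1, cap)

  E1 <- if (rn$R_r > 1) racism_endemic_equilibrium(p) else NULL
  E2 <- if (rn$R_c > 1) corruption_endemic_equilibrium(p) else NULL

  seeds <- list()
  if (!is.null(guess)) seeds <- c(seeds, list(.as_state(guess)))
  traj <- tryCatch(
    coex_integrate("full", p, t_end = t_probe, n_out = 200),
    error = function(e) NULL)
  if (!is.null(traj)) {
    seeds <- c(seeds, list(traj$states[nrow(traj$states), ]))
  }
  if (!is.null(E1) && !is.null(E2)) {
    mix <- (E1$state + E2$state) / 2
    mix[mix == 0] <- 0.01 * cap
    seeds <- c(seeds, list(mix))
  }
  seeds <- c(seeds, list(coex_state(S = 0.5 * cap, C = 0.1 * cap, R = 0.1 * cap,
                                    C1 = 0.05 * cap, R1 = 0.05 * cap,
                                    R2 = 0.05 * cap, R3 = 0.05 * cap)))

  restore <- .with_local_seed(seed)
  on.exit(restore(), add = TRUE)
  best <- NULL
  seeds_used <- 0L
  try_seed <- function(x0) .newton_full(x0, p, tol_abs)
  for (s in seeds) {
    seeds_used <- seeds_used + 1L
    cand <- try_seed(s)
    if (is.null(best) || .better_root(cand, best, tol_accept)) best <- cand
    if (.root_ok(best, tol_accept)) break
  }
  if (!.root_ok(best, tol_accept)) {
    base <- if (!is.null(best)) best$state else seeds[[length(seeds)]]
    base[base <= 0] <- 0.01 * cap
    for (k in seq_len(n_restarts)) {
      seeds_used <- seeds_used + 1L
      x0 <- base * stats::runif(7, 0.5, 1.5)
      cand <- try_seed(x0)
      if (.better_root(cand, best, tol_accept)) best <- cand
      if (.root_ok(best, tol_accept)) break
    }
  }

  state <- best$state
  interior <- all(state > 1e-8 * cap)
  found <- best$residual <= tol_accept && interior
  kind <- if (found) "coexistence_endemic" else "coexistence_search_best"
  point <- .equilibrium_point("full", kind, state, p)
  list(found = found, point = point, residual = point$residual,
       E1 = E1, E2 = E2, seeds_used = seeds_used)
}

.root_ok <- function(root, tol) !is.null(root) && root$residual <= tol

## Prefer converged interior roots, then converged roots, then lower residual.
.better_root <- function(cand, best, tol) {
  if (is.null(best)) return(TRUE)
  c_ok <- cand$residual <= tol
  b_ok <- best$residual <= tol
  c_int <- c_ok && all(cand$state > 0)
  b_int <- b_ok && all(best$state > 0)
  if (c_int != b_int) return(c_int)
  if (c_ok != b_ok) return(c_ok)
  cand$residual < best$residual
}
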