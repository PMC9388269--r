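## Time integration, convergence detection, seeded scenario generation and
## the gamma3 sweep.

#' Default initial state for demonstrations
#'
#' 95% of the carrying population `Lambda/mu` susceptible, the remaining 5%
#' split evenly between the corrupted, racist and co-affected classes, and
#' empty recovered classes.
#'
#' @param params Validated parameters.
#' @return A 7-compartment state.
#' @export
default_initial_state <- function(params) {
  p <- validate_parameters(params)
  cap <- p[["Lambda"]] / p[["mu"]]
  coex_state(S = 0.95 * cap, C = (0.05 / 3) * cap, R = (0.05 / 3) * cap,
             C1 = (0.05 / 3) * cap)
}

#' Integrate the model in time
#'
#' Solves the (sub)model with a stiff-capable adaptive integrator
#' (`deSolve`, `lsoda` by default) on an even output grid. Small negative
#' excursions of the solver (within `-1e-9`) are clipped to zero before the
#' incidence terms are formed and in the returned samples.
#'
#' @inheritParams coex_rhs
#' @param init Initial state; defaults to [default_initial_state()] (the
#'   compartments absent from a submodel are zeroed).
#' @param t_end Integration horizon (years), positive.
#' @param n_out Number of output intervals (grid has `n_out + 1` samples).
#' @param rtol,atol Relative / absolute solver tolerances.
#' @param method `deSolve` method name.
#' @return Object of class `"coex_trajectory"`: list with `model`, `times`,
#'   `states` (matrix, one row per sample), `params`, `diagnostics`.
#' @examples
#' p <- reference_parameters(alpha = 1e-6, beta = 0.005)
#' tr <- coex_integrate("full", p, t_end = 50, n_out = 50)
#' tail(as.data.frame(tr), 2)
#' @export
coex_integrate <- function(model, params, init = NULL, t_end = 100,
                           n_out = 400, rtol = 1e-8, atol = 1e-10,
                           racism_incidence = c("mass_action", "standard"),
                           method = "lsoda") {
  model <- .match_model(model)
  p <- validate_parameters(params)
  racism_incidence <- match.arg(racism_incidence)
  if (!is.numeric(t_end) || !is.finite(t_end) || t_end <= 0) {
    stop("t_end must be a positive number", call. = FALSE)
  }
  if (is.null(init)) init <- default_initial_state(p)
  init <- .as_state(init)
  if (any(init < 0)) stop("negative initial state", call. = FALSE)
  init[setdiff(1:7, .active_idx[[model]])] <- 0

  times <- seq(0, t_end, length.out = n_out + 1)
  derivs <- function(t, y, parms) {
    list(coex_rhs(model, y, p, racism_incidence))
  }
  out <- deSolve::ode(y = init, times = times, func = derivs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed: istate = ", attr(out, "istate")[1], call. = FALSE)
  }
  states <- unclass(out)[, .coex_compartments, drop = FALSE]
  raw_min <- min(states)
  states[states < 0 & states >= -1e-9] <- 0
  structure(list(model = model, times = out[, "time"], states = states,
                 params = p,
                 diagnostics = list(rtol = rtol, atol = atol, method = method,
                                    min_pre_clip = raw_min,
                                    istate = attr(out, "istate"),
                                    racism_incidence = racism_incidence)),
            class = "coex_trajectory")
}

#' @export
as.data.frame.coex_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states, check.names = FALSE)
}

#' @export
print.coex_trajectory <- function(x, ...) {
  cat(sprintf("<coex_trajectory> model = %s, %d samples on [0, %g]\n",
              x$model, length(x$times), max(x$times)))
  print(utils::tail(as.data.frame(x), 3))
  invisible(x)
}

#' Detect steady state of a trajectory
#'
#' The trajectory is declared converged when, over the trailing `window` of
#' time, the span (max minus min) of every compartment is at most `tol`
#' times that compartment's largest magnitude over the whole trajectory
#' (so compartments that have decayed to zero count as converged).
#'
#' @param trajectory A `"coex_trajectory"`.
#' @param window Trailing time window (same units as `times`); must be
#'   shorter than the trajectory.
#' @param tol Relative span tolerance.
#' @return List with `converged`, `state` (terminal sample), and
#'   `max_rel_change`.
#' @export
steady_state <- function(trajectory, window = NULL, tol = 1e-6) {
  stopifnot(inherits(trajectory, "coex_trajectory"))
  tmax <- max(trajectory$times)
  if (is.null(window)) window <- tmax / 5
  if (window >= tmax - min(trajectory$times)) {
    stop("window must be shorter than the trajectory", call. = FALSE)
  }
  keep <- trajectory$times >= tmax - window
  tailmat <- trajectory$states[keep, , drop = FALSE]
  span <- apply(tailmat, 2, function(v) max(v) - min(v))
  scale <- pmax(apply(abs(trajectory$states), 2, max), 1e-12)
  rel <- span / scale
  list(converged = all(rel <= tol),
       state = trajectory$states[nrow(trajectory$states), ],
       max_rel_change = max(rel))
}

#' Seeded scenario generator
#'
#' Reproducible parameter/initial-state fixtures anchored on the reference
#' rate set: the slow rates (`sigma*`, `gamma*`, `theta*`) are jittered by
#' +/-10%, `Lambda = 50`, `mu = 0.01`, `eta = 1.3`, `xi = 1.2`,
#' `omega1 = omega2 = 1` are held fixed, and the transmission coefficients
#' are set by drawing target reproduction numbers and inverting the closed
#' forms: subcritical draws `R_r, R_c ~ U(0.15, 0.7)` (so `R_rc < 0.9`),
#' supercritical `U(1.5, 6)` (so `R_rc > 1.1`, bracketing the magnitudes
#' reported for the reference scenario), and the single-contagion regimes
#' zero the other transmission rate. The regime is re-verified through
#' [reproduction_number()] before returning.
#'
#' @param seed Integer seed (determines the scenario completely).
#' @param regime One of `"subcritical"`, `"supercritical"`, `"racism_only"`,
#'   `"corruption_only"`.
#' @return List with `params`, `init`, `regime`, `seed`, `R_r`, `R_c`.
#' @export
scenario <- function(seed, regime = c("subcritical", "supercritical",
                                      "racism_only", "corruption_only")) {
  regime <- match.arg(regime)
  restore <- .with_local_seed(seed)
  on.exit(restore(), add = TRUE)

  jit <- function(v) v * stats::runif(1, 0.9, 1.1)
  base <- list(Lambda = 50, mu = 0.01, eta = 1.3, xi = 1.2,
               omega1 = 1, omega2 = 1,
               sigma1 = jit(0.6), sigma2 = jit(0.7),
               gamma1 = jit(0.007), gamma2 = jit(0.006), gamma3 = jit(0.008),
               theta1 = jit(0.3), theta2 = jit(0.25), theta3 = jit(0.2))
  draw <- function(lo, hi) stats::runif(1, lo, hi)
  targets <- switch(regime,
    subcritical    = c(Rr = draw(0.15, 0.7), Rc = draw(0.15, 0.7)),
    supercritical  = c(Rr = draw(1.5, 6), Rc = draw(1.5, 6)),
    racism_only    = c(Rr = draw(1.5, 6), Rc = 0),
    corruption_only = c(Rr = 0, Rc = draw(1.5, 6)))
  alpha <- targets[["Rr"]] * base$mu * (base$gamma2 + base$mu) / base$Lambda
  beta <- targets[["Rc"]] * (base$gamma1 + base$mu)
  p <- do.call(coex_parameters, c(base, list(alpha = alpha, beta = beta)))

  rn <- reproduction_number("full", p)
  ok <- switch(regime,
    subcritical = rn$closed_form < 0.9,
    supercritical = rn$closed_form > 1.1,
    racism_only = p[["beta"]] == 0 && rn$R_r > 1.1,
    corruption_only = p[["alpha"]] == 0 && rn$R_c > 1.1)
  if (!ok) stop("scenario regime contract violated (internal error)", call. = FALSE)

  cap <- base$Lambda / base$mu
  init <- switch(regime,
    racism_only = coex_state(S = 0.95 * cap, R = 0.05 * cap),
    corruption_only = coex_state(S = 0.95 * cap, C = 0.05 * cap),
    default_initial_state(p))
  list(params = p, init = init, regime = regime, seed = seed,
       R_r = rn$R_r, R_c = rn$R_c)
}

#' Terminal co-affected class across a recovery-rate sweep
#'
#' Integrates the full model once per value of the coexistence recovery
#' rate `gamma3` and records the terminal size of the co-affected class
#' `C1`. In a supercritical setting the terminal `C1` decreases as
#' `gamma3` grows.
#'
#' @param params Baseline parameters (supercritical for a meaningful sweep).
#' @param values Increasing `gamma3` values.
#' @param t_end Integration horizon per run.
#' @param init Optional initial state.
#' @param tol Convergence tolerance passed to [steady_state()].
#' @return `data.frame` with columns `gamma3`, `C1`, `converged`.
#' @export
gamma3_sweep <- function(params, values, t_end = 3000, init = NULL,
                         tol = 1e-5) {
  p <- validate_parameters(params)
  if (is.unsorted(values, strictly = FALSE)) {
    stop("values must be increasing", call. = FALSE)
  }
  rows <- lapply(values, function(g3) {
    pi <- p
    pi[["gamma3"]] <- g3
    pi <- validate_parameters(pi)
    tr <- coex_integrate("full", pi, init = init, t_end = t_end, n_out = 200)
    ss <- steady_state(tr, window = t_end / 5, tol = tol)
    data.frame(gamma3 = g3, C1 = ss$state[["C1"]], converged = ss$converged)
  })
  do.call(rbind, rows)
}
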