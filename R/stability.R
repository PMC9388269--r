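## Local stability machinery: analytic Jacobians, eigenvalue classification,
## Routh-Hurwitz tables, and a sampled Lyapunov-derivative check at the
## contagion-free equilibrium.

#' Analytic Jacobian of the model right-hand side
#'
#' Exact Jacobian of [coex_rhs()] at an arbitrary state, with the
#' quotient-rule terms of the standard-incidence corruption force of
#' infection (every compartment enters through the live total `N`).
#' Submodels return the Jacobian of their reduced system (3x3, over the
#' active compartments with the absent ones pinned to zero).
#'
#' @inheritParams coex_rhs
#' @return Jacobian matrix (7x7 for the full model, 3x3 for submodels),
#'   dimnames set to compartment names.
#' @export
coex_jacobian <- function(model, state, params) {
  model <- .match_model(model)
  p <- validate_parameters(params)
  state <- .clip_state(.as_state(state))
  active <- .active_idx[[model]]
  x <- numeric(7L); names(x) <- .coex_compartments
  x[active] <- state[active]

  N <- sum(x)
  if (N <= 0) stop("Jacobian undefined at N = 0", call. = FALSE)
  e <- c(0, 1, 0, p[["omega1"]], 0, 0, 0)            # d(C + w1 C1)/dx
  r <- p[["alpha"]] * c(0, 0, 1, p[["omega2"]], 0, 0, 0)  # dlambda_R/dx
  w <- x[["C"]] + p[["omega1"]] * x[["C1"]]
  lC <- p[["beta"]] * w / N
  lR <- p[["alpha"]] * (x[["R"]] + p[["omega2"]] * x[["C1"]])
  cv <- p[["beta"]] * (e / N - w / N^2)              # dlambda_C/dx

  S <- x[["S"]]; C <- x[["C"]]; R <- x[["R"]]
  d1 <- function(j) as.numeric(seq_len(7L) == j)
  J <- matrix(0, 7, 7, dimnames = list(.coex_compartments, .coex_compartments))
  J[1, ] <- p[["theta1"]] * d1(5) + p[["theta2"]] * d1(6) + p[["theta3"]] * d1(7) -
    (r + cv) * S - (lR + lC + p[["mu"]]) * d1(1)
  J[2, ] <- cv * S + lC * d1(1) + p[["sigma1"]] * d1(4) -
    (p[["gamma1"]] + p[["xi"]] * lR + p[["mu"]]) * d1(2) - p[["xi"]] * r * C
  J[3, ] <- r * S + lR * d1(1) + p[["sigma2"]] * d1(4) -
    (p[["eta"]] * lC + p[["gamma2"]] + p[["mu"]]) * d1(3) - p[["eta"]] * cv * R
  J[4, ] <- p[["eta"]] * (cv * R + lC * d1(3)) + p[["xi"]] * (r * C + lR * d1(2)) -
    (p[["sigma2"]] + p[["gamma3"]] + p[["sigma1"]] + p[["mu"]]) * d1(4)
  J[5, ] <- p[["gamma1"]] * d1(2) - (p[["theta1"]] + p[["mu"]]) * d1(5)
  J[6, ] <- p[["gamma2"]] * d1(3) - (p[["theta2"]] + p[["mu"]]) * d1(6)
  J[7, ] <- p[["gamma3"]] * d1(4) - (p[["theta3"]] + p[["mu"]]) * d1(7)

  if (model == "full") J else J[active, active, drop = FALSE]
}

#' Classify a spectrum
#'
#' Asymptotically stable when every eigenvalue has real part below
#' `-tol_abs`, unstable when some real part exceeds `+tol_abs`, marginal
#' otherwise, where `tol_abs = zero_tolerance * max(|eigenvalues|)` (a
#' relative dead band around the imaginary axis).
#'
#' @param eigenvalues Complex (or numeric) vector, nonempty and finite.
#' @param zero_tolerance Relative dead band; default `1e-8`.
#' @return One of `"asymptotically_stable"`, `"unstable"`, `"marginal"`.
#' @export
classify_local <- function(eigenvalues, zero_tolerance = 1e-8) {
  if (length(eigenvalues) == 0L) stop("empty eigenvalue list", call. = FALSE)
  if (any(!is.finite(Re(eigenvalues)) | !is.finite(Im(eigenvalues)))) {
    stop("non-finite eigenvalues", call. = FALSE)
  }
  tol_abs <- zero_tolerance * max(Mod(eigenvalues))
  re <- Re(eigenvalues)
  if (all(re < -tol_abs)) return("asymptotically_stable")
  if (any(re > tol_abs)) return("unstable")
  "marginal"
}

#' Routh-Hurwitz table for a cubic
#'
#' For `a0 x^3 + a1 x^2 + a2 x + a3` with `a0 > 0`, builds the Routh array
#' first column `(a0, a1, b1, c1)` with `b1 = (a1 a2 - a0 a3)/a1` and
#' `c1 = a3`. All roots lie strictly in the left half plane iff `a1 > 0`,
#' `a3 > 0` and `a1 a2 > a0 a3`. A zero pivot (`a1 = 0`) is returned as an
#' explicit indeterminate verdict rather than perturbed.
#'
#' @param a0,a1,a2,a3 Cubic coefficients, `a0 > 0`.
#' @return List with `coefficients`, `b1`, `c1`, `first_column`,
#'   `first_column_signs`, and `verdict` (`"stable"`, `"unstable"` or
#'   `"indeterminate"`).
#' @export
routh_hurwitz_cubic <- function(a0, a1, a2, a3) {
  if (!is.finite(a0) || a0 <= 0) stop("a0 must be positive", call. = FALSE)
  if (a1 == 0) {
    return(list(coefficients = c(a0 = a0, a1 = a1, a2 = a2, a3 = a3),
                b1 = NA_real_, c1 = a3,
                first_column = c(a0, a1, NA_real_, a3),
                first_column_signs = c(1, 0, NA_real_, sign(a3)),
                verdict = "indeterminate"))
  }
  b1 <- (a1 * a2 - a0 * a3) / a1
  c1 <- a3
  first <- c(a0, a1, b1, c1)
  verdict <- if (a1 > 0 && a3 > 0 && a1 * a2 > a0 * a3) "stable" else "unstable"
  list(coefficients = c(a0 = a0, a1 = a1, a2 = a2, a3 = a3),
       b1 = b1, c1 = c1, first_column = first,
       first_column_signs = sign(first), verdict = verdict)
}

#' Characteristic cubic of a 3x3 matrix
#'
#' Coefficients `(a0, a1, a2, a3)` of `det(lambda I - J) = a0 lambda^3 +
#' a1 lambda^2 + a2 lambda + a3`, i.e. `a1 = -tr(J)`, `a2` the sum of
#' principal 2x2 minors, `a3 = -det(J)`.
#'
#' @param J A 3x3 numeric matrix.
#' @return Named numeric vector `c(a0, a1, a2, a3)`.
#' @export
characteristic_cubic <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == c(3L, 3L)))
  m2 <- det(J[-1, -1, drop = FALSE]) + det(J[-2, -2, drop = FALSE]) +
    det(J[-3, -3, drop = FALSE])
  c(a0 = 1, a1 = -sum(diag(J)), a2 = m2, a3 = -det(J))
}

.stability_report <- function(model, state, params, zero_tolerance,
                              routh_hurwitz = NULL) {
  J <- coex_jacobian(model, state, params)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(model = model, point = state, jacobian = J,
                 eigenvalues = ev,
                 classification = classify_local(ev, zero_tolerance),
                 zero_tolerance = zero_tolerance,
                 routh_hurwitz = routh_hurwitz),
            class = "coex_stability")
}

#' Local stability of the contagion-free equilibrium
#'
#' Jacobian eigenvalues at the contagion-free equilibrium of the chosen
#' model, classified per [classify_local()]. The verdict is concordant with
#' the threshold: stable iff the model's reproduction number is below 1.
#'
#' @inheritParams ngm_matrices
#' @param zero_tolerance Dead band for [classify_local()].
#' @return A `"coex_stability"` report (eigenvalues, classification,
#'   Jacobian, reproduction number in `$R`).
#' @export
dfe_stability <- function(model, params, zero_tolerance = 1e-8) {
  model <- .match_model(model)
  p <- validate_parameters(params)
  eq <- disease_free_equilibrium(model, p)
  rep <- .stability_report(model, eq$state, p, zero_tolerance)
  rep$R <- reproduction_number(model, p)$closed_form
  rep
}

#' Stability report at an equilibrium
#'
#' Convenience wrapper: computes the requested equilibrium (contagion-free
#' or endemic) and classifies it. For the submodel endemic points the
#' Routh-Hurwitz table of the characteristic cubic is attached.
#'
#' @inheritParams dfe_stability
#' @param point `"dfe"` or `"endemic"`.
#' @return A `"coex_stability"` report.
#' @export
stability_report <- function(model, params, point = c("dfe", "endemic"),
                             zero_tolerance = 1e-8) {
  model <- .match_model(model)
  point <- match.arg(point)
  p <- validate_parameters(params)
  if (point == "dfe") return(dfe_stability(model, p, zero_tolerance))
  eq <- switch(model,
    racism = racism_endemic_equilibrium(p),
    corruption = corruption_endemic_equilibrium(p),
    full = {
      res <- coexistence_endemic_equilibrium(p)
      if (!res$found) stop("no coexistence equilibrium located", call. = FALSE)
      res$point
    })
  rh <- NULL
  if (model != "full") {
    J <- coex_jacobian(model, eq$state, p)
    cc <- characteristic_cubic(J)
    rh <- routh_hurwitz_cubic(cc[["a0"]], cc[["a1"]], cc[["a2"]], cc[["a3"]])
  }
  .stability_report(model, eq$state, p, zero_tolerance, routh_hurwitz = rh)
}

#' Sampled Lyapunov-derivative check of global stability
#'
#' For a submodel below threshold, the linear Lyapunov function `V = R`
#' (racism) or `V = C` (corruption) decays along trajectories everywhere in
#' the invariant region `Omega` (nonnegative states with total at most
#' `Lambda/mu`): `dR/dt <= (gamma2 + mu)(R_r - 1) R` since
#' `alpha S <= alpha Lambda/mu`, and `dC/dt <= (gamma1 + mu)(R_c - 1) C`
#' since `S/N <= 1`. This check samples `Omega` uniformly (Dirichlet scaling
#' of the simplex) and reports the worst decay margin `dV/dt`; the pass
#' verdict requires decay (`dV/dt <= 0` up to round-off) at every sample,
#' which holds iff the reproduction number is at most 1. Above threshold
#' violations are reported, not raised.
#'
#' @param model `"racism"` or `"corruption"` (the full model has no such
#'   linear certificate).
#' @param params Validated parameters.
#' @param n_samples Number of sampled states.
#' @param seed Integer seed for the sampler.
#' @return List with `pass`, `worst_margin` (max of `dV/dt` over samples),
#'   `bound_margin` (max of `dV/dt - (gamma+mu)(R-1)V`, the structural
#'   inequality, nonpositive on `Omega` for any parameters),
#'   `n_violations`, `n_samples`, `seed`, `R`.
#' @export
lyapunov_gas_check <- function(model, params, n_samples = 1000L, seed = 1L) {
  model <- .match_model(model)
  if (model == "full") {
    stop("Lyapunov check is available for the submodels only", call. = FALSE)
  }
  p <- validate_parameters(params)
  cap <- p[["Lambda"]] / p[["mu"]]
  active <- .active_idx[[model]]
  R <- reproduction_number(model, p)$closed_form
  decay_rate <- if (model == "racism") {
    (p[["gamma2"]] + p[["mu"]]) * (R - 1)
  } else {
    (p[["gamma1"]] + p[["mu"]]) * (R - 1)
  }
  inf_name <- if (model == "racism") "R" else "C"

  worst <- -Inf; worst_bound <- -Inf; nviol <- 0L
  withr_seed <- .with_local_seed(seed)
  on.exit(withr_seed(), add = TRUE)
  for (i in seq_len(n_samples)) {
    g <- stats::rexp(4L)                      # Dirichlet(1,1,1,1): first three
    frac <- g[1:3] / sum(g)                   # coords uniform on {x>=0, sum<=1}
    x <- numeric(7L); names(x) <- .coex_compartments
    x[active] <- cap * frac
    d <- coex_rhs(model, x, p)
    dV <- d[[inf_name]]
    margin <- dV
    bound <- dV - decay_rate * x[[inf_name]]
    if (margin > 1e-10 * max(1, cap)) nviol <- nviol + 1L
    worst <- max(worst, margin)
    worst_bound <- max(worst_bound, bound / max(1, cap))
  }
  list(pass = nviol == 0L, worst_margin = worst, bound_margin = worst_bound,
       n_violations = nviol, n_samples = n_samples, seed = seed, R = R)
}

## Run code under a private RNG state; returns a restore function.
.with_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' @export
print.coex_stability <- function(x, ...) {
  cat(sprintf("<coex_stability> model = %s: %s\n", x$model, x$classification))
  cat("  eigenvalues:\n")
  print(x$eigenvalues)
  if (!is.null(x$routh_hurwitz)) {
    cat(sprintf("  Routh-Hurwitz verdict: %s\n", x$routh_hurwitz$verdict))
  }
  invisible(x)
}
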