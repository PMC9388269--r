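## Center-manifold analysis at the corruption transmission threshold.

#' Critical corruption transmission rate
#'
#' The bifurcation value `beta* = gamma1 + mu` at which `R_c = 1` (and,
#' provided `R_r < 1`, the full-model reproduction number crosses 1).
#' The identity `R_c(beta*) = 1` is re-verified through the
#' next-generation machinery before returning.
#'
#' @param params Validated parameters (the stored `beta` is ignored).
#' @return The critical rate `gamma1 + mu` (per year).
#' @export
critical_transmission_rate <- function(params) {
  p <- validate_parameters(params)
  beta_star <- p[["gamma1"]] + p[["mu"]]
  p[["beta"]] <- beta_star
  Rc <- reproduction_number("corruption", validate_parameters(p))$closed_form
  if (abs(Rc - 1) > 1e-12) {
    stop("internal error: R_c(beta*) = ", Rc, call. = FALSE)
  }
  beta_star
}

## Analytic Hessians of the seven right-hand-side components at an
## arbitrary interior state (mass-action racism, standard-incidence
## corruption). Only four nonlinear building blocks occur:
##   q_m = x_m (x2 + w1 x4)/N   (standard incidence, m = 1 or 3)
##   b_m = (x3 + w2 x4) x_m     (mass action, m = 1 or 2)
.coex_hessians <- function(state, params) {
  p <- validate_parameters(params)
  x <- .clip_state(.as_state(state))
  N <- sum(x)
  if (N <= 0) stop("Hessian undefined at N = 0", call. = FALSE)
  e <- c(0, 1, 0, p[["omega1"]], 0, 0, 0)
  r <- c(0, 0, 1, p[["omega2"]], 0, 0, 0)
  w <- x[["C"]] + p[["omega1"]] * x[["C1"]]

  quo <- function(m) {
    ## Hessian of beta * x_m * w / N
    dm <- as.numeric(seq_len(7L) == m)
    xm <- x[[m]]
    H <- outer(dm, e) / N + outer(e, dm) / N -
      (outer(dm, rep(w, 7L)) + outer(rep(w, 7L), dm) +
         xm * outer(e, rep(1, 7L)) + xm * outer(rep(1, 7L), e)) / N^2 +
      2 * xm * w / N^3
    p[["beta"]] * H
  }
  bil <- function(m) {
    dm <- as.numeric(seq_len(7L) == m)
    p[["alpha"]] * (outer(dm, r) + outer(r, dm))
  }
  Z <- matrix(0, 7, 7)
  list(
    S  = -quo(1) - bil(1),
    C  =  quo(1) - p[["xi"]] * bil(2),
    R  =  bil(1) - p[["eta"]] * quo(3),
    C1 =  p[["eta"]] * quo(3) + p[["xi"]] * bil(2),
    R1 = Z, R2 = Z, R3 = Z
  )
}

## Mixed second partials d^2 f_k / dx_i dbeta: matrix M[k, i].
.coex_beta_cross <- function(state, params) {
  p <- validate_parameters(params)
  x <- .clip_state(.as_state(state))
  N <- sum(x)
  e <- c(0, 1, 0, p[["omega1"]], 0, 0, 0)
  w <- x[["C"]] + p[["omega1"]] * x[["C1"]]
  g <- function(m) {
    dm <- as.numeric(seq_len(7L) == m)
    e * x[[m]] / N + dm * w / N - x[[m]] * w / N^2
  }
  M <- matrix(0, 7, 7, dimnames = list(.coex_compartments, .coex_compartments))
  M[1, ] <- -g(1)
  M[2, ] <- g(1)
  M[3, ] <- -p[["eta"]] * g(3)
  M[4, ] <- p[["eta"]] * g(3)
  M
}

#' Center-manifold bifurcation coefficients at the threshold
#'
#' At `beta = beta* = gamma1 + mu` the full-model Jacobian at the
#' contagion-free equilibrium has a simple zero eigenvalue (provided
#' `R_r < 1`, so the racism direction is stable). The associated right (`u`)
#' and left (`v`) null eigenvectors, normalized to `v . u = 1` with
#' `u_2 > 0`, yield the two center-manifold coefficients
#' `a = sum_k v_k u' H_k u` (full second-order Hessian sums of the
#' right-hand side, including the quotient-rule terms of standard
#' incidence) and `b = sum_k v_k sum_i u_i d2 f_k / dx_i dbeta = v_2 u_2`.
#' A forward (transcritical) bifurcation corresponds to `a < 0 < b`.
#'
#' @param params Validated parameters; `beta` is replaced by `beta*`.
#' @return Object of class `"coex_bifurcation"`: list with `beta_star`,
#'   `u`, `v`, `a`, `b`, `a_reduced` (the two-term cross-derivative
#'   expression `2 v2 u2 (u1 beta* + u3 xi alpha)` reported by the audit),
#'   `b_scaled` (`beta* v2 u2`), `verdict`, and residual diagnostics.
#' @export
center_manifold_coefficients <- function(params) {
  p <- validate_parameters(params)
  beta_star <- critical_transmission_rate(p)
  p[["beta"]] <- beta_star
  p <- validate_parameters(p)
  Rr <- reproduction_number("racism", p)$closed_form
  if (abs(Rr - 1) <= 1e-10) {
    stop("codimension-2 point: R_r = 1 at beta = beta*", call. = FALSE)
  }
  if (Rr > 1) {
    stop("center-manifold reduction requires R_r < 1 at beta = beta* ",
         "(got R_r = ", signif(Rr, 6), ")", call. = FALSE)
  }

  dfe <- disease_free_equilibrium("full", p)$state
  J <- coex_jacobian("full", dfe, p)
  Jnorm <- norm(J, "2")

  pick_null <- function(M) {
    es <- eigen(M)
    i <- which.min(Mod(es$values))
    if (Mod(es$values[i]) > 1e-8 * Jnorm) {
      stop("no numerically zero eigenvalue found", call. = FALSE)
    }
    vec <- es$vectors[, i]
    if (max(abs(Im(vec))) > 1e-10 * max(abs(vec))) {
      stop("zero eigenvector unexpectedly complex", call. = FALSE)
    }
    Re(vec)
  }
  u <- pick_null(J)
  v <- pick_null(t(J))
  if (u[2] < 0) u <- -u
  if (v[2] < 0) v <- -v
  sc <- sum(v * u)
  if (abs(sc) < 1e-12) stop("degenerate eigenvector normalization", call. = FALSE)
  v <- v / sc
  names(u) <- names(v) <- .coex_compartments

  res_u <- max(abs(J %*% u))
  res_v <- max(abs(t(J) %*% v))

  H <- .coex_hessians(dfe, p)
  a <- sum(vapply(seq_len(7L), function(k) {
    v[k] * as.numeric(t(u) %*% H[[k]] %*% u)
  }, numeric(1)))
  M <- .coex_beta_cross(dfe, p)
  b <- sum(vapply(seq_len(7L), function(k) {
    v[k] * sum(M[k, ] * u)
  }, numeric(1)))

  a_reduced <- 2 * v[["C"]] * u[["C"]] *
    (u[["S"]] * beta_star + u[["R"]] * p[["xi"]] * p[["alpha"]])
  structure(list(beta_star = beta_star, u = u, v = v, a = a, b = b,
                 a_reduced = a_reduced, b_scaled = beta_star * v[["C"]] * u[["C"]],
                 verdict = classify_bifurcation(a, b),
                 residual_u = res_u, residual_v = res_v,
                 jacobian_norm = Jnorm, R_r = Rr),
            class = "coex_bifurcation")
}

#' Classify a bifurcation from its coefficients
#'
#' Forward (transcritical, no subthreshold endemic branch) when
#' `a < 0 < b`; backward (a stable endemic branch coexists with the stable
#' contagion-free state below threshold) when `a > 0` and `b > 0`. A
#' non-positive `b` means the transversality condition fails.
#'
#' @param a,b Center-manifold coefficients.
#' @return `"forward"`, `"backward"`, `"degenerate"` (a = 0), or
#'   `"transversality_failure"`.
#' @export
classify_bifurcation <- function(a, b) {
  if (!is.finite(a) || !is.finite(b)) stop("non-finite coefficients", call. = FALSE)
  if (b <= 0) return("transversality_failure")
  if (a < 0) return("forward")
  if (a > 0) return("backward")
  "degenerate"
}

#' @export
print.coex_bifurcation <- function(x, ...) {
  cat(sprintf("<coex_bifurcation> beta* = %.6g, a = %.6g, b = %.6g: %s\n",
              x$beta_star, x$a, x$b, x$verdict))
  invisible(x)
}
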