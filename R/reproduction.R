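## Next-generation matrices and basic reproduction numbers.

#' Next-generation matrices at the contagion-free equilibrium
#'
#' Splits the linearized infected subsystem at the contagion-free
#' equilibrium into a new-infection matrix `F` and a transition matrix `V`.
#' Infected compartments are ordered `(R, R2)` for the racism submodel,
#' `(C, R1)` for the corruption submodel, and `(C, R, C1)` for the full
#' model (the stored matrices depend on this ordering; the spectral radius
#' of `F V^{-1}` does not).
#'
#' @param model `"full"`, `"racism"` or `"corruption"`.
#' @param params Validated [coex_parameters()].
#' @return List with matrices `F` and `V` (dimnames = compartments).
#' @export
ngm_matrices <- function(model, params) {
  model <- .match_model(model)
  p <- validate_parameters(params)
  S0 <- p[["Lambda"]] / p[["mu"]]
  if (model == "racism") {
    cn <- c("R", "R2")
    F_ <- matrix(c(p[["alpha"]] * S0, 0,
                   0, 0), 2, 2, byrow = TRUE, dimnames = list(cn, cn))
    V_ <- matrix(c(p[["gamma2"]] + p[["mu"]], 0,
                   -p[["gamma2"]], p[["theta2"]] + p[["mu"]]),
                 2, 2, byrow = TRUE, dimnames = list(cn, cn))
  } else if (model == "corruption") {
    cn <- c("C", "R1")
    F_ <- matrix(c(p[["beta"]], 0,
                   0, 0), 2, 2, byrow = TRUE, dimnames = list(cn, cn))
    V_ <- matrix(c(p[["gamma1"]] + p[["mu"]], 0,
                   -p[["gamma1"]], p[["theta1"]] + p[["mu"]]),
                 2, 2, byrow = TRUE, dimnames = list(cn, cn))
  } else {
    cn <- c("C", "R", "C1")
    ## New infections at the contagion-free point: corruption into C (rate
    ## beta per infective since S/N = 1), racism into R (alpha * S0 per
    ## infective); the co-affected class is reached only from the singly
    ## affected classes, never directly from S.
    F_ <- matrix(c(
      p[["beta"]], 0, p[["beta"]] * p[["omega1"]],
      0, p[["alpha"]] * S0, p[["alpha"]] * p[["omega2"]] * S0,
      0, 0, 0), 3, 3, byrow = TRUE, dimnames = list(cn, cn))
    V_ <- matrix(c(
      p[["gamma1"]] + p[["mu"]], 0, -p[["sigma1"]],
      0, p[["gamma2"]] + p[["mu"]], -p[["sigma2"]],
      0, 0, p[["sigma2"]] + p[["gamma3"]] + p[["sigma1"]] + p[["mu"]]),
      3, 3, byrow = TRUE, dimnames = list(cn, cn))
  }
  list(F = F_, V = V_)
}

#' Basic reproduction number
#'
#' Spectral radius of the next-generation matrix `K = F V^{-1}` at the
#' contagion-free equilibrium, recorded alongside the closed form:
#' `R_r = Lambda alpha / ((gamma2 + mu) mu)` for the racism submodel,
#' `R_c = beta / (gamma1 + mu)` for the corruption submodel, and
#' `R_rc = max(R_r, R_c)` for the full model.
#'
#' @inheritParams ngm_matrices
#' @return Object of class `"coex_ngm"`: list with `model`, `F`, `V`, `K`,
#'   `spectral_radius`, `closed_form`, and (for every model) the submodel
#'   numbers `R_r` and `R_c`.
#' @examples
#' reproduction_number("corruption", reference_parameters(beta = 1.51))
#' @export
reproduction_number <- function(model, params) {
  model <- .match_model(model)
  p <- validate_parameters(params)
  m <- ngm_matrices(model, p)
  K <- m$F %*% solve(m$V)
  rho <- max(Mod(eigen(K, only.values = TRUE)$values))
  R_r <- p[["Lambda"]] * p[["alpha"]] / ((p[["gamma2"]] + p[["mu"]]) * p[["mu"]])
  R_c <- p[["beta"]] / (p[["gamma1"]] + p[["mu"]])
  closed <- switch(model, racism = R_r, corruption = R_c, full = max(R_r, R_c))
  structure(list(model = model, F = m$F, V = m$V, K = K,
                 spectral_radius = rho, closed_form = closed,
                 R_r = R_r, R_c = R_c),
            class = "coex_ngm")
}

#' @export
print.coex_ngm <- function(x, ...) {
  cat(sprintf("<coex_ngm> model = %s\n", x$model))
  cat(sprintf("  spectral radius rho(F V^-1) = %.10g\n", x$spectral_radius))
  cat(sprintf("  closed form                 = %.10g\n", x$closed_form))
  cat(sprintf("  R_r = %.10g, R_c = %.10g, R_rc = %.10g\n",
              x$R_r, x$R_c, max(x$R_r, x$R_c)))
  invisible(x)
}
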