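## Normalized forward sensitivity indices of the reproduction numbers,
## finite-difference cross-checks, and threshold scans.

.si_targets <- c("Rr", "Rc")

## Closed-form reproduction number as a function of a parameter vector.
.target_value <- function(target, params) {
  if (target == "Rr") {
    params[["Lambda"]] * params[["alpha"]] /
      ((params[["gamma2"]] + params[["mu"]]) * params[["mu"]])
  } else {
    params[["beta"]] / (params[["gamma1"]] + params[["mu"]])
  }
}

.si_dependencies <- list(
  Rr = c("Lambda", "alpha", "gamma2", "mu"),
  Rc = c("beta", "gamma1", "mu")
)

#' Normalized forward sensitivity index
#'
#' The elasticity `SI(p) = (dR/dp) (p/R)` of a reproduction number with
#' respect to one rate: the proportional change in `R` per proportional
#' change in `p`. Closed forms: for `R_r = Lambda alpha/((gamma2+mu) mu)` the
#' indices are `+1` (Lambda), `+1` (alpha), `-gamma2/(gamma2+mu)` (gamma2)
#' and `-(gamma2+2mu)/(gamma2+mu)` (mu); for `R_c = beta/(gamma1+mu)` they
#' are `+1` (beta), `-gamma1/(gamma1+mu)` (gamma1) and `-mu/(gamma1+mu)`
#' (mu). A parameter the target does not depend on has index 0 (returned
#' with a note), as does a parameter sitting at 0 (the elasticity scaling
#' `p/R` vanishes). Every analytic index is cross-checked against a central
#' finite difference of the closed form.
#'
#' @param target `"Rr"` or `"Rc"`.
#' @param parameter One of the 16 rate names.
#' @param params Validated parameters; the target must be positive.
#' @return Object of class `"coex_sensitivity"`: list with `target`,
#'   `parameter`, `analytic_index`, `fd_index`, `note`, `params`.
#' @examples
#' sensitivity_index("Rc", "gamma1", reference_parameters(beta = 1.51))
#' @export
sensitivity_index <- function(target, parameter, params) {
  target <- match.arg(target, .si_targets)
  parameter <- match.arg(parameter, .coex_param_names)
  p <- validate_parameters(params)
  R <- .target_value(target, p)
  if (!is.finite(R) || R <= 0) {
    stop("target ", target, " is not positive at these parameters", call. = FALSE)
  }
  deps <- .si_dependencies[[target]]
  note <- NA_character_

  if (!(parameter %in% deps)) {
    note <- "target does not depend on this parameter"
    analytic <- 0
    fd <- 0
  } else if (p[[parameter]] == 0) {
    note <- "parameter at 0: elasticity scaling p/R vanishes"
    analytic <- 0
    fd <- 0
  } else {
    analytic <- switch(paste(target, parameter),
      "Rr Lambda" = 1,
      "Rr alpha"  = 1,
      "Rr gamma2" = -p[["gamma2"]] / (p[["gamma2"]] + p[["mu"]]),
      "Rr mu"     = -(p[["gamma2"]] + 2 * p[["mu"]]) / (p[["gamma2"]] + p[["mu"]]),
      "Rc beta"   = 1,
      "Rc gamma1" = -p[["gamma1"]] / (p[["gamma1"]] + p[["mu"]]),
      "Rc mu"     = -p[["mu"]] / (p[["gamma1"]] + p[["mu"]])
    )
    fd <- .fd_elasticity(target, parameter, p)
  }
  structure(list(target = target, parameter = parameter,
                 analytic_index = analytic, fd_index = fd,
                 note = note, params = p),
            class = "coex_sensitivity")
}

## Central-difference elasticity of the closed form; relative step 1e-6 p,
## absolute fallback 1e-9 at p = 0.
.fd_elasticity <- function(target, parameter, p) {
  val <- p[[parameter]]
  h <- if (val != 0) 1e-6 * abs(val) else 1e-9
  up <- p; up[[parameter]] <- val + h
  dn <- p; dn[[parameter]] <- val - h
  dR <- (.target_value(target, up) - .target_value(target, dn)) / (2 * h)
  dR * val / .target_value(target, p)
}

#' @export
print.coex_sensitivity <- function(x, ...) {
  cat(sprintf("<coex_sensitivity> SI_%s(%s) = %.6g (fd %.6g)\n",
              x$target, x$parameter, x$analytic_index, x$fd_index))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Full sensitivity table with published-value comparison
#'
#' All defined indices for both reproduction numbers, each with its
#' finite-difference cross-check and, where a published value exists, a
#' discrepancy flag (`consistent` is `TRUE` when the computed index matches
#' the published one to the printed precision, 0.005). The published
#' entries `-0.85` (gamma2), `-0.546` (gamma1), `-0.346` (mu for the
#' corruption number) and `+1` (Lambda for the corruption number) do not
#' follow from the closed forms at the reference rates; the table records
#' the disagreement instead of asserting either side.
#'
#' @param params Validated parameters.
#' @return `data.frame` with columns `target`, `parameter`, `analytic`,
#'   `fd`, `published`, `consistent`.
#' @export
sensitivity_table <- function(params) {
  p <- validate_parameters(params)
  published <- list(
    "Rr Lambda" = 1, "Rr gamma2" = -0.85, "Rr alpha" = 1,
    "Rc beta" = 1, "Rc gamma1" = -0.546, "Rc mu" = -0.346, "Rc Lambda" = 1
  )
  rows <- list()
  for (target in .si_targets) {
    pars <- union(.si_dependencies[[target]],
                  sub("^R[rc] ", "", grep(paste0("^", target, " "),
                                          names(published), value = TRUE)))
    for (par in pars) {
      si <- sensitivity_index(target, par, p)
      key <- paste(target, par)
      pub <- if (key %in% names(published)) published[[key]] else NA_real_
      rows[[key]] <- data.frame(
        target = target, parameter = par,
        analytic = si$analytic_index, fd = si$fd_index,
        published = pub,
        consistent = if (is.na(pub)) NA else abs(si$analytic_index - pub) <= 0.005
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameter value at which a reproduction number crosses 1
#'
#' Solves `R(target) = 1` for one parameter from the closed form, holding
#' the others fixed. Supported pairs: for `R_r` — `alpha`
#' (`mu(gamma2+mu)/Lambda`), `Lambda` (`mu(gamma2+mu)/alpha`), `gamma2`
#' (`alpha Lambda/mu - mu`), `mu` (positive root of
#' `mu^2 + gamma2 mu - alpha Lambda = 0`); for `R_c` — `beta`
#' (`gamma1 + mu`), `gamma1` (`beta - mu`), `mu` (`beta - gamma1`). When the
#' crossing lies outside the admissible range (a negative rate would be
#' required) the result is `NA` with a `"note"` attribute.
#'
#' @inheritParams sensitivity_index
#' @return The threshold value (numeric), or `NA_real_` with a note
#'   attribute when no admissible crossing exists.
#' @export
threshold_value <- function(target, parameter, params) {
  target <- match.arg(target, .si_targets)
  parameter <- match.arg(parameter, .coex_param_names)
  p <- validate_parameters(params)
  no_threshold <- function(msg) structure(NA_real_, note = msg)

  if (target == "Rr") {
    L <- p[["Lambda"]]; a <- p[["alpha"]]; g2 <- p[["gamma2"]]; mu <- p[["mu"]]
    out <- switch(parameter,
      alpha = mu * (g2 + mu) / L,
      Lambda = if (a > 0) mu * (g2 + mu) / a else no_threshold("alpha = 0: R_r is identically 0"),
      gamma2 = {
        v <- a * L / mu - mu
        if (v >= 0) v else no_threshold("R_r < 1 for every admissible gamma2")
      },
      mu = {
        if (a * L > 0) (-g2 + sqrt(g2^2 + 4 * a * L)) / 2
        else no_threshold("alpha = 0: R_r is identically 0")
      },
      no_threshold("R_r does not depend on this parameter"))
  } else {
    b <- p[["beta"]]; g1 <- p[["gamma1"]]; mu <- p[["mu"]]
    out <- switch(parameter,
      beta = g1 + mu,
      gamma1 = {
        v <- b - mu
        if (v >= 0) v else no_threshold("R_c < 1 for every admissible gamma1")
      },
      mu = {
        v <- b - g1
        if (v > 0) v else no_threshold("R_c < 1 for every admissible mu")
      },
      no_threshold("R_c does not depend on this parameter"))
  }
  out
}

#' Scan a reproduction number over one parameter
#'
#' Evaluates the closed-form target along an even grid of one parameter,
#' for sweep plots and threshold inspection.
#'
#' @inheritParams sensitivity_index
#' @param from,to Range of the scanned parameter; defaults to
#'   `[0, 2 x threshold]` when a threshold exists.
#' @param steps Number of grid points.
#' @return `data.frame` with the parameter grid and the target value.
#' @export
threshold_scan <- function(target, parameter, params, from = NULL, to = NULL,
                           steps = 200L) {
  target <- match.arg(target, .si_targets)
  parameter <- match.arg(parameter, .coex_param_names)
  p <- validate_parameters(params)
  if (is.null(from) || is.null(to)) {
    thr <- threshold_value(target, parameter, p)
    if (is.na(thr)) stop("no threshold to anchor the default range; give from/to",
                         call. = FALSE)
    if (is.null(from)) from <- 0
    if (is.null(to)) to <- 2 * thr
  }
  grid <- seq(from, to, length.out = steps)
  vals <- vapply(grid, function(v) {
    q <- p; q[[parameter]] <- v
    .target_value(target, q)
  }, numeric(1))
  out <- data.frame(grid, vals)
  names(out) <- c(parameter, target)
  out
}
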