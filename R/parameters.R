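#' @keywords internal
"_PACKAGE"

## The 16 model rates, in canonical order.
.coex_param_names <- c(
  "Lambda", "mu", "alpha", "beta", "omega1", "omega2", "eta", "xi",
  "sigma1", "sigma2", "gamma1", "gamma2", "gamma3", "theta1", "theta2", "theta3"
)

#' Model parameters
#'
#' Construct and validate the 16 nonnegative rates of the coexistence model.
#' Time is measured in years; `Lambda` is a recruitment inflow
#' (individuals/year), `mu` the natural removal rate, `alpha` the racism
#' transmission coefficient (mass-action incidence, per individual per year),
#' `beta` the corruption transmission coefficient (standard incidence, per
#' year), `omega1`/`omega2` infectivity amplification of the co-affected
#' class (both at least 1), `eta`/`xi` coexistence-acquisition modification
#' factors, `sigma1`/`sigma2` reversion rates from the co-affected class to
#' the single classes, `gamma1`/`gamma2`/`gamma3` recovery rates from
#' corruption, racism and coexistence, and `theta1`/`theta2`/`theta3`
#' re-susceptibility rates of the recovered classes.
#'
#' @param Lambda,mu,alpha,beta,omega1,omega2,eta,xi,sigma1,sigma2,gamma1,gamma2,gamma3,theta1,theta2,theta3
#'   Nonnegative rates; `mu` and `Lambda` must be positive and
#'   `omega1`, `omega2` at least 1.
#' @return A validated named numeric vector of class `"coex_parameters"`.
#' @seealso [reference_parameters()] for the reference value set,
#'   [read_parameter_config()] for file input.
#' @examples
#' p <- coex_parameters(Lambda = 1, mu = 0.1, alpha = 0.04, gamma2 = 0.1,
#'                      theta2 = 0.1)
#' p[["Lambda"]] / p[["mu"]]  # carrying total population
#' @export
coex_parameters <- function(Lambda = 50, mu = 0.01, alpha = 0, beta = 0,
                            omega1 = 1, omega2 = 1, eta = 1.3, xi = 1.2,
                            sigma1 = 0.6, sigma2 = 0.7,
                            gamma1 = 0.007, gamma2 = 0.006, gamma3 = 0.008,
                            theta1 = 0.3, theta2 = 0.25, theta3 = 0.2) {
  p <- c(Lambda = Lambda, mu = mu, alpha = alpha, beta = beta,
         omega1 = omega1, omega2 = omega2, eta = eta, xi = xi,
         sigma1 = sigma1, sigma2 = sigma2,
         gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
         theta1 = theta1, theta2 = theta2, theta3 = theta3)
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' Checks the invariants of the model rates: all 16 named, numeric, finite
#' and nonnegative; `mu > 0` and `Lambda > 0` (the contagion-free population
#' `Lambda/mu` must exist); `omega1 >= 1` and `omega2 >= 1` (the co-affected
#' class is at least as infectious as the singly affected ones).
#'
#' @param params Named numeric vector or list with exactly the 16 rate names.
#' @return The validated parameters, as a `"coex_parameters"` vector.
#' @export
validate_parameters <- function(params) {
  if (is.list(params)) params <- unlist(params)
  if (!is.numeric(params)) stop("parameters must be numeric", call. = FALSE)
  missing <- setdiff(.coex_param_names, names(params))
  if (length(missing) > 0L) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(params), .coex_param_names)
  if (length(unknown) > 0L) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  params <- params[.coex_param_names]
  if (any(!is.finite(params))) {
    stop("non-finite parameter(s): ",
         paste(names(params)[!is.finite(params)], collapse = ", "), call. = FALSE)
  }
  neg <- names(params)[params < 0]
  if (length(neg) > 0L) {
    stop("negative rate(s): ", paste(neg, collapse = ", "), call. = FALSE)
  }
  if (params[["mu"]] <= 0) stop("mu must be > 0", call. = FALSE)
  if (params[["Lambda"]] <= 0) stop("Lambda must be > 0", call. = FALSE)
  if (params[["omega1"]] < 1) stop("omega1 must be >= 1", call. = FALSE)
  if (params[["omega2"]] < 1) stop("omega2 must be >= 1", call. = FALSE)
  structure(params, class = "coex_parameters")
}

#' Reference parameter values
#'
#' The reference rate set used throughout the numerical experiments
#' (recruitment 50/year, natural removal 0.01/year, recovery rates
#' 0.007/0.006/0.008, re-susceptibility 0.3/0.25/0.2, reversion 0.6/0.7,
#' acquisition modification 1.3/1.2). The transmission coefficients `alpha`
#' and `beta` carry no reference value and must be supplied; the infectivity
#' amplifications `omega1`, `omega2` default to 1 (no amplification).
#'
#' @param alpha,beta Transmission coefficients.
#' @param omega1,omega2 Infectivity amplification of the co-affected class.
#' @param ... Overrides for any other rate, passed to [coex_parameters()].
#' @return A `"coex_parameters"` vector.
#' @examples
#' reference_parameters(alpha = 1e-5, beta = 0.1)
#' @export
reference_parameters <- function(alpha = 1.37, beta = 1.51,
                                 omega1 = 1, omega2 = 1, ...) {
  coex_parameters(Lambda = 50, mu = 0.01, alpha = alpha, beta = beta,
                  omega1 = omega1, omega2 = omega2, eta = 1.3, xi = 1.2,
                  sigma1 = 0.6, sigma2 = 0.7,
                  gamma1 = 0.007, gamma2 = 0.006, gamma3 = 0.008,
                  theta1 = 0.3, theta2 = 0.25, theta3 = 0.2, ...)
}

#' Read a parameter configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) file whose keys are
#' exactly the 16 rate names. Unknown keys and missing keys are errors (the
#' latter listing every absent name), so a truncated or misspelled
#' configuration never silently falls back to defaults.
#'
#' @param path Path to the configuration file.
#' @return A validated `"coex_parameters"` vector.
#' @export
read_parameter_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stop("unsupported config format '", ext, "' (use YAML or JSON)", call. = FALSE)
  )
  if (!is.list(raw) && !is.numeric(raw)) {
    stop("config must be a flat mapping of parameter names to numbers", call. = FALSE)
  }
  validate_parameters(raw)
}

#' Write a parameter configuration file
#'
#' Inverse of [read_parameter_config()]; the format follows the file
#' extension.
#'
#' @param params Parameters to write.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_parameter_config <- function(params, path) {
  params <- validate_parameters(params)
  ext <- tolower(tools::file_ext(path))
  lst <- as.list(as.numeric(params))
  names(lst) <- names(params)
  switch(ext,
    yml = ,
    yaml = yaml::write_yaml(lst, path, precision = 15L),
    json = jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' @export
print.coex_parameters <- function(x, ...) {
  cat("<coex_parameters>\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
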