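## Compartment bookkeeping and the model right-hand sides.

.coex_compartments <- c("S", "C", "R", "C1", "R1", "R2", "R3")

.coex_models <- c("full", "racism", "corruption")

## Compartments that are dynamically active in each (sub)model; the racism
## submodel keeps only susceptibles, racists and racism-recovered, the
## corruption submodel susceptibles, corrupted and corruption-recovered.
.active_idx <- list(
  full       = 1:7,
  racism     = c(1L, 3L, 6L),   # S, R, R2
  corruption = c(1L, 2L, 5L)    # S, C, R1
)

## Infected compartments entering the next-generation decomposition.
.infected_idx <- list(
  full       = c(2L, 3L, 4L),   # C, R, C1
  racism     = c(3L, 6L),       # R, R2
  corruption = c(2L, 5L)        # C, R1
)

.match_model <- function(model) match.arg(model, .coex_models)

#' Compartment names of a model
#'
#' @param model One of `"full"`, `"racism"`, `"corruption"`.
#' @return Character vector of the model's dynamically active compartments
#'   (in full-state order `S, C, R, C1, R1, R2, R3`).
#' @export
model_compartments <- function(model = "full") {
  .coex_compartments[.active_idx[[.match_model(model)]]]
}

#' Construct a model state
#'
#' A state is a named numeric vector over the seven compartments:
#' susceptible `S`, corrupted `C`, racist `R`, co-affected `C1`
#' (simultaneously corrupted and racist), and the recovered classes `R1`
#' (stopped corruption), `R2` (stopped racism), `R3` (stopped both).
#'
#' @param S,C,R,C1,R1,R2,R3 Compartment sizes (individuals), nonnegative.
#' @return Named numeric vector of length 7.
#' @examples
#' coex_state(S = 5000, C = 10)
#' @export
coex_state <- function(S = 0, C = 0, R = 0, C1 = 0, R1 = 0, R2 = 0, R3 = 0) {
  x <- c(S = S, C = C, R = R, C1 = C1, R1 = R1, R2 = R2, R3 = R3)
  if (any(!is.finite(x))) stop("non-finite state entries", call. = FALSE)
  if (any(x < 0)) stop("negative state entries", call. = FALSE)
  x
}

.as_state <- function(state) {
  if (is.null(names(state))) {
    if (length(state) != 7L) stop("state must have 7 components", call. = FALSE)
    names(state) <- .coex_compartments
  } else {
    state <- state[.coex_compartments]
    if (any(is.na(names(state)))) stop("state names must be S,C,R,C1,R1,R2,R3", call. = FALSE)
  }
  if (any(!is.finite(state))) stop("non-finite state entries", call. = FALSE)
  state
}

## Solver round-off: components in [-1e-9, 0) are treated as 0 before
## incidence terms are formed; anything more negative is a genuine error
## upstream and is left alone so that it surfaces.
.clip_state <- function(state, slack = 1e-9) {
  tiny <- state < 0 & state >= -slack
  state[tiny] <- 0
  state
}

#' Forces of infection
#'
#' The per-susceptible acquisition rates of the two contagions. Corruption
#' spreads by standard incidence, `lambda_C = (beta/N) (C + omega1 C1)`
#' with `N` the live total population; racism by mass action,
#' `lambda_R = alpha (R + omega2 C1)` (optionally by standard incidence via
#' `racism_incidence = "standard"`, dividing by `N` as well). An empty
#' population (`N = 0`) has no contacts, so `lambda_C` is defined as 0 there
#' rather than dividing by zero.
#'
#' @param state Full 7-compartment state (nonnegative; entries within
#'   `-1e-9` of 0 are clipped to 0 as solver round-off).
#' @param params Validated [coex_parameters()].
#' @param racism_incidence `"mass_action"` (default) or `"standard"`.
#' @return Named numeric vector `c(lambda_C, lambda_R)` (per year).
#' @examples
#' p <- coex_parameters(alpha = 0.1, beta = 0.5, omega1 = 2, omega2 = 3)
#' forces_of_infection(coex_state(S = 50, C = 10, R = 5, C1 = 5,
#'                                R1 = 10, R2 = 10, R3 = 10), p)
#' @export
forces_of_infection <- function(state, params,
                                racism_incidence = c("mass_action", "standard")) {
  racism_incidence <- match.arg(racism_incidence)
  state <- .clip_state(.as_state(state))
  N <- sum(state)
  w <- state[["C"]] + params[["omega1"]] * state[["C1"]]
  lambda_C <- if (N > 0) params[["beta"]] * w / N else 0
  lambda_R <- params[["alpha"]] * (state[["R"]] + params[["omega2"]] * state[["C1"]])
  if (racism_incidence == "standard") {
    lambda_R <- if (N > 0) lambda_R / N else 0
  }
  c(lambda_C = lambda_C, lambda_R = lambda_R)
}

#' Model right-hand side
#'
#' Time derivative of the seven compartments. Susceptibles are recruited at
#' rate `Lambda`, regained from the recovered classes at rates
#' `theta1 R1 + theta2 R2 + theta3 R3`, and lost to the two contagions and
#' natural removal. Singly affected classes can progress to the co-affected
#' class `C1` (at modified rates `eta lambda_C R` and `xi lambda_R C`), which
#' reverts at rates `sigma1`, `sigma2` or recovers at `gamma3`. For the
#' submodels the absent compartments are pinned to zero (state entries
#' ignored, derivatives 0). The derivatives always sum to `Lambda - mu N`.
#'
#' @inheritParams forces_of_infection
#' @param model `"full"`, `"racism"` or `"corruption"`.
#' @return Named derivative vector of length 7.
#' @export
coex_rhs <- function(model, state, params,
                     racism_incidence = c("mass_action", "standard")) {
  model <- .match_model(model)
  state <- .clip_state(.as_state(state))
  active <- .active_idx[[model]]
  x <- numeric(7L)
  names(x) <- .coex_compartments
  x[active] <- state[active]

  lam <- forces_of_infection(x, params, racism_incidence)
  lC <- lam[["lambda_C"]]
  lR <- lam[["lambda_R"]]
  S <- x[["S"]]; C <- x[["C"]]; R <- x[["R"]]; C1 <- x[["C1"]]
  R1 <- x[["R1"]]; R2 <- x[["R2"]]; R3 <- x[["R3"]]
  p <- params

  d <- c(
    S  = p[["Lambda"]] + p[["theta1"]] * R1 + p[["theta2"]] * R2 +
         p[["theta3"]] * R3 - (lR + lC + p[["mu"]]) * S,
    C  = lC * S + p[["sigma1"]] * C1 - (p[["gamma1"]] + p[["xi"]] * lR + p[["mu"]]) * C,
    R  = lR * S + p[["sigma2"]] * C1 - (p[["eta"]] * lC + p[["gamma2"]] + p[["mu"]]) * R,
    C1 = p[["eta"]] * lC * R + p[["xi"]] * lR * C -
         (p[["sigma2"]] + p[["gamma3"]] + p[["sigma1"]] + p[["mu"]]) * C1,
    R1 = p[["gamma1"]] * C - (p[["theta1"]] + p[["mu"]]) * R1,
    R2 = p[["gamma2"]] * R - (p[["theta2"]] + p[["mu"]]) * R2,
    R3 = p[["gamma3"]] * C1 - (p[["theta3"]] + p[["mu"]]) * R3
  )
  d[setdiff(1:7, active)] <- 0
  d
}
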