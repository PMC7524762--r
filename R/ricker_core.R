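#' Deterministic Ricker growth mathematics
#'
#' The discrete Ricker model \eqn{N_{t+1} = \alpha N_t e^{-\beta_\Delta N_t}}
#' linearizes to the growth response \eqn{r_t = \ln(N_{t+1}/N_t) = r_{max} +
#' \beta N_t}, with \eqn{r_{max} = \ln \alpha}. In the linearized form the
#' fitted slope \eqn{\beta} is negative under density dependence; the classical
#' form uses the positive decay rate \eqn{\beta_\Delta = |\beta|}. All sign
#' conversions live in this file.
#'
#' @name ricker_core
NULL

#' Growth-response parameters
#'
#' Container for the parameters of a linearized Ricker growth response,
#' optionally with per-year temporal effects (an additive offset `gamma_t` on
#' the growth rate and/or a year-specific slope `beta_t`).
#'
#' @param r_max intrinsic (maximum) per-capita growth rate, per year.
#' @param beta slope of the growth response in abundance (per animal per
#'   year); negative under density dependence.
#' @param gamma_t optional named numeric vector of per-year growth-rate
#'   offsets (names are years).
#' @param beta_t optional named numeric vector of per-year slopes; when a year
#'   is present here it replaces `beta` in predictions for that year.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(r_max, beta, gamma_t = NULL, beta_t = NULL) {
  stopifnot(is.numeric(r_max), length(r_max) == 1L, is.finite(r_max),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (!is.null(gamma_t) && is.null(names(gamma_t)))
    stop("gamma_t must be named by year")
  if (!is.null(beta_t) && is.null(names(beta_t)))
    stop("beta_t must be named by year")
  structure(list(r_max = r_max, beta = beta,
                 gamma_t = gamma_t, beta_t = beta_t),
            class = "growth_params")
}

#' Expected per-capita growth rate at abundance N
#'
#' Evaluates \eqn{r_{max} (+ \gamma_{year}) + (\beta~or~\beta_{year}) N}
#' with no noise. If `year` is supplied the stored temporal effects for that
#' year are used; requesting a year when no temporal effects are stored is an
#' error.
#'
#' @param N abundance (animals), vectorized; must be non-negative.
#' @param params a [growth_params] object.
#' @param year optional integer year selecting temporal effects.
#' @return Expected growth rate(s), per year.
#' @export
expected_growth <- function(N, params, year = NULL) {
  stopifnot(inherits(params, "growth_params"), is.numeric(N), all(N >= 0))
  g <- 0
  b <- params$beta
  if (!is.null(year)) {
    if (is.null(params$gamma_t) && is.null(params$beta_t))
      stop("year requested but no temporal effects stored in params")
    y <- as.character(year)
    if (!is.null(params$gamma_t) && y %in% names(params$gamma_t))
      g <- params$gamma_t[[y]]
    if (!is.null(params$beta_t) && y %in% names(params$beta_t))
      b <- params$beta_t[[y]]
  }
  params$r_max + g + b * N
}

#' Carrying capacity as the x-intercept of the growth response
#'
#' K is the abundance at which the expected growth rate is zero:
#' \eqn{K = -r_{max}/\beta}, positive when \eqn{\beta < 0 < r_{max}}. A
#' positive `beta` (no regulation) yields a negative K, returned with
#' attribute `regulated = FALSE`.
#'
#' @param r_max intrinsic growth rate (per year).
#' @param beta slope (per animal per year); must be non-zero.
#' @return Carrying capacity (animals) with logical attribute `regulated`.
#' @export
carrying_capacity <- function(r_max, beta) {
  stopifnot(is.numeric(r_max), is.numeric(beta))
  if (any(beta == 0)) stop("carrying capacity undefined for beta = 0")
  K <- -r_max / beta
  attr(K, "regulated") <- beta < 0
  K
}

#' Classical-form multiplier alpha
#'
#' Converts the linearized intercept to the classical Ricker multiplier:
#' \eqn{\alpha = e^{r_{max}}}.
#'
#' @param r_max intrinsic growth rate (per year), vectorized.
#' @return alpha (dimensionless).
#' @export
classical_form <- function(r_max) exp(r_max)
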