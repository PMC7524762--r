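#' Demographic / environmental stochasticity decomposition
#'
#' Predicted variance of next abundance under the classical Ricker map
#' \eqn{N_t = \alpha N_{t-1} e^{-\beta_\Delta N_{t-1}}} splits into three
#' components:
#' \deqn{Var(N) = Var_{dem}(N) + Var_r(N) + Var_\beta(N)}
#' with
#' \deqn{Var_{dem}(N) = \alpha N e^{-\beta_\Delta N}(1 - e^{-\beta_\Delta N})
#'   + \sigma_{dem}^2 N e^{-2\beta_\Delta N},}
#' \deqn{Var_r(N) = \sigma_r^2 \alpha^2 N^2 e^{-2\beta_\Delta N},}
#' \deqn{Var_\beta(N) = \sigma_\beta^2 \alpha^2 N^4 e^{-2\beta_\Delta N}.}
#' At the carrying capacity \eqn{K = r_{max}/\beta_\Delta} (where
#' \eqn{e^{-\beta_\Delta K} = 1/\alpha}) these collapse to
#' \eqn{Var_{dem}(K) = K} (with the conventional \eqn{\sigma_{dem}^2 =
#' \alpha}), \eqn{Var_r(K) = \sigma_r^2 K^2} and
#' \eqn{Var_\beta(K) = \sigma_\beta^2 K^4}.
#'
#' @name stochasticity
NULL

#' Stochasticity parameters
#'
#' `beta_mag` is the magnitude of the fitted (negative) growth-response
#' slope; conversion from the fitted sign happens here, once. The
#' density-independent variance `sigma_r_sq` is the caller's choice: the
#' fitted temporal-r variance \eqn{\sigma_\gamma^2} under the default mode,
#' or the temporal-slope variance under the `as_printed` mode (see
#' [stoch_params_from_estimates]).
#'
#' @param alpha classical-form multiplier \eqn{e^{r_{max}}} (> 0).
#' @param beta_mag positive density-dependence decay rate (per animal).
#' @param sigma_dem_sq demographic variance scale; conventionally `alpha`.
#' @param sigma_r_sq density-independent (temporal-r) variance.
#' @param sigma_beta_sq density-dependent (temporal-slope) variance.
#' @return A `stoch_params` object.
#' @export
stoch_params <- function(alpha, beta_mag, sigma_dem_sq = alpha,
                         sigma_r_sq = 0, sigma_beta_sq = 0) {
  stopifnot(alpha > 0, beta_mag > 0, sigma_dem_sq >= 0, sigma_r_sq >= 0,
            sigma_beta_sq >= 0)
  structure(list(alpha = alpha, beta_mag = beta_mag,
                 sigma_dem_sq = sigma_dem_sq, sigma_r_sq = sigma_r_sq,
                 sigma_beta_sq = sigma_beta_sq), class = "stoch_params")
}

#' Build stochasticity parameters from a herd's fitted estimates
#'
#' @param est one row of [summarize_herds] output.
#' @param sigma_r_mode `"fitted_gamma"` (default; uses the temporal-r SD
#'   \eqn{\sigma_\gamma}, zero when the selected variant has none) or
#'   `"as_printed"` (reuses the temporal-slope SD, the form the source
#'   equations print — almost certainly a transcription artifact, provided
#'   for strict reproduction).
#' @return A `stoch_params` object.
#' @export
stoch_params_from_estimates <- function(est,
                                        sigma_r_mode = c("fitted_gamma",
                                                         "as_printed")) {
  sigma_r_mode <- match.arg(sigma_r_mode)
  stopifnot(nrow(est) == 1)
  if (est$beta >= 0)
    stop("no density dependence fitted for herd ", est$herd,
         " (beta >= 0); stochasticity profile undefined")
  sg <- if (is.na(est$sigma_gamma)) 0 else est$sigma_gamma
  sb <- if (is.na(est$sigma_betad)) 0 else est$sigma_betad
  sr <- if (sigma_r_mode == "fitted_gamma") sg else sb
  stoch_params(alpha = classical_form(est$r_max), beta_mag = abs(est$beta),
               sigma_r_sq = sr^2, sigma_beta_sq = sb^2)
}

#' Demographic stochasticity component
#' @param N abundance (animals), vectorized, non-negative.
#' @param p a [stoch_params].
#' @return Variance (animals^2).
#' @export
var_dem <- function(N, p) {
  stopifnot(inherits(p, "stoch_params"), all(N >= 0))
  e <- exp(-p$beta_mag * N)
  p$alpha * N * e * (1 - e) + p$sigma_dem_sq * N * e^2
}

#' Density-independent (temporal-r) stochasticity component
#' @inheritParams var_dem
#' @export
var_r <- function(N, p) {
  stopifnot(inherits(p, "stoch_params"), all(N >= 0))
  p$sigma_r_sq * p$alpha^2 * N^2 * exp(-2 * p$beta_mag * N)
}

#' Density-dependent (temporal-slope) stochasticity component
#' @inheritParams var_dem
#' @export
var_beta <- function(N, p) {
  stopifnot(inherits(p, "stoch_params"), all(N >= 0))
  p$sigma_beta_sq * p$alpha^2 * N^4 * exp(-2 * p$beta_mag * N)
}

#' Stochasticity decomposition over an abundance grid
#'
#' Evaluates the three components and their total on a grid from 5 animals
#' to 1.2 K (inclusive, at least `n_grid` points).
#'
#' @param p a [stoch_params].
#' @param K carrying capacity (animals), must exceed 5.
#' @param n_grid number of grid points (>= 50).
#' @return data.frame: N, var_dem, var_r, var_beta, var_total.
#' @export
decomposition_profile <- function(p, K, n_grid = 100) {
  stopifnot(inherits(p, "stoch_params"))
  if (K <= 5) stop("grid undefined: K must exceed 5 animals")
  n_grid <- max(n_grid, 50)
  N <- seq(5, 1.2 * K, length.out = n_grid)
  d <- var_dem(N, p); r <- var_r(N, p); b <- var_beta(N, p)
  data.frame(N = N, var_dem = d, var_r = r, var_beta = b,
             var_total = d + r + b)
}

#' Relative total stochasticity at carrying capacity
#'
#' Total predicted abundance variance evaluated at K, divided by K — a
#' per-capita measure of fluctuation around equilibrium.
#'
#' @param p a [stoch_params].
#' @param K carrying capacity (> 0).
#' @return Dimensionless ratio.
#' @export
relative_total_stochasticity <- function(p, K) {
  stopifnot(K > 0)
  (var_dem(K, p) + var_r(K, p) + var_beta(K, p)) / K
}
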