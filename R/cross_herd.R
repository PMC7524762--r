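#' Cross-herd inverse regressions
#'
#' Two herd-level relationships are summarized by ordinary least squares of a
#' response on the reciprocal of a positive predictor (y ~ 1/x): temporal
#' variation in the strength of density dependence against carrying capacity,
#' and the strength of density dependence against relative total
#' stochasticity. Posterior medians feed the fits; herds in which density
#' dependence was not detected are excluded first.
#'
#' @name cross_herd
NULL

#' Ordinary least squares of y on 1/x
#'
#' @param x positive predictor values (n >= 3).
#' @param y response values.
#' @return A `regression_result`: list with `slope`, `intercept` (on the
#'   transformed scale y = slope/x + intercept), `r_squared`, `p_value`
#'   (two-sided t test on the slope, n - 2 df), `n`, and the underlying
#'   `lm` fit.
#' @export
inverse_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (any(x <= 0)) stop("all predictor values must be positive")
  u <- 1 / x
  if (stats::var(u) == 0) stop("degenerate predictor: zero variance in 1/x")
  fit <- stats::lm(y ~ u)
  sm <- suppressWarnings(summary(fit))  # noiseless input is legitimate
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(x), fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.4g/x + %.4g  (R^2 = %.3f, P = %.3g, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

.eligible <- function(estimates) {
  keep <- estimates$density_dependence_detected
  dropped <- estimates$herd[!keep]
  if (length(dropped))
    message("excluding herd(s) without detected density dependence: ",
            paste(dropped, collapse = ", "))
  est <- estimates[keep, , drop = FALSE]
  if (nrow(est) < 3)
    stop("need >= 3 herds with detected density dependence; have ", nrow(est))
  est
}

#' Temporal slope variation vs carrying capacity
#'
#' Regresses the posterior-median temporal-slope SD on the reciprocal of the
#' posterior-median carrying capacity across herds with detected density
#' dependence.
#'
#' @param estimates data.frame of per-herd estimates ([summarize_herds]).
#' @return A `regression_result`.
#' @export
fig_k_analysis <- function(estimates) {
  est <- .eligible(estimates)
  if (any(is.na(est$sigma_betad)))
    stop("temporal-slope SD missing for herd(s): ",
         paste(est$herd[is.na(est$sigma_betad)], collapse = ", "))
  inverse_regression(est$K, est$sigma_betad)
}

#' Density dependence vs relative total stochasticity
#'
#' Regresses the posterior-median growth-response slope on the reciprocal of
#' each eligible herd's relative total stochasticity. The sign of the slope
#' is the robust output here; exact coefficients depend on an x-axis
#' construction that is not fully determined (see the methods vignette).
#'
#' @param estimates data.frame of per-herd estimates ([summarize_herds]).
#' @param sigma_r_mode passed to [stoch_params_from_estimates].
#' @return A `regression_result` with an extra element `inputs` (herd,
#'   relative total stochasticity, beta).
#' @export
fig_stoch_analysis <- function(estimates,
                               sigma_r_mode = c("fitted_gamma",
                                                "as_printed")) {
  sigma_r_mode <- match.arg(sigma_r_mode)
  est <- .eligible(estimates)
  rts <- vapply(seq_len(nrow(est)), function(i) {
    p <- stoch_params_from_estimates(est[i, , drop = FALSE], sigma_r_mode)
    relative_total_stochasticity(p, est$K[i])
  }, 0)
  res <- inverse_regression(rts, est$beta)
  res$inputs <- data.frame(herd = est$herd, relative_total_stochasticity = rts,
                           beta = est$beta)
  res
}
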