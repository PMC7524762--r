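#' Hierarchical Bayesian fitting of the linearized Ricker models
#'
#' Four per-herd model variants are available for the growth response
#' \eqn{r_t}: `none` (\eqn{r_{max,j} + \beta_j N_t}), `r_var` (adds a
#' zero-centred temporal effect \eqn{\gamma_{t,j}}), `beta_var` (replaces
#' \eqn{\beta_j} with per-year slopes \eqn{\beta_{\delta t,j} \sim
#' N(\mu_{\beta\delta,j}, \sigma_{\beta\delta,j})}) and `both`. All herds are
#' fitted jointly: \eqn{r_{max,j}} is a random effect drawn from a common
#' normal distribution (borrowing strength among herds) while every
#' \eqn{\beta} parameter is herd-specific, and a single residual SD is shared
#' across herds. Per-herd variants are chosen by posterior mean deviance with
#' a margin-of-2 rule.
#'
#' @name bayes_fit
NULL

#' Model variant labels in complexity order
#' @export
model_variants <- function() c("none", "r_var", "beta_var", "both")

.variant_code <- function(v) {
  match(match.arg(v, model_variants()), model_variants()) - 1L
}
.variant_complexity <- c(none = 0L, r_var = 1L, beta_var = 1L, both = 2L)

#' Prior specification
#'
#' Means (hyper-mean of r_max, the fixed slopes and the slope hyper-means)
#' get vague zero-centred normals with precision `mean_prior_precision`
#' (0.001, i.e. variance 1000, the JAGS-style parameterization); every SD
#' (among-herd r_max SD, temporal-effect SDs, residual SD) gets a
#' Uniform(0, `sd_upper`) prior.
#'
#' @param mean_prior_precision precision of the normal priors on means.
#' @param sd_upper upper bound of the uniform priors on SDs.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(mean_prior_precision = 0.001, sd_upper = 100) {
  stopifnot(mean_prior_precision > 0, sd_upper > 0)
  structure(list(mean_prior_precision = mean_prior_precision,
                 sd_upper = sd_upper), class = "prior_spec")
}

#' MCMC run configuration
#'
#' Defaults mirror the full-scale analysis (3 chains of 150,000 iterations,
#' burn-in 75,000, adaptation 75,000, no thinning). The adaptation period is
#' run as extra discarded warm-up before the counted iterations; retained
#' draws per chain = `(iterations - burn_in) / thinning`.
#'
#' @param chains number of chains (>= 2 for convergence checking).
#' @param iterations counted iterations per chain.
#' @param burn_in leading counted iterations discarded.
#' @param adaptation extra warm-up sweeps run before the counted iterations.
#' @param thinning keep every `thinning`-th retained draw.
#' @param seed integer master seed; per-chain streams derive from it.
#' @return An `mcmc_config` object.
#' @export
mcmc_config <- function(chains = 3, iterations = 150000, burn_in = 75000,
                        adaptation = 75000, thinning = 1, seed = 1L) {
  stopifnot(chains >= 1, thinning >= 1, burn_in >= 0, adaptation >= 0,
            burn_in < iterations)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 adaptation = as.integer(adaptation),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed)), class = "mcmc_config")
}

#' Reduced configuration for quick runs and tests
#' @param seed integer seed.
#' @param iterations counted iterations (half are burn-in).
#' @export
quick_config <- function(seed = 1L, iterations = 10000) {
  mcmc_config(chains = 3, iterations = iterations,
              burn_in = iterations %/% 2, adaptation = iterations %/% 10,
              thinning = 1, seed = seed)
}

# column layout of one herd's block, shared by init builder and names
.herd_layout <- function(herd, variant, years) {
  rv <- variant %in% c("r_var", "both")
  bv <- variant %in% c("beta_var", "both")
  nm <- sprintf("rmax[%s]", herd)
  if (rv) nm <- c(nm, sprintf("sigma_gamma[%s]", herd),
                  sprintf("gamma[%s,%d]", herd, years))
  if (bv) nm <- c(nm, sprintf("mu_betad[%s]", herd),
                  sprintf("sigma_betad[%s]", herd),
                  sprintf("betad[%s,%d]", herd, years))
  else nm <- c(nm, sprintf("beta[%s]", herd))
  nm
}

.build_init <- function(obs_list, assignment, jitter_sd = 0) {
  herds <- names(obs_list)
  ols <- lapply(obs_list, function(d) {
    f <- stats::lm(r_t ~ N_t, data = d)
    list(a = unname(stats::coef(f)[1]), b = unname(stats::coef(f)[2]),
         s = max(suppressWarnings(summary(f))$sigma, 1e-3))
  })
  a <- vapply(ols, `[[`, 0, "a")
  jit <- function(x, scale) x + stats::rnorm(length(x), 0, jitter_sd * scale)
  sd_a <- if (length(a) > 1) stats::sd(a) else 0
  init <- c(jit(mean(a), 0.2), max(sd_a, 0.02, na.rm = TRUE) * exp(jit(0, 1)),
            mean(vapply(ols, `[[`, 0, "s")) * exp(jit(0, 1)))
  for (h in herds) {
    v <- assignment[[h]]
    n <- nrow(obs_list[[h]])
    b0 <- ols[[h]]$b
    if (!is.finite(b0)) b0 <- 0
    init <- c(init, jit(ols[[h]]$a, 0.2))
    if (v %in% c("r_var", "both"))
      init <- c(init, 0.05 * exp(jit(0, 1)), rep(0, n))
    if (v %in% c("beta_var", "both"))
      init <- c(init, jit(b0, max(abs(b0), 1e-3)),
                max(abs(b0) / 2, 1e-4) * exp(jit(0, 1)), rep(b0, n))
    else
      init <- c(init, jit(b0, max(abs(b0), 1e-3)))
  }
  init
}

#' Fit the joint hierarchical model
#'
#' @param obs_list named list of per-herd growth-observation data.frames
#'   (see [growth_observations]), each with at least 2 rows.
#' @param assignment named character vector/list giving each herd's variant
#'   (one of [model_variants()]); a single unnamed value is recycled.
#' @param priors a [prior_spec].
#' @param config an [mcmc_config].
#' @param check if `TRUE` (default), attach a convergence report and warn on
#'   failure (never silently).
#' @return A `posterior_draws` object: per-chain matrices of retained draws
#'   (one named column per parameter plus `deviance`), with the assignment,
#'   config and convergence report attached.
#' @export
fit_joint <- function(obs_list, assignment = "none", priors = prior_spec(),
                      config = quick_config(), check = TRUE) {
  stopifnot(is.list(obs_list), length(obs_list) >= 1)
  if (is.null(names(obs_list)))
    names(obs_list) <- vapply(obs_list, function(d) as.character(d$herd[1]), "")
  herds <- names(obs_list)
  if (length(assignment) == 1L && is.null(names(assignment)))
    assignment <- stats::setNames(rep(as.character(assignment),
                                      length(herds)), herds)
  assignment <- vapply(herds, function(h) {
    if (!h %in% names(assignment)) stop("assignment missing for herd ", h)
    match.arg(assignment[[h]], model_variants())
  }, "")
  bad <- herds[vapply(obs_list, nrow, 0L) < 2L]
  if (length(bad))
    stop("need >= 2 growth observations per herd; too few for: ",
         paste(bad, collapse = ", "))

  par_names <- c("mu_rmax", "sigma_rmax", "sigma_eps",
                 unlist(lapply(herds, function(h)
                   .herd_layout(h, assignment[[h]], obs_list[[h]]$year_t))),
                 "deviance")
  variant_codes <- vapply(assignment, .variant_code, 0L)
  n_iter <- ((config$iterations - config$burn_in) %/% config$thinning) *
    config$thinning
  herd_N <- lapply(obs_list, `[[`, "N_t")
  herd_r <- lapply(obs_list, `[[`, "r_t")

  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed * 1000L + ch)
    init <- .build_init(obs_list, assignment,
                        jitter_sd = if (ch == 1L) 0 else 0.5)
    m <- .ricker_gibbs_chain(herd_N, herd_r, unname(variant_codes),
                             1 / priors$mean_prior_precision,
                             priors$sd_upper,
                             config$adaptation + config$burn_in,
                             n_iter, config$thinning, init)
    colnames(m) <- par_names
    chains[[ch]] <- m
  }
  draws <- structure(list(chains = chains, herds = herds,
                          assignment = assignment, priors = priors,
                          config = config,
                          obs_years = lapply(obs_list, `[[`, "year_t")),
                     class = "posterior_draws")
  if (check && config$chains >= 2L) {
    conv <- check_convergence(draws)
    draws$convergence <- conv
    if (!attr(conv, "pass"))
      warning("convergence check failed: max split-Rhat = ",
              round(max(conv$rhat, na.rm = TRUE), 3), call. = FALSE)
  }
  draws
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws> ", length(x$herds), " herd(s), ",
      length(x$chains), " chains x ", nrow(x$chains[[1]]),
      " retained draws, ", ncol(x$chains[[1]]), " parameters\n", sep = "")
  cat("  variants:", paste(x$herds, x$assignment, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Stack retained draws across chains
#'
#' @param draws a `posterior_draws`.
#' @param pars optional character vector of parameter names to keep.
#' @return Matrix with one column per parameter, chains stacked row-wise.
#' @export
draws_matrix <- function(draws, pars = NULL) {
  m <- do.call(rbind, draws$chains)
  if (!is.null(pars)) {
    missing <- setdiff(pars, colnames(m))
    if (length(missing))
      stop("unknown parameter(s): ", paste(missing, collapse = ", "))
    m <- m[, pars, drop = FALSE]
  }
  m
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Each chain is split in half; the potential scale reduction factor is
#' computed from the between- and within-sequence variances of the resulting
#' half-chains. Overall pass requires every parameter's split-Rhat < 1.01.
#' Parameters with (near-)zero total variance are reported as NA.
#'
#' @param draws a `posterior_draws`, or a list/array of chain matrices with
#'   equal dimensions.
#' @return data.frame (parameter, rhat) with logical attribute `pass`.
#' @export
check_convergence <- function(draws) {
  chains <- if (inherits(draws, "posterior_draws")) draws$chains else draws
  if (is.matrix(chains)) stop("need >= 2 chains for the diagnostic")
  stopifnot(length(chains) >= 2L)
  n <- nrow(chains[[1]])
  half <- n %/% 2L
  splits <- unlist(lapply(chains, function(m)
    list(m[seq_len(half), , drop = FALSE],
         m[seq.int(n - half + 1L, n), , drop = FALSE])), recursive = FALSE)
  rhat <- vapply(seq_len(ncol(chains[[1]])), function(p) {
    s <- vapply(splits, function(m) m[, p], numeric(half))  # half x 2C
    split_rhat(s)
  }, 0)
  out <- data.frame(parameter = colnames(chains[[1]]), rhat = rhat)
  structure(out, pass = all(out$rhat < 1.01, na.rm = TRUE))
}

#' Split-Rhat of a draws-by-sequences matrix
#'
#' @param s numeric matrix, one column per (half-)sequence.
#' @return The potential scale reduction factor, NA for degenerate input.
#' @export
split_rhat <- function(s) {
  n <- nrow(s); m <- ncol(s)
  mu <- colMeans(s)
  W <- mean(apply(s, 2, stats::var))
  B <- n * stats::var(mu)
  if (!is.finite(W) || W <= 1e-300 * max(1, B)) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior mean deviance
#'
#' Deviance is joint over all herds: per retained draw,
#' \eqn{-2 \sum \log N(r_{t,j} \mid \mu_{t,j}, \sigma_\epsilon)}.
#'
#' @param draws a `posterior_draws`.
#' @return Mean deviance over all retained draws of all chains.
#' @export
mean_deviance <- function(draws) {
  mean(draws_matrix(draws, "deviance"))
}

#' Select a herd's variant from its four mean deviances
#'
#' The minimum-deviance variant is selected if it beats the runner-up by
#' more than 2; otherwise the simplest variant among those within 2 of the
#' minimum wins (complexity order none < r_var = beta_var < both; ties at
#' equal complexity go to the lower deviance).
#'
#' @param deviances numeric length-4 vector of mean deviances, in the order
#'   of [model_variants()] (names optional but checked if present).
#' @param margin selection margin (2 deviance units).
#' @return One of [model_variants()].
#' @export
select_variant <- function(deviances, margin = 2) {
  stopifnot(length(deviances) == 4, all(is.finite(deviances)))
  v <- model_variants()
  if (!is.null(names(deviances))) {
    stopifnot(setequal(names(deviances), v))
    deviances <- deviances[v]
  } else names(deviances) <- v
  ord <- order(deviances)
  best <- ord[1]
  if (deviances[ord[2]] - deviances[best] > margin) return(v[best])
  cand <- v[deviances <= deviances[best] + margin]
  comp <- .variant_complexity[cand]
  cand <- cand[comp == min(comp)]
  cand[which.min(deviances[cand])]
}

#' Per-herd variant selection by one-at-a-time upgraded joint fits
#'
#' A baseline joint fit places every herd on `none`; then, for each herd in
#' turn, three further joint fits upgrade only that herd's variant. The
#' resulting herds-by-variants matrix of joint mean deviances (its first
#' column constant, equal to the baseline) feeds [select_variant] per herd.
#'
#' @inheritParams fit_joint
#' @param keep_fits keep the upgraded fit for each herd's selected variant
#'   (needed downstream by [summarize_herds]).
#' @return List with `deviance` (herds x 4 matrix), `selection` (named
#'   character vector) and, if `keep_fits`, `fits` (named list of
#'   `posterior_draws` for each herd's selected variant; the baseline fit is
#'   used where `none` was selected).
#' @export
selection_procedure <- function(obs_list, priors = prior_spec(),
                                config = quick_config(), keep_fits = TRUE) {
  herds <- names(obs_list)
  v <- model_variants()
  base <- fit_joint(obs_list, "none", priors, config, check = FALSE)
  dev <- matrix(NA_real_, length(herds), 4,
                dimnames = list(herds, v))
  dev[, "none"] <- mean_deviance(base)
  fits <- list()
  for (h in herds) {
    for (var in v[-1]) {
      assignment <- stats::setNames(rep("none", length(herds)), herds)
      assignment[h] <- var
      f <- tryCatch(
        fit_joint(obs_list, assignment, priors, config, check = FALSE),
        error = function(e) stop("fit failed for herd ", h, " variant ", var,
                                 ": ", conditionMessage(e), call. = FALSE))
      dev[h, var] <- mean_deviance(f)
      if (keep_fits) fits[[paste(h, var, sep = ".")]] <- f
    }
  }
  selection <- vapply(herds, function(h) select_variant(dev[h, ]), "")
  out <- list(deviance = dev, selection = selection)
  if (keep_fits) {
    out$fits <- lapply(herds, function(h) {
      if (selection[[h]] == "none") base
      else fits[[paste(h, selection[[h]], sep = ".")]]
    })
    names(out$fits) <- herds
  }
  out
}

#' Posterior summaries for one herd
#'
#' Medians and central 95% credible intervals for r_max, the temporal-r SD,
#' the slope (the fixed \eqn{\beta_j}, or \eqn{\mu_{\beta\delta,j}} under
#' slope-varying variants), the temporal-slope SD, and carrying capacity K
#' computed per draw as \eqn{-r_{max,j}/\beta}. Density dependence is
#' "detected" when the slope's 95% CrI lies entirely below zero; herds
#' failing detection are flagged for exclusion from downstream stages.
#'
#' @param draws a `posterior_draws` containing the herd.
#' @param herd herd identifier.
#' @param K_beta `"mean"` (default: per-draw \eqn{\mu_{\beta\delta}}) or
#'   `"per_year"` (pool per-draw, per-year \eqn{-r_{max}/\beta_{\delta t}}).
#' @return One-row data.frame of estimates with `_lo`/`_hi` CrI columns and
#'   `density_dependence_detected`.
#' @export
summarize_herd <- function(draws, herd, K_beta = c("mean", "per_year")) {
  K_beta <- match.arg(K_beta)
  stopifnot(herd %in% draws$herds)
  variant <- draws$assignment[[herd]]
  m <- draws_matrix(draws)
  q <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  rmax <- m[, sprintf("rmax[%s]", herd)]
  bcol <- if (variant %in% c("beta_var", "both"))
    sprintf("mu_betad[%s]", herd) else sprintf("beta[%s]", herd)
  beta <- m[, bcol]
  qr <- q(rmax); qb <- q(beta)
  qs <- if (variant %in% c("r_var", "both"))
    q(m[, sprintf("sigma_gamma[%s]", herd)]) else rep(NA_real_, 3)
  qbd <- if (variant %in% c("beta_var", "both"))
    q(m[, sprintf("sigma_betad[%s]", herd)]) else rep(NA_real_, 3)
  Kdraws <- if (K_beta == "per_year" && variant %in% c("beta_var", "both")) {
    bd <- m[, grep(sprintf("^betad\\[%s,", herd), colnames(m),
                   fixed = FALSE), drop = FALSE]
    as.vector(-rmax / bd)
  } else -rmax / beta
  qK <- q(Kdraws)
  data.frame(herd = herd, variant = variant,
             r_max = qr[1], r_max_lo = qr[2], r_max_hi = qr[3],
             sigma_gamma = qs[1], sigma_gamma_lo = qs[2],
             sigma_gamma_hi = qs[3],
             beta = qb[1], beta_lo = qb[2], beta_hi = qb[3],
             sigma_betad = qbd[1], sigma_betad_lo = qbd[2],
             sigma_betad_hi = qbd[3],
             K = qK[1], K_lo = qK[2], K_hi = qK[3],
             density_dependence_detected = unname(qb[3] < 0),
             row.names = NULL)
}

#' Posterior summaries for every herd of a selection result
#'
#' @param sel output of [selection_procedure] with `keep_fits = TRUE`, or a
#'   single `posterior_draws` covering all herds.
#' @inheritParams summarize_herd
#' @return data.frame with one row per herd (Table-2 style).
#' @export
summarize_herds <- function(sel, K_beta = c("mean", "per_year")) {
  K_beta <- match.arg(K_beta)
  if (inherits(sel, "posterior_draws")) {
    rows <- lapply(sel$herds, function(h) summarize_herd(sel, h, K_beta))
  } else {
    rows <- lapply(names(sel$fits), function(h)
      summarize_herd(sel$fits[[h]], h, K_beta))
  }
  do.call(rbind, rows)
}

#' Export retained draws as one long CSV-ready data.frame
#'
#' @param draws a `posterior_draws`.
#' @return data.frame: chain, iteration, then one column per parameter.
#' @export
draws_as_df <- function(draws) {
  do.call(rbind, lapply(seq_along(draws$chains), function(ch) {
    m <- draws$chains[[ch]]
    cbind(data.frame(chain = ch, iteration = seq_len(nrow(m))),
          as.data.frame(m, check.names = FALSE))
  }))
}
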