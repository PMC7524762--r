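#' Synthetic multi-herd Ricker datasets
#'
#' Forward-simulates herd abundance under the stochastic linearized Ricker
#' model the inference stage assumes: on the log scale,
#' \deqn{\ln N_{t+1} = \ln N_t + r_{max} + \gamma_t + \beta_t N_t + \epsilon_t,}
#' with \eqn{\gamma_t \sim N(0, \sigma_\gamma)},
#' \eqn{\beta_t \sim N(\bar\beta, \sigma_\beta)} and
#' \eqn{\epsilon_t \sim N(0, \sigma_\epsilon)}. Latent abundance is kept
#' continuous and floored at one animal; observation draws binomial counts at
#' a fixed detection probability from the rounded latent abundance (a
#' stand-in: the source surveys report only that detection exceeded 0.8).
#' Harvest is removed after growth, before the next observation, and recorded
#' in the harvest table.
#'
#' @name synthetic_data
NULL

#' Simulation parameters for one herd
#'
#' Defaults mirror the scale of the elk monitoring series the model targets:
#' about two decades of annual surveys, r_max near 0.23, carrying capacities
#' of tens to hundreds of animals, and high detection.
#'
#' @param r_max intrinsic growth rate (per year).
#' @param beta_mean mean growth-response slope (per animal per year,
#'   negative for density dependence).
#' @param sigma_gamma SD of temporal growth-rate effects (per year).
#' @param sigma_beta SD of temporal slope effects (per animal per year).
#' @param epsilon_sd residual SD of the realized growth rate (per year).
#' @param N0 initial abundance (animals).
#' @param T series length (years), at least 2.
#' @param detection_p per-animal detection probability in (0, 1].
#' @param n_replicates surveys per year.
#' @param missing_years integer years (1-based within the series) dropped
#'   from the survey table.
#' @param annual_harvest animals removed per year.
#' @param first_year calendar year of the first survey.
#' @return A `herd_sim_params` object.
#' @export
herd_sim_params <- function(r_max = 0.23, beta_mean = -0.0046,
                            sigma_gamma = 0, sigma_beta = 0,
                            epsilon_sd = 0.1, N0 = 25, T = 20,
                            detection_p = 0.9, n_replicates = 4,
                            missing_years = integer(), annual_harvest = 0,
                            first_year = 1997L) {
  stopifnot(T >= 2, sigma_gamma >= 0, sigma_beta >= 0, epsilon_sd >= 0,
            detection_p > 0, detection_p <= 1, N0 > 0, n_replicates >= 1,
            annual_harvest >= 0)
  structure(as.list(environment()), class = "herd_sim_params")
}

#' Simulate one herd
#'
#' @param params a [herd_sim_params].
#' @param seed integer seed; identical seed gives identical output.
#' @return List with `latent` (a [herd_series] of the true abundance over all
#'   years), `surveys` (survey-record data.frame, missing years removed),
#'   `harvests` (harvest-record data.frame, empty when no harvest), and
#'   `truth` (the parameters plus realized temporal effects).
#' @export
simulate_herd <- function(params, seed = 1L, herd = "herd1") {
  stopifnot(inherits(params, "herd_sim_params"))
  set.seed(as.integer(seed))
  p <- params
  N <- numeric(p$T)
  N[1] <- p$N0
  gam <- stats::rnorm(p$T - 1, 0, p$sigma_gamma)
  bet <- stats::rnorm(p$T - 1, p$beta_mean, p$sigma_beta)
  eps <- stats::rnorm(p$T - 1, 0, p$epsilon_sd)
  for (t in seq_len(p$T - 1)) {
    lnN <- log(N[t]) + p$r_max + gam[t] + bet[t] * N[t] + eps[t]
    N[t + 1] <- max(exp(lnN) - p$annual_harvest, 1)
  }
  years <- p$first_year + seq_len(p$T) - 1L
  obs_years <- setdiff(seq_len(p$T), p$missing_years)
  # composition split of the female/juvenile/subadult-male group is cosmetic;
  # only the group total enters the abundance index
  sv <- do.call(rbind, lapply(obs_years, function(t) {
    latent <- round(N[t])
    tot <- stats::rbinom(p$n_replicates, latent, p$detection_p)
    nf <- round(tot * 0.6); nj <- round(tot * 0.25)
    data.frame(herd = herd, year = years[t],
               replicate = seq_len(p$n_replicates),
               n_female = nf, n_juvenile = nj,
               n_subadult_male = tot - nf - nj,
               n_adult_male = stats::rbinom(p$n_replicates,
                                            max(1, round(latent * 0.2)),
                                            p$detection_p))
  }))
  hv <- if (p$annual_harvest > 0)
    data.frame(herd = herd, year = years[years %in% years[obs_years]],
               harvest = p$annual_harvest)
  else data.frame(herd = character(), year = integer(), harvest = numeric())
  list(latent = herd_series(herd, years, N), surveys = sv, harvests = hv,
       truth = c(p, list(gamma_t = gam, beta_t = bet)))
}

#' Meta-parameters for a multi-herd dataset
#'
#' Herd-level r_max values are drawn from a common normal distribution; the
#' defaults reproduce the fitted hyperparameters of the seven-herd elk
#' analysis this package emulates (mean 0.231, SD 0.045), with carrying
#' capacities spanning roughly 22 to 600 animals and 18-23 years per herd.
#'
#' @param n_herds number of herds.
#' @param mu_rmax mean of herd r_max values.
#' @param sigma_rmax SD of herd r_max values.
#' @param overrides named list (by herd) of argument lists passed on to
#'   [herd_sim_params] to override per-herd defaults.
#' @param seed master integer seed; per-herd streams derive from it.
#' @return A `meta_sim_params` object.
#' @export
meta_sim_params <- function(n_herds = 7, mu_rmax = 0.231, sigma_rmax = 0.045,
                            overrides = list(), seed = 1L) {
  stopifnot(n_herds >= 1, sigma_rmax >= 0)
  structure(list(n_herds = n_herds, mu_rmax = mu_rmax,
                 sigma_rmax = sigma_rmax, overrides = overrides,
                 seed = as.integer(seed)),
            class = "meta_sim_params")
}

# default per-herd scenario: K from ~22 to ~600, series lengths 18-23,
# one harvested herd, one herd with missing survey years
.default_herd_scenarios <- function(n_herds) {
  K <- round(exp(seq(log(22), log(600), length.out = n_herds)))
  lapply(seq_len(n_herds), function(i) {
    list(K = K[i], T = 18L + (i - 1L) %% 6L,
         annual_harvest = if (i == n_herds) 5 else 0,
         missing_years = if (i == 2 && n_herds >= 2) c(3L, 4L) else integer())
  })
}

#' Simulate a multi-herd dataset
#'
#' @param meta a [meta_sim_params].
#' @return List with `surveys`, `harvests` (stacked data.frames in the CSV
#'   dialect [read_surveys]/[read_harvests] use), `latent` (list of true
#'   [herd_series]) and `truth` (data.frame of true per-herd parameters).
#' @export
simulate_dataset <- function(meta = meta_sim_params()) {
  stopifnot(inherits(meta, "meta_sim_params"))
  set.seed(meta$seed)
  rmax_j <- stats::rnorm(meta$n_herds, meta$mu_rmax, meta$sigma_rmax)
  herd_seeds <- sample.int(.Machine$integer.max, meta$n_herds)
  scen <- .default_herd_scenarios(meta$n_herds)
  herds <- sprintf("herd%02d", seq_len(meta$n_herds))
  sims <- vector("list", meta$n_herds)
  for (i in seq_len(meta$n_herds)) {
    args <- list(r_max = rmax_j[i],
                 beta_mean = -rmax_j[i] / scen[[i]]$K,
                 T = scen[[i]]$T,
                 N0 = max(5, round(scen[[i]]$K / 3)),
                 annual_harvest = scen[[i]]$annual_harvest,
                 missing_years = scen[[i]]$missing_years)
    ov <- meta$overrides[[herds[i]]]
    if (!is.null(ov)) args[names(ov)] <- ov
    sims[[i]] <- simulate_herd(do.call(herd_sim_params, args),
                               seed = herd_seeds[i], herd = herds[i])
  }
  names(sims) <- herds
  truth <- do.call(rbind, lapply(herds, function(h) {
    tr <- sims[[h]]$truth
    data.frame(herd = h, r_max = tr$r_max, beta_mean = tr$beta_mean,
               K = carrying_capacity(tr$r_max, tr$beta_mean)[1],
               sigma_gamma = tr$sigma_gamma, sigma_beta = tr$sigma_beta,
               epsilon_sd = tr$epsilon_sd, T = tr$T)
  }))
  list(surveys = do.call(rbind, lapply(sims, `[[`, "surveys")),
       harvests = do.call(rbind, lapply(sims, `[[`, "harvests")),
       latent = lapply(sims, `[[`, "latent"),
       truth = truth)
}

#' Write a simulated dataset as the CSV files the reader consumes
#'
#' @param dataset output of [simulate_dataset].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (surveys, harvests, truth).
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("surveys.csv", "harvests.csv", "truth.csv"))
  utils::write.csv(dataset$surveys, paths[1], row.names = FALSE)
  utils::write.csv(dataset$harvests, paths[2], row.names = FALSE)
  utils::write.csv(dataset$truth, paths[3], row.names = FALSE)
  invisible(paths)
}
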