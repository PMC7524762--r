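# shared fixtures: all built in code at test time

# latent-series growth observations for J herds simulated from the
# no-temporal-variation truth (optionally sigma_gamma on selected herds)
sim_obs_list <- function(J, seed, sigma_gamma = rep(0, J),
                         r_max = 0.23, beta_mean = -0.005,
                         epsilon_sd = 0.1, T = 20, N0 = 20) {
  obs <- list()
  for (j in seq_len(J)) {
    p <- herd_sim_params(r_max = r_max, beta_mean = beta_mean,
                         sigma_gamma = sigma_gamma[j],
                         epsilon_sd = epsilon_sd, N0 = N0, T = T,
                         detection_p = 1)
    s <- simulate_herd(p, seed = seed * 100 + j, herd = sprintf("h%d", j))
    obs[[sprintf("h%d", j)]] <- growth_observations(s$latent)
  }
  obs
}

# tiny survey table used by the io tests
toy_surveys <- function() {
  data.frame(
    herd = "A", year = rep(c(2001L, 2002L), c(3L, 2L)),
    replicate = c(1L, 2L, 3L, 1L, 2L),
    n_female = c(25, 30, 27, 18, 18),
    n_juvenile = c(10, 11, 11, 7, 7),
    n_subadult_male = c(6, 6, 6, 5, 5),
    n_adult_male = c(4, 9, 2, 3, 8))
}
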