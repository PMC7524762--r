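test_that("closed-form collapses hold at N = K", {
  set.seed(31)
  for (i in 1:25) {
    r_max <- runif(1, 0.05, 0.6)
    K <- runif(1, 10, 600)
    p <- stoch_params(alpha = exp(r_max), beta_mag = r_max / K,
                      sigma_r_sq = runif(1, 0, 0.05),
                      sigma_beta_sq = runif(1, 0, 1e-4))
    expect_equal(var_dem(K, p), K, tolerance = 1e-10)
    expect_equal(var_r(K, p), p$sigma_r_sq * K^2, tolerance = 1e-10)
    expect_equal(var_beta(K, p), p$sigma_beta_sq * K^4, tolerance = 1e-10)
  }
})

test_that("component formulas match direct substitution", {
  # alpha = 1 (r_max = 0), sigma_dem^2 = 1, N = 10, beta_mag = 0.1
  p <- stoch_params(alpha = 1, beta_mag = 0.1)
  expect_equal(var_dem(10, p),
               10 * exp(-1) * (1 - exp(-1)) + 10 * exp(-2), tolerance = 1e-12)
  expect_equal(var_dem(0, p), 0)
  p2 <- stoch_params(alpha = 1.2, beta_mag = 0.01, sigma_r_sq = 0,
                     sigma_beta_sq = 0)
  expect_equal(var_r(50, p2), 0)
  expect_equal(var_beta(50, p2), 0)

  # quadratic scaling in sigma; fixed N^2 component ratio
  p3 <- stoch_params(alpha = 1.2, beta_mag = 0.01, sigma_r_sq = 0.02,
                     sigma_beta_sq = 3e-5)
  p4 <- stoch_params(alpha = 1.2, beta_mag = 0.01, sigma_r_sq = 4 * 0.02,
                     sigma_beta_sq = 3e-5)
  N <- c(5, 20, 80)
  expect_equal(var_r(N, p4), 4 * var_r(N, p3), tolerance = 1e-12)
  expect_equal(var_beta(N, p3) / var_r(N, p3),
               (3e-5 / 0.02) * N^2, tolerance = 1e-12)
})

test_that("decomposition profile spans 5 to 1.2K and sums exactly", {
  p <- stoch_params(alpha = exp(0.25), beta_mag = 0.25 / 60,
                    sigma_r_sq = 0.01, sigma_beta_sq = 1e-6)
  prof <- decomposition_profile(p, K = 60)
  expect_gte(nrow(prof), 50)
  expect_equal(range(prof$N), c(5, 72))
  expect_equal(prof$var_total, prof$var_dem + prof$var_r + prof$var_beta)
  expect_true(all(prof[-1] >= 0))
  expect_error(decomposition_profile(p, K = 4), "exceed 5")
})

test_that("relative total stochasticity collapses and grows as derived", {
  K <- 80; r_max <- 0.3
  p0 <- stoch_params(alpha = exp(r_max), beta_mag = r_max / K)
  expect_equal(relative_total_stochasticity(p0, K), 1, tolerance = 1e-12)
  s <- 2e-6
  p1 <- stoch_params(alpha = exp(r_max), beta_mag = r_max / K,
                     sigma_beta_sq = s)
  expect_equal(relative_total_stochasticity(p1, K), 1 + s * K^3,
               tolerance = 1e-10)
  # strictly increasing in each variance at fixed K
  p2 <- stoch_params(alpha = exp(r_max), beta_mag = r_max / K,
                     sigma_r_sq = 0.01, sigma_beta_sq = s)
  expect_gt(relative_total_stochasticity(p2, K),
            relative_total_stochasticity(p1, K))
})

test_that("fitted estimates map onto stochasticity parameters by mode", {
  est <- elk_growth_estimates()[3, ]  # an r-and-beta-varying herd
  pg <- stoch_params_from_estimates(est, "fitted_gamma")
  pp <- stoch_params_from_estimates(est, "as_printed")
  expect_equal(pg$alpha, exp(est$r_max))
  expect_equal(pg$beta_mag, -est$beta)
  expect_equal(pg$sigma_r_sq, est$sigma_gamma^2)
  expect_equal(pp$sigma_r_sq, est$sigma_betad^2)
  expect_equal(pg$sigma_beta_sq, est$sigma_betad^2)

  # a variant with no temporal-r term contributes zero sigma_r
  pr <- stoch_params_from_estimates(elk_growth_estimates()[6, ],
                                    "fitted_gamma")
  expect_equal(pr$sigma_r_sq, 0)

  und <- est; und$beta <- 0.001
  expect_error(stoch_params_from_estimates(und), "density dependence")
})
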