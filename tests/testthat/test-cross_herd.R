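test_that("inverse regression equals OLS on 1/x (normal-equations oracle)", {
  x <- c(20, 50, 120, 400)
  y <- c(0.005, 0.0021, 0.0009, 0.0002)
  u <- 1 / x
  # hand-solved 2x2 normal equations
  n <- 4
  Sxx <- sum(u^2) - sum(u)^2 / n
  Sxy <- sum(u * y) - sum(u) * sum(y) / n
  slope <- Sxy / Sxx
  intercept <- mean(y) - slope * mean(u)
  r <- inverse_regression(x, y)
  expect_equal(r$slope, slope, tolerance = 1e-12)
  expect_equal(r$intercept, intercept, tolerance = 1e-12)
  expect_equal(r$n, 4L)
  # R^2 against its definition
  yhat <- intercept + slope * u
  expect_equal(r$r_squared, 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  # p-value from the t distribution with n - 2 df
  se <- sqrt(sum((y - yhat)^2) / (n - 2) / Sxx)
  expect_equal(r$p_value, 2 * pt(abs(slope / se), n - 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("noiseless y = a/x + b is recovered exactly", {
  x <- c(10, 30, 90, 200, 500)
  y <- 0.099 / x - 0.00036
  r <- inverse_regression(x, y)
  expect_equal(r$slope, 0.099, tolerance = 1e-10)
  expect_equal(r$intercept, -0.00036, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)

  # R^2 invariant under affine rescaling of y
  r3 <- inverse_regression(x, 0.02 / x + 0.004 + rep(c(1e-4, -1e-4), c(3, 2)))
  r4 <- inverse_regression(x, 1000 * (0.02 / x + 0.004 +
                                        rep(c(1e-4, -1e-4), c(3, 2))) + 7)
  expect_equal(r4$r_squared, r3$r_squared, tolerance = 1e-10)

  expect_error(inverse_regression(c(0, 1, 2), 1:3), "positive")
  expect_error(inverse_regression(c(3, 3, 3), 1:3), "degenerate")
  expect_error(inverse_regression(1:2, 1:2), "3 points")
})

test_that("temporal-slope-variation vs K regression reproduces the published fit", {
  est <- elk_growth_estimates()
  r <- fig_k_analysis(est)
  expect_equal(r$n, 6L)  # the non-regulated herd is excluded
  expect_equal(r$slope, 0.099, tolerance = 0.05)
  expect_equal(r$intercept, -0.00036, tolerance = 0.05)
  expect_equal(r$r_squared, 0.87, tolerance = 0.03)
  expect_lt(r$p_value, 0.05)

  same_K <- est[est$density_dependence_detected, ]
  same_K$K <- 100
  expect_error(fig_k_analysis(same_K), "degenerate")
  expect_error(fig_k_analysis(est[1:2, ]), ">= 3 herds")
})

test_that("density dependence vs relative stochasticity slopes negative", {
  est <- elk_growth_estimates()
  for (mode in c("fitted_gamma", "as_printed")) {
    r <- fig_stoch_analysis(est, mode)
    expect_lt(r$slope, 0)
    expect_equal(nrow(r$inputs), 6L)
    expect_true(all(r$inputs$relative_total_stochasticity > 0))
  }
  # noiseless synthetic inputs on the printed line are recovered
  rts <- c(2, 5, 10, 30, 120)
  beta <- -0.0293 / rts + 0.0034
  fit <- inverse_regression(rts, beta)
  expect_equal(fit$slope, -0.0293, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.0034, tolerance = 1e-10)
})

test_that("estimates drawn from the fitted line are recovered (round trip)", {
  set.seed(44)
  K <- c(22, 40, 50, 53, 267, 380)
  sbd <- 0.099 / K - 0.00036 + rnorm(6, 0, 2e-5)
  est <- data.frame(herd = paste0("h", 1:6), K = K, sigma_betad = sbd,
                    density_dependence_detected = TRUE)
  r <- fig_k_analysis(est)
  expect_equal(r$slope, 0.099, tolerance = 0.05)
  expect_equal(r$intercept, -0.00036, tolerance = 0.25)
  expect_gt(r$r_squared, 0.95)
})
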