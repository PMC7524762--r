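test_that("variant selection applies the margin-of-2 rule", {
  # clear winner by more than 2
  expect_equal(select_variant(c(-131.83, -158.99, -150.08, -167.70)), "both")
  expect_equal(select_variant(c(-131.83, -131.83, -174.71, -169.92)),
               "beta_var")
  # no margin: simplest within 2 of the minimum
  expect_equal(select_variant(c(-100, -101.5, -100.2, -101.9)), "none")
  # tie at equal complexity: lower deviance among r_var/beta_var
  expect_equal(select_variant(c(-105, -106.5, -107.2, -106.9)), "beta_var")
  # named input in scrambled order is reordered
  expect_equal(select_variant(c(both = -167.70, none = -131.83,
                                beta_var = -150.08, r_var = -158.99)), "both")
  expect_error(select_variant(c(-1, -2, Inf, -3)))
})

test_that("recorded deviance matches a density-sum oracle", {
  obs <- sim_obs_list(1, seed = 4, T = 7)  # 6 observations
  f <- fit_joint(obs, "none", config = quick_config(seed = 2, iterations = 2000),
                 check = FALSE)
  m <- draws_matrix(f)
  d <- obs$h1
  for (i in c(1, 57, 500)) {
    mu <- m[i, "rmax[h1]"] + m[i, "beta[h1]"] * d$N_t
    oracle <- -2 * sum(dnorm(d$r_t, mu, m[i, "sigma_eps"], log = TRUE))
    expect_equal(m[i, "deviance"], oracle, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_equal(mean_deviance(f), mean(m[, "deviance"]))
})

test_that("joint deviance is additive over independent herds", {
  obs2 <- sim_obs_list(2, seed = 6, T = 8)
  f <- fit_joint(obs2, "none", config = quick_config(seed = 3, iterations = 2000),
                 check = FALSE)
  m <- draws_matrix(f)
  i <- 25
  dev_by_herd <- vapply(names(obs2), function(h) {
    d <- obs2[[h]]
    mu <- m[i, sprintf("rmax[%s]", h)] + m[i, sprintf("beta[%s]", h)] * d$N_t
    -2 * sum(dnorm(d$r_t, mu, m[i, "sigma_eps"], log = TRUE))
  }, 0)
  expect_equal(unname(m[i, "deviance"]), sum(dev_by_herd), tolerance = 1e-10)
})

test_that("split-Rhat matches a hand computation and flags disjoint chains", {
  # arithmetic oracle on a 2-chain, 10-draw array
  set.seed(8)
  a <- matrix(rnorm(20), 10, 2)
  s <- cbind(a[1:5, 1], a[6:10, 1], a[1:5, 2], a[6:10, 2])
  n <- 5; mcol <- 4
  W <- mean(apply(s, 2, var))
  B <- n * var(colMeans(s))
  by_hand <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(split_rhat(s), by_hand, tolerance = 1e-12)
  chains <- list(a[, 1, drop = FALSE], a[, 2, drop = FALSE])
  for (ch in chains) colnames(ch) <- "x"
  chains <- lapply(chains, function(m) { colnames(m) <- "x"; m })
  rep <- check_convergence(chains)
  expect_equal(rep$rhat, by_hand, tolerance = 1e-12)

  # well-mixed null case
  set.seed(9)
  iid <- lapply(1:3, function(i) {
    m <- matrix(rnorm(4000), ncol = 2)
    colnames(m) <- c("a", "b"); m
  })
  expect_true(all(check_convergence(iid)$rhat < 1.01))

  # offset chains blow up
  off <- iid
  off[[2]][, 1] <- off[[2]][, 1] + 50
  r <- check_convergence(off)
  expect_gt(r$rhat[r$parameter == "a"], 1.5)
  expect_true(!attr(r, "pass"))
  expect_error(check_convergence(iid[[1]]), "chains")
})

test_that("flat growth response concentrates beta near zero", {
  d <- data.frame(herd = "h1", year_t = 2000:2014, N_t = seq(40, 180, 10),
                  r_t = 0.2, span = 1L)
  f <- fit_joint(list(h1 = d), "none",
                 config = quick_config(seed = 4, iterations = 4000),
                 check = FALSE)
  s <- summarize_herd(f, "h1")
  expect_lt(abs(s$beta), 5e-4)
  expect_equal(s$r_max, 0.2, tolerance = 0.15)
  expect_false(s$density_dependence_detected)
})

test_that("single-herd recovery: truth inside the 95% CrI", {
  obs <- sim_obs_list(1, seed = 12)
  f <- fit_joint(obs, "none", config = quick_config(seed = 5), check = FALSE)
  s <- summarize_herd(f, "h1")
  expect_true(s$r_max_lo < 0.23 && 0.23 < s$r_max_hi)
  expect_true(s$beta_lo < -0.005 && -0.005 < s$beta_hi)
  expect_true(s$r_max_lo <= s$r_max & s$r_max <= s$r_max_hi)
})

test_that("fits are reproducible given the seed", {
  obs <- sim_obs_list(1, seed = 3, T = 10)
  cfg <- quick_config(seed = 7, iterations = 1500)
  f1 <- fit_joint(obs, "r_var", config = cfg, check = FALSE)
  f2 <- fit_joint(obs, "r_var", config = cfg, check = FALSE)
  expect_identical(f1$chains, f2$chains)
})

test_that("rescaling abundance rescales beta and K accordingly", {
  obs <- sim_obs_list(1, seed = 15)
  scaled <- obs
  scaled$h1$N_t <- 10 * scaled$h1$N_t
  f1 <- fit_joint(obs, "none", config = quick_config(seed = 6), check = FALSE)
  f2 <- fit_joint(scaled, "none", config = quick_config(seed = 6),
                  check = FALSE)
  s1 <- summarize_herd(f1, "h1"); s2 <- summarize_herd(f2, "h1")
  expect_equal(s2$beta, s1$beta / 10, tolerance = 0.05)
  expect_equal(s2$K, 10 * s1$K, tolerance = 0.05)
})

test_that("posterior summaries match brute-force quantiles of the draws", {
  obs <- sim_obs_list(1, seed = 18, T = 12)
  f <- fit_joint(obs, "both", config = quick_config(seed = 8, iterations = 4000),
                 check = FALSE)
  s <- summarize_herd(f, "h1")
  m <- draws_matrix(f)
  K <- -m[, "rmax[h1]"] / m[, "mu_betad[h1]"]
  expect_equal(s$K, unname(quantile(K, 0.5)))
  expect_equal(c(s$K_lo, s$K_hi),
               unname(quantile(K, c(0.025, 0.975))))
  expect_equal(s$beta, unname(median(m[, "mu_betad[h1]"])))
  # detection flag consistent with the interval itself
  expect_identical(s$density_dependence_detected, unname(s$beta_hi < 0))
  # per-year K option pools the per-year slopes
  s2 <- summarize_herd(f, "h1", K_beta = "per_year")
  bd <- m[, grep("^betad\\[h1,", colnames(m)), drop = FALSE]
  expect_equal(s2$K, unname(median(as.vector(-m[, "rmax[h1]"] / bd))))
})

test_that("selection procedure emits the Table-1 shape with a constant baseline", {
  obs <- sim_obs_list(3, seed = 22, T = 12)
  sel <- selection_procedure(obs, config = quick_config(seed = 9,
                                                        iterations = 2000))
  expect_equal(dim(sel$deviance), c(3L, 4L))
  expect_equal(length(unique(sel$deviance[, "none"])), 1L)
  expect_true(all(sel$selection %in% model_variants()))
  expect_named(sel$fits, names(obs))
  # estimates table carries one row per herd
  est <- summarize_herds(sel)
  expect_equal(est$herd, names(obs))
  expect_true(all(est$K_lo <= est$K & est$K <= est$K_hi))
})

test_that("mismatched assignments and short herds are rejected", {
  obs <- sim_obs_list(2, seed = 30, T = 8)
  expect_error(fit_joint(obs, c(h1 = "none"), check = FALSE), "h2")
  short <- obs
  short$h2 <- short$h2[1, ]
  expect_error(fit_joint(short, "none", check = FALSE), ">= 2")
})
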