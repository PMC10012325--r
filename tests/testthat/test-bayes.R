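test_that("HDI is the narrowest interval holding the stated mass", {
  set.seed(1)
  h <- hdi(rnorm(1e6))
  expect_lt(abs(h[1] + 1.959964), 0.02)
  expect_lt(abs(h[2] - 1.959964), 0.02)
  expect_equal(hdi(rep(2.5, 500)), c(2.5, 2.5))
  # skewed sample: HDI hugs the mode, unlike the equal-tailed interval
  e <- stats::rexp(1e5)
  he <- hdi(e)
  expect_lt(he[1], 0.01)
  expect_lt(abs(he[2] - stats::qexp(0.95)), 0.1)
  eq_tail <- unname(quantile(e, c(0.025, 0.975)))
  expect_lt(diff(he), eq_tail[2] - eq_tail[1])
})

test_that("ROPE decisions partition into the three canonical outcomes", {
  expect_equal(rope_decision(c(0.508, 0.586), rope_interval(0.95, 1.05)),
               "different")
  expect_equal(rope_decision(c(-0.1, 0.1), rope_interval(-0.3, 0.3)),
               "equivalent")
  expect_equal(rope_decision(c(0.075, 0.230), rope_interval(-0.12, 0.12)),
               "undecided")
  # deterministic given samples, invariant to sample order
  set.seed(2)
  s <- rnorm(5000, 0.2, 0.1)
  r <- rope_interval(-0.15, 0.15)
  expect_identical(rope_decision(hdi(s), r), rope_decision(hdi(rev(s)), r))
  expect_error(rope_interval(1, 1))
})

test_that("difference posterior matches the conjugate normal oracle", {
  set.seed(3)
  d <- rnorm(500, 0.7, 0.5)
  post <- estimate_mean_difference(d, config = mcmc_config(seed = 4))
  # analytic posterior for mu with sigma fixed at sd(d) and the same
  # normal prior (prior is vague, so this is accurate to well within MCSE)
  prior_sd <- 10 * sd(d)
  prior_mean <- mean(d)
  lik_prec <- length(d) / sd(d)^2
  post_prec <- 1 / prior_sd^2 + lik_prec
  oracle_mean <- (prior_mean / prior_sd^2 + sum(d) / sd(d)^2) / post_prec
  oracle_sd <- sqrt(1 / post_prec)
  mu <- as.matrix(post$samples)[, "mu"]
  mcse <- post$diagnostics$mcse["mu"]
  expect_lt(abs(mean(mu) - oracle_mean), 4 * mcse + 1e-4)
  expect_lt(abs(sd(mu) - oracle_sd), 0.15 * oracle_sd)
  expect_equal(post$mu$decision, "different")  # HDI far above (-0.3, 0.3)
  expect_equal(post$mu$mass_above_rope, 1)
  expect_true(post$diagnostics$pass)

  # tight null data -> practically equivalent
  set.seed(5)
  null_post <- estimate_mean_difference(rnorm(300, 0, 0.05),
                                        config = mcmc_config(seed = 6))
  expect_equal(null_post$mu$decision, "equivalent")

  # diffuse data with mean near the ROPE edge -> undecided
  set.seed(7)
  amb <- estimate_mean_difference(rnorm(500, 0.2, 1.5),
                                  config = mcmc_config(seed = 8))
  expect_equal(amb$mu$decision, "undecided")

  expect_error(estimate_mean_difference(c(1, NA, 2)), "non-finite")
  expect_error(estimate_mean_difference(numeric(0)), "at least 2")
})

test_that("robust regression recovers generator truth and resists gross outliers", {
  co <- generate_cohort(500, slope = 0.55, intercept = 0.16, seed = 11)
  reg <- robust_linear_regression(co$ssr_task1, co$ssr_task2,
                                  config = mcmc_config(seed = 12))
  expect_true(reg$beta1$hdi_low <= 0.55 && 0.55 <= reg$beta1$hdi_high)
  expect_true(reg$beta0$hdi_low <= 0.16 && 0.16 <= reg$beta0$hdi_high)
  expect_equal(reg$beta1$decision, "different")  # far below (0.95, 1.05)
  expect_true(reg$diagnostics$pass)

  # identity map with tiny jitter
  set.seed(13)
  x <- runif(200, 1, 3)
  y <- x + rnorm(200, 0, 0.01)
  reg_id <- robust_linear_regression(x, y, config = mcmc_config(seed = 14))
  expect_true(reg_id$beta1$hdi_low <= 1 && 1 <= reg_id$beta1$hdi_high)
  expect_true(reg_id$beta0$hdi_low <= 0 && 0 <= reg_id$beta0$hdi_high)

  # 10% gross outliers: the t likelihood shrugs them off, OLS does not
  set.seed(15)
  x <- runif(400, 1, 3)
  y <- 0.2 + 0.6 * x + rnorm(400, 0, 0.1)
  clean_slope <- unname(coef(lm(y ~ x))[2])
  idx <- which(x > 2.5)[1:40]
  y_out <- y
  y_out[idx] <- y_out[idx] + 5
  ols_slope <- unname(coef(lm(y_out ~ x))[2])
  expect_gt(abs(ols_slope - clean_slope), 0.2)
  reg_rob <- robust_linear_regression(x, y_out, config = mcmc_config(seed = 16))
  expect_lt(abs(reg_rob$beta1$mode - clean_slope), 0.05)

  expect_error(robust_linear_regression(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(robust_linear_regression(1:2, 1:2), "at least 3")
})

test_that("sampler posterior agrees with an independent JAGS fit", {
  library(rjags)
  co <- generate_cohort(150, seed = 21)
  own <- robust_linear_regression(co$ssr_task1, co$ssr_task2,
                                  config = mcmc_config(chains = 4,
                                                       warmup = 1000,
                                                       draws = 5000,
                                                       seed = 22))
  p_own <- as.matrix(own$samples)
  model_str <- "model {
    for (i in 1:N) { y[i] ~ dt(b0 + b1 * x[i], pow(sigma, -2), nu) }
    b0 ~ dnorm(0, 0.01)
    b1 ~ dnorm(1, 0.01)
    sigma ~ dunif(0.001, 1000)
    nu ~ dexp(0.0333333)
  }"
  set.seed(23)
  jm <- jags.model(textConnection(model_str),
                   data = list(x = co$ssr_task1, y = co$ssr_task2, N = 150),
                   n.chains = 3, n.adapt = 1000, quiet = TRUE)
  update(jm, 1000)
  p_j <- as.matrix(coda.samples(jm, c("b0", "b1", "sigma", "nu"), 4000))
  map <- c(beta0 = "b0", beta1 = "b1", sigma = "sigma", nu = "nu")
  for (p in names(map)) {
    ref_sd <- sd(p_j[, map[p]])
    expect_lt(abs(mean(p_own[, p]) - mean(p_j[, map[p]])), 0.2 * ref_sd)
    expect_lt(abs(sd(p_own[, p]) - ref_sd), 0.2 * ref_sd)
  }
})

test_that("convergence diagnostics separate healthy and broken chain sets", {
  set.seed(31)
  good <- lapply(1:4, function(i) cbind(theta = rnorm(4000)))
  dg <- diagnostics(good)
  expect_lt(abs(dg$shrink["theta"] - 1), 0.01)
  expect_true(dg$pass)

  apart <- lapply(1:4, function(i) cbind(theta = rnorm(2000, mean = 4 * i, sd = 0.1)))
  da <- diagnostics(apart)
  expect_gt(da$shrink["theta"], 5)
  expect_false(da$pass)

  # AR(1) chains: ESS should approach n * (1 - rho) / (1 + rho)
  rho <- 0.8
  n <- 20000
  ar_chains <- lapply(1:4, function(i) {
    cbind(theta = as.numeric(stats::arima.sim(list(ar = rho), n)))
  })
  dar <- diagnostics(ar_chains)
  expected_ess <- 4 * n * (1 - rho) / (1 + rho)
  expect_lt(abs(dar$ess["theta"] - expected_ess) / expected_ess, 0.2)

  uneven <- list(cbind(theta = rnorm(100)), cbind(theta = rnorm(50)))
  expect_error(diagnostics(uneven), "unequal")
  expect_error(diagnostics(list(cbind(a = rnorm(10)))), ">= 2 chains")
})

test_that("posterior HDI width shrinks as evidence accumulates", {
  widths <- sapply(c(20, 100, 500), function(n) {
    set.seed(41)
    d <- rnorm(n, 0.4, 0.6)
    p <- estimate_mean_difference(d, config = mcmc_config(chains = 4,
                                                          warmup = 500,
                                                          draws = 3000,
                                                          seed = 42))
    p$mu$hdi_high - p$mu$hdi_low
  })
  expect_true(all(diff(widths) < 0))
})
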