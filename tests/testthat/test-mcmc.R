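test_that("posterior_summary follows the type-7 quantile rule", {
  s <- posterior_summary(rep(3.2, 50))
  expect_equal(unlist(s[c("mean", "median", "lower", "upper")]),
               c(mean = 3.2, median = 3.2, lower = 3.2, upper = 3.2))
  s <- posterior_summary(1:100, level = 0.95)
  expect_equal(s$lower, 3.475)
  expect_equal(s$upper, 97.525)
  set.seed(1)
  x <- rnorm(20000)
  s <- posterior_summary(x)
  expect_lt(abs(s$mean - s$median), 0.02)
  expect_error(posterior_summary(numeric(0)), "no draws")
})

test_that("gelman_rubin matches the direct variance-decomposition oracle", {
  chains <- cbind(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                  c(2, 4, 6, 8, 10, 1, 3, 5, 7, 9))
  n <- nrow(chains)
  W <- mean(c(var(chains[, 1]), var(chains[, 2])))
  B_over_n <- var(colMeans(chains))
  oracle <- sqrt(((n - 1) / n * W + B_over_n) / W)
  expect_equal(gelman_rubin(chains)$r_hat, oracle)
  expect_gte(oracle, sqrt((n - 1) / n))
})

test_that("gelman_rubin separates mixed from unmixed chains", {
  set.seed(21)
  same <- cbind(rnorm(10000), rnorm(10000), rnorm(10000))
  expect_gt(gelman_rubin(same)$r_hat, 0.99)
  expect_lt(gelman_rubin(same)$r_hat, 1.01)
  apart <- cbind(rnorm(5000), rnorm(5000) + 5)
  expect_gt(gelman_rubin(apart)$r_hat, 1.5)
  expect_error(gelman_rubin(matrix(1:10, ncol = 1)), "2 chains")
  expect_error(gelman_rubin(matrix(1:8, ncol = 2)), "at least 10")
})

test_that("fixed-model runs are bit-reproducible and validate inputs", {
  s <- toy_summaries(O = c(10, 25, 4), E = c(12, 20, 6))
  cfg <- small_mcmc(iters = 600, burn = 200)
  a <- fit_fixed_model(s, mcmc = cfg)
  b <- fit_fixed_model(s, mcmc = cfg)
  expect_identical(a$theta, b$theta)
  expect_equal(nrow(a$theta), 3 * 400)
  expect_equal(a$chain, rep(1:3, each = 400))
  expect_error(fit_fixed_model(toy_summaries(1, 0)), "positive")
  expect_error(mcmc_config(n_iterations = 100, burn_in = 100))
})

test_that("fixed-model posterior matches the conjugate Gamma oracle", {
  # flat-prior limit: SMR = exp(theta) | O, E ~ Gamma(shape O, rate E)
  s <- toy_summaries(O = 19, E = 9.97)
  draws <- fit_fixed_model(s, mcmc = small_mcmc(seed = 31, iters = 4000,
                                                burn = 500))
  smr <- exp(draws$theta[, 1])
  ks <- suppressWarnings(
    ks.test(smr, pgamma, shape = 19, rate = 9.97)$statistic)
  expect_lt(ks, 0.05)  # reduced scale; the 0.02 bound is tested at 1e5 draws
  # quantile-by-quantile agreement, 5% to 95%
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_lt(max(abs(quantile(smr, qs) - qgamma(qs, 19, rate = 9.97))), 0.12)
  # posterior mean RAMR near the plug-in value 19.44
  expect_lt(abs(mean(10.2 * smr) - 19.44), 0.6)
})

test_that("O = E with large counts concentrates the SMR at 1", {
  s <- toy_summaries(O = 400, E = 400)
  draws <- fit_fixed_model(s, mcmc = small_mcmc(seed = 5))
  expect_lt(abs(mean(exp(draws$theta)) - 1), 0.02)
})

test_that("doubling O and E tightens every credible interval", {
  sim <- simulate_summaries(n_hosp = 15, seed = 3, median_size = 300)
  cfg <- small_mcmc(seed = 13, iters = 2500, burn = 500)
  d1 <- fit_fixed_model(sim$summaries, mcmc = cfg)
  s2 <- sim$summaries
  s2$observed <- 2 * s2$observed
  s2$expected <- 2 * s2$expected
  d2 <- fit_fixed_model(s2, mcmc = cfg)
  w1 <- {x <- posterior_summary(d1$theta); x$upper - x$lower}
  w2 <- {x <- posterior_summary(d2$theta); x$upper - x$lower}
  expect_true(all(w2 < w1))
})

test_that("hierarchical posterior of mu0 concentrates at 0 when O = E", {
  s <- toy_summaries(O = rep(300, 12), E = rep(300, 12))
  draws <- fit_hierarchical_model(s, mcmc = small_mcmc(seed = 17))
  expect_lt(abs(mean(draws$mu0)), 0.06)
  expect_lt(sd(draws$mu0), 0.1)
  expect_false(is.null(draws$sigma0_sq))
  rep <- gelman_rubin(draws)
  expect_true(all(c("mu0", "sigma0_sq") %in% rep$parameter))
})

test_that("hierarchical medians are shrunk relative to fixed medians", {
  sim <- simulate_summaries(n_hosp = 128, seed = 4)
  cfg <- small_mcmc(seed = 19, iters = 2500, burn = 500)
  df <- fit_fixed_model(sim$summaries, mcmc = cfg)
  dh <- fit_hierarchical_model(sim$summaries, mcmc = cfg)
  mf <- apply(df$theta, 2, median)
  mh <- apply(dh$theta, 2, median)
  expect_lt(sd(mh), sd(mf))
  pooled <- median(mf)
  viol <- mean(abs(mh - pooled) > abs(mf - pooled))
  expect_lte(viol, 0.05)
})

test_that("uniform-SD prior gives results comparable to the gamma prior", {
  sim <- simulate_summaries(n_hosp = 60, seed = 6)
  cfg <- small_mcmc(seed = 23, iters = 2500, burn = 500)
  dg <- fit_hierarchical_model(sim$summaries,
                               model_spec("hierarchical",
                                          sigma_prior = "gamma"), cfg)
  du <- fit_hierarchical_model(sim$summaries,
                               model_spec("hierarchical",
                                          sigma_prior = "uniform"), cfg)
  sg <- median(sqrt(dg$sigma0_sq))
  su <- median(sqrt(du$sigma0_sq))
  expect_lt(abs(sg - su) / sg, 0.5)
  expect_lt(abs(sg - 0.2) / 0.2, 0.6)
})

test_that("draws round-trip through the columnar text format", {
  s <- toy_summaries(O = c(8, 15), E = c(10, 12))
  draws <- fit_hierarchical_model(rbind(s, toy_summaries(9, 11, ids = 3)),
                                  mcmc = small_mcmc(iters = 300, burn = 100))
  path <- file.path(withr::local_tempdir(), "draws.tsv")
  write_draws(draws, path)
  back <- read_draws(path)
  expect_equal(back$theta, unname(draws$theta), tolerance = 1e-6)
  expect_equal(back$mu0, draws$mu0, tolerance = 1e-6)
  expect_equal(back$model, "hierarchical")
})
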