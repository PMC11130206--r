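test_that("hdi recovers analytic intervals", {
  set.seed(1)
  u <- runif(1e5)
  h <- hdi(u, 0.89)
  expect_lt(abs((h["high"] - h["low"]) - 0.89), 0.01)

  z <- rnorm(1e5)
  hz <- hdi(z, 0.89)
  expect_lt(abs(hz["low"] - (-1.60)), 0.05)
  expect_lt(abs(hz["high"] - 1.60), 0.05)

  expect_equal(unname(hdi(rep(3.5, 100), 0.89)), c(3.5, 3.5))
  expect_error(hdi(u, 1.2), "mass")
})

test_that("hdi inside-mass is exact up to discreteness", {
  set.seed(2)
  cases <- list(rnorm(501), rexp(730), rt(997, df = 3), rbeta(1203, 2, 5))
  for (x in cases) {
    for (mass in c(0.5, 0.89, 0.95)) {
      h <- hdi(x, mass)
      inside <- mean(x >= h["low"] & x <= h["high"])
      expect_gte(inside, mass)
      expect_lte(inside, mass + 2 / length(x))
    }
  }
})

test_that("probability of direction counts signs and ignores zeros", {
  expect_equal(prob_direction(c(2, 1, 5)), 1)
  expect_equal(prob_direction(c(-1, 1, -2, 2)), 0.5)
  expect_equal(prob_direction(c(-1, 2, 3, 4)), 0.75)
  expect_equal(prob_direction(c(0, 0, -1, 2, 3, 4)), 0.75)  # zeros excluded
  # invariant to sign-preserving monotone transforms
  set.seed(3)
  x <- rnorm(500, 0.3)
  expect_equal(prob_direction(x), prob_direction(100 * x))
  expect_equal(prob_direction(x), prob_direction(sign(x) * abs(x)^3))
})

test_that("effect summaries are equivariant and transform correctly", {
  set.seed(4)
  x <- rnorm(2001, 1, 2)  # odd length: the median is an order statistic
  s <- summarize_effect(x)
  s_shift <- summarize_effect(x + 10)
  expect_equal(s_shift$median, s$median + 10)
  expect_equal(s_shift$mad, s$mad)
  expect_equal(s_shift$hdi_low, s$hdi_low + 10, tolerance = 1e-8)
  # OR-scale reporting: median commutes with the monotone exp transform
  expect_equal(summarize_effect(exp(x))$median, exp(s$median))
  # symmetric draws: pd near 0.5, median near 0
  y <- c(x - 1, -(x - 1))
  expect_equal(summarize_effect(y)$pd, 0.5)
  expect_equal(summarize_effect(y)$median, 0)
})

test_that("contrasts are per-draw weighted sums", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(0, 1, 0, 1))
  d <- posterior_draws(m, chain = c(1, 1, 2, 2))
  expect_equal(contrast_draws(d, c(a = 1)), m[, "a"])
  # condition difference under sum coding = twice the coefficient
  expect_equal(contrast_draws(d, c(a = 2)), 2 * m[, "a"])
  expect_equal(contrast_draws(d, c(a = 0, b = 0)), rep(0, 4))
  expect_error(contrast_draws(d, c(zz = 1)), "unknown parameter")
})

test_that("posterior sampling solves conjugate toys", {
  # Bernoulli with a flat prior on p, 10 of 20 successes -> mean ~ 0.5
  code <- "model { for (i in 1:N) { y[i] ~ dbern(p) } p ~ dbeta(1, 1) }"
  d <- sample_posterior(code, list(y = rep(0:1, 10), N = 20), "p",
                        quick_settings(11))
  expect_lt(abs(mean(as.matrix(d)) - 0.5), 0.05)

  # Normal location, prior N(0, 5), strong data at 3 -> posterior near 3
  code2 <- paste("model { for (i in 1:N) { y[i] ~ dnorm(mu, 100) }",
                 "mu ~ dnorm(0, 0.04) }")
  d2 <- sample_posterior(code2, list(y = rep(3, 20), N = 20), "mu",
                         quick_settings(12))
  post_mean <- 3 * (20 * 100) / (20 * 100 + 0.04)  # conjugate closed form
  expect_lt(abs(mean(as.matrix(d2)) - post_mean), 0.01)
})

test_that("sampling is deterministic given the seed", {
  code <- "model { for (i in 1:N) { y[i] ~ dbern(p) } p ~ dbeta(1, 1) }"
  data <- list(y = rep(0:1, 10), N = 20)
  d1 <- sample_posterior(code, data, "p", quick_settings(13))
  d2 <- sample_posterior(code, data, "p", quick_settings(13))
  expect_identical(d1$draws, d2$draws)
  # different seeds agree within Monte-Carlo error on the conjugate toy
  d3 <- sample_posterior(code, data, "p", quick_settings(14))
  mcse <- sd(as.matrix(d1)) / sqrt(200)  # generous ESS lower bound
  expect_lt(abs(mean(as.matrix(d1)) - mean(as.matrix(d3))), 3 * mcse * 5)
})

test_that("split-R-hat separates mixed from unmixed chains", {
  set.seed(5)
  iid <- posterior_draws(cbind(theta = rnorm(4000)),
                         chain = rep(1:4, each = 1000))
  diag_iid <- mcmc_diagnostics(iid)
  expect_lt(abs(diag_iid$parameters$rhat - 1), 0.02)
  expect_equal(diag_iid$n_divergences, 0L)

  shifted <- posterior_draws(
    cbind(theta = c(rnorm(1000), rnorm(1000) + 10)),
    chain = rep(1:2, each = 1000))
  expect_gt(mcmc_diagnostics(shifted)$parameters$rhat, 1.1)

  const <- posterior_draws(cbind(theta = rep(1, 2000)),
                           chain = rep(1:2, each = 1000))
  dc <- mcmc_diagnostics(const)
  expect_equal(dc$parameters$lag1_autocorr, 1)  # flagged as fully stuck

  single <- posterior_draws(cbind(theta = rnorm(1000)),
                            chain = rep(1L, 1000))
  ds <- mcmc_diagnostics(single)
  expect_false(ds$rhat_available)
  expect_true(is.na(ds$parameters$rhat))
})

test_that("posterior_draws validates its structure", {
  expect_error(posterior_draws(cbind(a = 1:4), chain = c(1, 1, 1, 2)),
               "same number of draws")
  expect_error(posterior_draws(cbind(a = c(1, NA)), chain = c(1, 2)),
               "missing values")
  expect_error(posterior_draws(matrix(1:4, 2), chain = c(1, 2)),
               "named columns")
})

test_that("sampler settings enforce the warmup contract", {
  s <- sampler_settings(seed = 1)
  expect_equal(s$n_chains * (s$n_iterations - s$n_warmup), 20000)
  expect_error(sampler_settings(n_iterations = 500, n_warmup = 500, seed = 1),
               "n_warmup")
})
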