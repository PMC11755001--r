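# Hierarchical growth and survival model fits: oracle checks against
# conjugate closed forms, exchangeability, pooling direction, and an
# independent MCMC engine on a tiny instance.

test_that("single-species growth posterior matches the conjugate limit", {
  obs <- make_growth_obs(2, 0.5, 1000, seed = 21)
  obs2 <- obs; obs2$species <- "sp002"
  fit <- fit_growth_model(rbind(obs, obs2), fast_config(), seed = 1)
  est <- fit$species_estimates
  # with 1000 observations the posterior mean sits on the data
  expect_lt(max(abs(est$g_mean - 2)), 0.05)
  # exchangeability: identical data gives estimates within MC error
  expect_lt(abs(est$g_mean[1] - est$g_mean[2]), 0.02)
  expect_lt(abs(est$sigma_mean[1] - 0.5), 0.05)
})

test_that("species below the observation floor are excluded from the fit", {
  obs <- rbind(make_growth_obs(c(1, 2), c(0.3, 0.3), c(50, 9), seed = 3))
  fit <- fit_growth_model(obs, fast_config(), seed = 2)
  expect_equal(fit$species_estimates$species, "sp001")
  expect_equal(fit$excluded, "sp002")
  sobs <- make_survival_obs(c(0.9, 0.8), c(60, 9), seed = 4)
  sfit <- fit_survival_model(sobs, fast_config(), seed = 2)
  expect_equal(sfit$excluded, "sp002")
})

test_that("survival posterior matches the Beta-Binomial oracle", {
  # 1000 one-year observations, 900 alive: posterior of s is approximately
  # Beta(900 + a, 100 + b) with a weak class prior -> mean near 0.9
  obs <- data.frame(species = rep(c("sp001", "sp002"), each = 1000),
                    alive = rep(rep(c(1L, 0L), 2), c(900, 100, 900, 100)),
                    t = 1)
  fit <- fit_survival_model(obs, fast_config(), seed = 5)
  expect_lt(max(abs(fit$species_estimates$s_mean - 0.9)), 0.03)
  expect_true(all(fit$species_estimates$s_mean > 0 &
                    fit$species_estimates$s_mean < 1))
})

test_that("all-alive data still shrinks the posterior away from 1", {
  obs <- data.frame(species = rep(sprintf("sp%03d", 1:3), each = 40),
                    alive = 1L, t = 1)
  fit <- fit_survival_model(obs, fast_config(), seed = 6)
  expect_true(all(fit$species_estimates$s_mean < 1))
  expect_true(all(is.finite(fit$species_estimates$lifespan)))
})

test_that("interval censoring is honoured: five-year survivors imply higher s", {
  set.seed(31)
  # identical per-interval survival fractions, different interval lengths
  obs1 <- data.frame(species = "sp001",
                     alive = rep(c(1L, 0L), c(810, 190)), t = 1)
  obs5 <- data.frame(species = "sp002",
                     alive = rep(c(1L, 0L), c(810, 190)), t = 5)
  fit <- fit_survival_model(rbind(obs1, obs5), fast_config(), seed = 7)
  est <- fit$species_estimates
  s1 <- est$s_mean[est$species == "sp001"]
  s5 <- est$s_mean[est$species == "sp002"]
  expect_gt(s5, s1)                      # 0.81^(1/5) > 0.81
  expect_lt(abs(s1 - 0.81), 0.03)
  expect_lt(abs(s5 - 0.81^0.2), 0.03)
})

test_that("estimates pool towards the class mean for every species", {
  set.seed(41)
  g_true <- rnorm(30, 1, 0.8)
  obs <- make_growth_obs(g_true, rep(0.6, 30), sample(20:60, 30, TRUE), seed = 42)
  fit <- fit_growth_model(obs, fast_config(), seed = 8)
  est <- fit$species_estimates
  class_mean <- fit$hyper$mean[fit$hyper$parameter == "g_class"]
  towards <- (est$g_mean - est$raw_mean) * (class_mean - est$raw_mean) >= 0
  within <- abs(est$g_mean - class_mean) <= abs(est$raw_mean - class_mean) + 1e-12
  expect_true(all(towards & within))
})

test_that("the sampler agrees with an independent MCMC engine (rjags) on a tiny fit", {
  skip_if_not_installed("rjags")
  set.seed(51)
  g_true <- c(0.5, 1.5, 2.5)
  obs <- make_growth_obs(g_true, rep(0.4, 3), rep(120, 3), seed = 52)
  fit <- fit_growth_model(obs, pipeline_config(n_chains = 3L, n_iter = 2000L,
                                               n_burnin = 1000L), seed = 9)
  model_string <- "model {
    for (i in 1:N) { y[i] ~ dnorm(g[sp[i]], pow(sigma[sp[i]], -2)) }
    for (j in 1:J) {
      g[j] ~ dnorm(g_class, 1)
      sigma[j] ~ dlnorm(sigma_class, 1)
    }
    g_class ~ dunif(-100, 100)
    sigma_class ~ dunif(-20, 20)
  }"
  jm <- rjags::jags.model(textConnection(model_string),
                          data = list(y = obs$y,
                                      sp = as.integer(factor(obs$species)),
                                      N = nrow(obs), J = 3L),
                          n.chains = 2, quiet = TRUE)
  stats::update(jm, 1000, progress.bar = "none")
  draws <- rjags::coda.samples(jm, c("g"), 3000, progress.bar = "none")
  ref <- colMeans(as.matrix(draws))
  expect_lt(max(abs(fit$species_estimates$g_mean - ref)), 0.03)
})

test_that("split-Rhat distinguishes mixed from unmixed chains", {
  set.seed(61)
  mixed <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(mixed), 1.01)
  apart <- mixed + rep(c(0, 0, 3, 3), each = 1000)
  expect_gt(split_rhat(apart), 1.5)
})
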