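# Oracle checks for the MCMC engine.  The strategy throughout: freeze all
# parameters except one block via `fixed =`, so the sampled conditional can
# be compared against direct arithmetic (exact Bernoulli conditionals,
# conjugate normal posteriors, 1-D quadrature).

test_that("same master seed reproduces the draws exactly", {
  sim <- simulate_melsm(n = 6, J = 12, seed = 21)
  ctl <- sampler_spec(n_iter = 400, burn_in = 100, n_chains = 2, seed = 5)
  f1 <- fit_melsm(sim$data, control = ctl)
  f2 <- fit_melsm(sim$data, control = ctl)
  expect_identical(f1$draws, f2$draws)
})

test_that("initialization is deterministic, data-anchored, and guards degeneracy", {
  sim <- simulate_melsm(n = 10, J = 25, seed = 13)
  st <- varwithin:::person_stats(sim$data)
  set.seed(3); a <- varwithin:::init_state(st, prior_spec(), 1L)
  set.seed(3); b <- varwithin:::init_state(st, prior_spec(), 1L)
  expect_identical(a, b)
  expect_equal(a$beta0, mean(sim$data$y))
  expect_equal(a$eta0, log(oracle_pooled_var(sim$data)), tolerance = 1e-12)
  expect_equal(a$delta, 1L)
  # prior medians for the SDs
  expect_equal(a$tau_mu, qt(0.75, 10))
  const <- data.frame(person_id = rep(c("a", "b"), each = 3), y = rep(1, 6))
  expect_error(fit_melsm(const), "degenerate")
})

test_that("indicator full conditional matches a two-point likelihood oracle", {
  sim <- simulate_melsm(n = 3, J = 8, tau_sigma = 0.6, seed = 17)
  st <- varwithin:::person_stats(sim$data)
  fx <- list(beta0 = 0.7, eta0 = -3.0, tau_mu = 0.1, tau_sigma = 0.5,
             z_f = 0.3, z_mu = c(-0.5, 0.2, 1.1), z_sigma = c(0.8, -1, 0.4))
  fit <- fit_melsm(sim$data, priors = prior_spec(pi = 0.4),
                   control = sampler_spec(n_iter = 21000, burn_in = 1000,
                                          n_chains = 1, seed = 7),
                   fixed = fx)
  # oracle: direct two-point likelihood evaluation per person
  rho <- tanh(fx$z_f); lam <- fx$z_mu * rho + fx$z_sigma * sqrt(1 - rho^2)
  ll1 <- ll0 <- 0
  for (i in 1:3) {
    y <- sim$data$y[sim$data$person_id == st$person_id[i]]
    m <- fx$beta0 + fx$tau_mu * fx$z_mu[i]
    ll1 <- ll1 + oracle_loglik(y, m, exp(fx$eta0 + fx$tau_sigma * lam[i]))
    ll0 <- ll0 + oracle_loglik(y, m, exp(fx$eta0))
  }
  p1 <- plogis(log(0.4 / 0.6) + ll1 - ll0)
  # with everything else fixed the delta draws are iid Bernoulli(p1)
  d <- as.matrix(fit)[, "delta"]
  expect_false(p1 %in% c(0, 1))
  expect_lt(abs(mean(d) - p1),
            4 * sqrt(max(p1 * (1 - p1), 1e-6) / length(d)) + 1e-3)
})

test_that("a likelihood-neutral slab makes inclusion revert to the prior", {
  sim <- simulate_melsm(n = 4, J = 10, seed = 19)
  fx <- list(beta0 = 0.7, eta0 = -3.2, tau_mu = 0.1, tau_sigma = 0,
             z_f = 0, z_mu = rep(0, 4), z_sigma = rep(0, 4))
  fit <- fit_melsm(sim$data, priors = prior_spec(pi = 0.3),
                   control = sampler_spec(n_iter = 11000, burn_in = 1000,
                                          n_chains = 1, seed = 2),
                   fixed = fx)
  d <- as.matrix(fit)[, "delta"]
  expect_lt(abs(mean(d) - 0.3), 4 * sqrt(0.3 * 0.7 / length(d)))
  # an extreme prior forces inclusion almost surely
  fit99 <- fit_melsm(sim$data, priors = prior_spec(pi = 0.99),
                     control = sampler_spec(n_iter = 6000, burn_in = 1000,
                                            n_chains = 1, seed = 2),
                     fixed = fx)
  expect_gt(mean(as.matrix(fit99)[, "delta"]), 0.95)
})

test_that("the location fixed effect reproduces its conjugate posterior", {
  set.seed(31)
  s2 <- 0.04
  y <- rnorm(60, 0.5, sqrt(s2))
  d <- data.frame(person_id = rep(c("a", "b"), each = 30), y = y)
  fx <- list(eta0 = log(s2), tau_mu = 0, tau_sigma = 0, z_f = 0,
             z_mu = c(0, 0), z_sigma = c(0, 0))
  fit <- fit_melsm(d, control = sampler_spec(model_variant = "plain_melsm",
                                             n_iter = 11000, burn_in = 1000,
                                             n_chains = 1, seed = 4),
                   fixed = fx)
  # reduced model: y ~ N(beta0, s2), beta0 ~ N(0, 1)
  prec <- 1 + length(y) / s2
  post_mean <- (sum(y) / s2) / prec
  post_sd <- 1 / sqrt(prec)
  b <- as.matrix(fit)[, "beta0"]
  mcse <- sd(b) / sqrt(length(b)) # conjugate draws are iid
  expect_lt(abs(mean(b) - post_mean), 3 * mcse)
  expect_lt(abs(sd(b) - post_sd) / post_sd, 0.05)
})

test_that("sampled joint of (eta0, delta) matches deterministic quadrature", {
  sim <- simulate_melsm(n = 2, J = 5, tau_sigma = 0.6, seed = 23)
  st <- varwithin:::person_stats(sim$data)
  fx <- list(beta0 = 0.7, tau_mu = 0.1, tau_sigma = 0.5, z_f = 0,
             z_mu = c(0.4, -0.6), z_sigma = c(1.2, -0.8))
  pi0 <- 0.5
  fit <- fit_melsm(sim$data, priors = prior_spec(pi = pi0),
                   control = sampler_spec(n_iter = 41000, burn_in = 1000,
                                          n_chains = 1, seed = 9),
                   fixed = fx)
  dr <- as.matrix(fit)
  # brute-force quadrature over eta0 for each indicator value
  lam <- fx$z_sigma # z_f = 0 so rho = 0: only z_sigma enters the scale
  ll_given <- function(e0, d) {
    s <- 0
    for (i in 1:2) {
      y <- sim$data$y[sim$data$person_id == st$person_id[i]]
      v <- exp(e0 + d * fx$tau_sigma * lam[i])
      s <- s + oracle_loglik(y, fx$beta0 + fx$tau_mu * fx$z_mu[i], v)
    }
    s
  }
  grid <- seq(-8, 2, length.out = 4001)
  h <- grid[2] - grid[1]
  f1 <- vapply(grid, function(e) ll_given(e, 1), 0.0) + dnorm(grid, log = TRUE)
  f0 <- vapply(grid, function(e) ll_given(e, 0), 0.0) + dnorm(grid, log = TRUE)
  mx <- max(c(f1, f0))
  m1 <- pi0 * sum(exp(f1 - mx)) * h
  m0 <- (1 - pi0) * sum(exp(f0 - mx)) * h
  p1 <- m1 / (m1 + m0)
  expect_false(p1 %in% c(0, 1))
  expect_lt(abs(mean(dr[, "delta"]) - p1), 0.03)
  # marginal of eta0: mixture CDF from the grid vs sampled quantiles
  dens <- (pi0 * exp(f1 - mx) + (1 - pi0) * exp(f0 - mx))
  cdf <- cumsum(dens) / sum(dens)
  for (q in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    oracle_q <- grid[which.min(abs(cdf - q))]
    expect_lt(abs(quantile(dr[, "eta0"], q) - oracle_q), 0.06)
  }
})

test_that("independent master seeds agree on the posterior model probability", {
  sim <- simulate_melsm(n = 20, J = 40, tau_sigma = 0.25, seed = 29)
  ev <- lapply(c(101, 202), function(s)
    model_evidence(fit_melsm(sim$data,
      control = sampler_spec(n_iter = 8000, burn_in = 2000,
                             n_chains = 2, seed = s))))
  se <- sqrt(ev[[1]]$mc_se^2 + ev[[2]]$mc_se^2)
  expect_lt(abs(ev[[1]]$pr_slab - ev[[2]]$pr_slab), 3 * se + 0.02)
})

test_that("posterior agrees with an independent JAGS fit of the same model", {
  sim <- simulate_melsm(n = 10, J = 40, tau_sigma = 0.4, seed = 37)
  fit <- fit_melsm(sim$data,
                   control = sampler_spec(n_iter = 12000, burn_in = 3000,
                                          n_chains = 2, seed = 3))
  d <- as.matrix(fit)

  ymat <- matrix(sim$data$y, nrow = 10, byrow = TRUE)
  model <- "
  model {
    for (i in 1:n) {
      mu[i] <- b0 + tmu * zmu[i]
      lam[i] <- zmu[i] * rho + zsig[i] * sqrt(1 - rho^2)
      eta[i] <- e0 + d * tsig * lam[i]
      for (j in 1:J) { y[i, j] ~ dnorm(mu[i], exp(-eta[i])) }
      zmu[i] ~ dnorm(0, 1)
      zsig[i] ~ dnorm(0, 1)
    }
    b0 ~ dnorm(0, 1)
    e0 ~ dnorm(0, 1)
    zf ~ dnorm(0, 1)
    rho <- tanh(zf)
    tmu ~ dt(0, 1, 10) T(0,)
    tsig ~ dt(0, 1, 10) T(0,)
    d ~ dbern(0.5)
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = ymat, n = 10, J = 40),
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Wichmann-Hill",
                                       .RNG.seed = 1))
  update(jm, 3000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("b0", "e0", "tmu", "d"), 9000,
                            progress.bar = "none")
  jd <- do.call(rbind, lapply(js, as.matrix))

  expect_lt(abs(mean(d[, "beta0"]) - mean(jd[, "b0"])), 0.03)
  expect_lt(abs(mean(d[, "eta0"]) - mean(jd[, "e0"])), 0.12)
  expect_lt(abs(mean(d[, "tau_mu"]) - mean(jd[, "tmu"])), 0.05)
  expect_lt(abs(mean(d[, "delta"]) - mean(jd[, "d"])), 0.1)
})

test_that("diagnostics flag duplicated, degenerate, and healthy chains", {
  set.seed(55)
  n <- 3
  S <- 2000
  draws <- flat_draws(beta0 = rnorm(S), eta0 = rnorm(S, -3, 0.1),
                      tau_mu = abs(rnorm(S, 0.1, 0.01)),
                      tau_sigma = abs(rnorm(S, 0.4, 0.05)),
                      rho = tanh(rnorm(S, 0.3, 0.1)), n = n,
                      delta = rbinom(S, 1, 0.5))
  fit <- fake_fit(draws, "pick_group", c("a", "b", "c"))
  fit$draws <- fit$draws[c(1, 1)] # duplicated chains
  dg <- diagnostics(fit)
  # independent draws: split R-hat within sampling noise of 1
  expect_true(all(abs(dg$summary$rhat - 1) < 0.02))
  # iid draws: ESS close to the nominal count
  expect_gt(dg$summary$ess[dg$summary$parameter == "beta0"], 0.8 * 2 * S)
  expect_lt(dg$summary$ess[dg$summary$parameter == "beta0"], 1.25 * 2 * S)
  # frozen indicator: zero switches plus a warning
  frozen <- flat_draws(beta0 = rnorm(S), eta0 = rnorm(S, -3, 0.1),
                       tau_mu = abs(rnorm(S, 0.1, 0.01)),
                       tau_sigma = abs(rnorm(S, 0.4, 0.05)),
                       rho = tanh(rnorm(S, 0.3, 0.1)), n = n,
                       delta = rep(1, S))
  ffit <- fake_fit(frozen, "pick_group", c("a", "b", "c"))
  w <- capture_warnings(dgf <- diagnostics(ffit))
  expect_true(any(grepl("single chain", w)))
  expect_true(any(grepl("never switched", w)))
  expect_identical(unname(dgf$delta_switches), 0)
})
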