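# Independent oracles used across tests.  These deliberately avoid the
# package's own computational paths: densities are summed point by point,
# posteriors are integrated on grids, and moments come from closed forms or
# numerical integration.

# point-by-point normal log density sum (variance parameterization)
oracle_loglik <- function(y, mean, var) {
  s <- 0
  for (v in y) s <- s + (-0.5 * log(2 * pi * var) - (v - mean)^2 / (2 * var))
  s
}

# half-Student-t log density from the folding definition
oracle_ldhalf_t <- function(x, df, scale) {
  if (x < 0) return(-Inf)
  log(2) + stats::dt(x / scale, df, log = TRUE) - log(scale)
}

# term-by-term joint log prior
oracle_log_prior <- function(state, pr) {
  if (state$tau_mu < 0 || state$tau_sigma < 0) return(-Inf)
  total <- stats::dnorm(state$beta0, pr$beta0_loc, pr$beta0_scale, log = TRUE)
  total <- total + stats::dnorm(state$eta0, pr$eta0_loc, pr$eta0_scale, log = TRUE)
  total <- total + oracle_ldhalf_t(state$tau_mu, pr$tau_mu_df, pr$tau_mu_scale)
  total <- total + oracle_ldhalf_t(state$tau_sigma, pr$tau_sigma_df,
                                   pr$tau_sigma_scale)
  total <- total + stats::dnorm(state$z_f, pr$rho_fisher_loc,
                                pr$rho_fisher_scale, log = TRUE)
  for (z in state$z_mu) total <- total + stats::dnorm(z, log = TRUE)
  for (z in state$z_sigma) total <- total + stats::dnorm(z, log = TRUE)
  for (d in state$delta)
    total <- total + if (d == 1) log(pr$pi) else log(1 - pr$pi)
  total
}

# two-pass pooled within-person variance
oracle_pooled_var <- function(data) {
  ids <- unique(data$person_id)
  ss <- 0; N <- 0
  for (id in ids) {
    y <- data$y[data$person_id == id]
    ss <- ss + sum((y - mean(y))^2)
    N <- N + length(y)
  }
  ss / (N - length(ids))
}

# fake fit object with hand-built draws, for analysis-layer arithmetic tests
fake_fit <- function(draws, variant, person_id, n_chains = 1) {
  n <- length(person_id)
  stopifnot(ncol(draws) == 5 + 2 * n +
              if (variant == "membership") n else 1)
  colnames(draws) <- varwithin:::draw_colnames(
    person_id, match(variant, c("plain_melsm", "pick_group", "membership")) - 1L)
  structure(list(draws = list(draws), variant = variant,
                 person_id = person_id, J = rep(10L, n), n = n,
                 priors = prior_spec(),
                 control = sampler_spec(model_variant = variant,
                                        n_iter = nrow(draws) + 1,
                                        burn_in = 1, n_chains = n_chains),
                 accept = NULL, fixed = NULL, prior_only = FALSE),
            class = "melsm_fit")
}

# draw matrix where every person has u1i = 0 (z vectors zero) and the
# globals follow supplied vectors
flat_draws <- function(beta0, eta0, tau_mu, tau_sigma, rho, n,
                      delta = rep(1, length(beta0)), membership = FALSE) {
  S <- length(beta0)
  zd <- matrix(0, S, 2 * n)
  dd <- if (membership) matrix(delta, S, n) else matrix(delta, S, 1)
  cbind(beta0, eta0, tau_mu, tau_sigma, rho, zd, dd)
}
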