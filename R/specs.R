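#' Prior specification for the location-scale model
#'
#' Collects every prior hyperparameter of the model.  Defaults follow the
#' weakly informative choices used throughout: standard normal priors on the
#' fixed location and scale intercepts and on the Fisher-z transformed
#' location-scale correlation, half-Student-t (df 10, scale 1) priors on both
#' between-person SDs, and an inclusion probability `pi = 0.5` that puts
#' equal prior odds on the spike and the slab.
#'
#' The outcome-scale priors assume the outcome is on a scale where values of
#' order 1 are plausible (e.g., reaction times in seconds, or standardized
#' scores).  For outcomes in milliseconds either rescale the data or widen
#' `beta0_scale`/`eta0_scale` accordingly.
#'
#' @param pi Prior slab inclusion probability, in (0, 1).  Smaller values
#'   act as a multiplicity control in the membership model.
#' @param beta0_loc,beta0_scale Normal prior on the fixed location intercept.
#' @param eta0_loc,eta0_scale Normal prior on the fixed scale intercept
#'   (log-variance units).
#' @param tau_mu_df,tau_mu_scale Half-Student-t prior on the between-person
#'   SD of location intercepts.
#' @param tau_sigma_df,tau_sigma_scale Half-Student-t prior on the
#'   between-person SD of scale intercepts (the slab component).
#' @param rho_fisher_loc,rho_fisher_scale Normal prior on the Fisher-z
#'   transformed location-scale correlation.
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(pi = 0.5,
                       beta0_loc = 0, beta0_scale = 1,
                       eta0_loc = 0, eta0_scale = 1,
                       tau_mu_df = 10, tau_mu_scale = 1,
                       tau_sigma_df = 10, tau_sigma_scale = 1,
                       rho_fisher_loc = 0, rho_fisher_scale = 1) {
  check_prob_open("pi", pi)
  for (nm in c("beta0_scale", "eta0_scale", "tau_mu_scale", "tau_sigma_scale",
               "rho_fisher_scale", "tau_mu_df", "tau_sigma_df")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
  }
  structure(list(pi = pi,
                 beta0_loc = beta0_loc, beta0_scale = beta0_scale,
                 eta0_loc = eta0_loc, eta0_scale = eta0_scale,
                 tau_mu_df = tau_mu_df, tau_mu_scale = tau_mu_scale,
                 tau_sigma_df = tau_sigma_df, tau_sigma_scale = tau_sigma_scale,
                 rho_fisher_loc = rho_fisher_loc,
                 rho_fisher_scale = rho_fisher_scale),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior specification\n")
  cat(sprintf("  inclusion probability pi      : %.3f\n", x$pi))
  cat(sprintf("  beta0  ~ N(%g, %g^2)\n", x$beta0_loc, x$beta0_scale))
  cat(sprintf("  eta0   ~ N(%g, %g^2)  [log-variance]\n", x$eta0_loc, x$eta0_scale))
  cat(sprintf("  tau_mu ~ half-t(df = %g, scale = %g)\n", x$tau_mu_df, x$tau_mu_scale))
  cat(sprintf("  tau_sigma ~ half-t(df = %g, scale = %g)  [slab]\n",
              x$tau_sigma_df, x$tau_sigma_scale))
  cat(sprintf("  Fisher-z(rho) ~ N(%g, %g^2)\n", x$rho_fisher_loc, x$rho_fisher_scale))
  invisible(x)
}

#' Sampler run settings
#'
#' MCMC settings for [fit_melsm()].  The defaults (20,000 iterations with a
#' 5,000-iteration burn-in) give stable posterior model probabilities on
#' typical reaction-time data sets; validation studies in this package use
#' shorter chains.
#'
#' @param model_variant One of `"pick_group"` (spike-and-slab on the scale
#'   random-effects SD: the global common-variance test), `"membership"`
#'   (per-person spike-and-slab on scale random effects), or `"plain_melsm"`
#'   (no selection; indicator fixed at 1).
#' @param n_iter Total MCMC iterations per chain.
#' @param burn_in Iterations discarded per chain (`< n_iter`).
#' @param n_chains Number of chains (>= 1); 2+ enables split R-hat.
#' @param seed Master seed; per-chain streams are derived from it.
#' @param adapt_until Proposal step sizes adapt up to this iteration
#'   (`<= burn_in`) and are frozen afterwards, so retained draws come from a
#'   fixed-kernel Markov chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @return An object of class `"sampler_spec"`.
#' @export
sampler_spec <- function(model_variant = c("pick_group", "membership",
                                           "plain_melsm"),
                         n_iter = 20000, burn_in = 5000, n_chains = 4,
                         seed = 1, adapt_until = burn_in, thin = 1) {
  model_variant <- match.arg(model_variant)
  stopifnot(n_iter >= 2, burn_in >= 0, n_chains >= 1, thin >= 1)
  if (burn_in >= n_iter) stop("`burn_in` must be < `n_iter`", call. = FALSE)
  if (adapt_until > burn_in)
    stop("`adapt_until` must be <= `burn_in`", call. = FALSE)
  structure(list(model_variant = model_variant,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 adapt_until = as.integer(adapt_until),
                 thin = as.integer(thin)),
            class = "sampler_spec")
}

#' @export
print.sampler_spec <- function(x, ...) {
  cat("Sampler settings\n")
  cat(sprintf("  variant: %s\n", x$model_variant))
  cat(sprintf("  %d iterations, %d burn-in, thin %d, %d chain(s), seed %d\n",
              x$n_iter, x$burn_in, x$thin, x$n_chains, x$seed))
  invisible(x)
}
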