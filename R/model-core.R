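#' Intraclass correlation for single scores, ICC(1)
#'
#' The proportion of total variance attributable to between-person
#' differences, `sigma0_sq / (sigma0_sq + sigma_eps_sq)`.  In repeated
#' measurement designs this is the reliability of a single trial: the
#' between-person variance over the total variance, where the residual
#' (within-person) variance captures trial-to-trial noise.
#'
#' @param sigma0_sq Between-person variance (>= 0).
#' @param sigma_eps_sq Within-person (residual) variance (> 0).
#' @return The ICC, a value in `[0, 1)`.  Vectorized over both arguments.
#' @seealso [varying_icc()] for the person-specific version.
#' @examples
#' icc1(1, 3)   # 0.25
#' @export
icc1 <- function(sigma0_sq, sigma_eps_sq) {
  if (any(!is.finite(sigma0_sq)) || any(sigma0_sq < 0))
    stop("`sigma0_sq` must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(sigma_eps_sq)) || any(sigma_eps_sq <= 0))
    stop("`sigma_eps_sq` must be finite and > 0", call. = FALSE)
  sigma0_sq / (sigma0_sq + sigma_eps_sq)
}

#' Individually varying intraclass correlation
#'
#' Person-specific reliability under a location-scale model: the common
#' between-person variance divided by that variance plus the person's own
#' residual variance `exp(eta0 + u1i)`, where `eta0` is the average
#' log-residual-variance and `u1i` the person's scale random effect.
#' With `u1i = 0` this reduces to [icc1()] evaluated at `exp(eta0)`.
#'
#' @param sigma0_sq Between-person variance (>= 0).
#' @param eta0 Average log residual variance.
#' @param u1i Person-specific deviation on the log-variance scale.
#' @return The person-specific ICC in `[0, 1)`.  Vectorized.
#' @examples
#' varying_icc(0.5, 0, log(2))  # 0.2
#' @export
varying_icc <- function(sigma0_sq, eta0, u1i) {
  if (any(!is.finite(sigma0_sq)) || any(sigma0_sq < 0))
    stop("`sigma0_sq` must be finite and >= 0", call. = FALSE)
  ex <- eta0 + u1i
  big <- is.finite(ex) & abs(ex) > 700
  if (any(big)) {
    warning("log-variance exponent clamped to +/-700 to avoid overflow")
    ex <- pmin(pmax(ex, -700), 700)
  }
  sigma0_sq / (sigma0_sq + exp(ex))
}

#' Bayes factors from a posterior inclusion probability
#'
#' Converts the posterior probability of the slab (unrestricted) component
#' into the Bayes factor for the spike (common-variance) model against the
#' unrestricted model, correcting for the prior odds:
#' `BF_0u = [(1 - p) / p] / [(1 - pi) / pi]` where `p` is the posterior
#' and `pi` the prior inclusion probability.  Equal prior odds
#' (`pi = 0.5`) make the posterior odds and the Bayes factor coincide.
#'
#' @param pr_slab Posterior probability of the slab component, in `[0, 1]`.
#' @param prior_inclusion Prior inclusion probability `pi`, in `(0, 1)`.
#'   Default 0.5 (equal prior odds).
#' @param s_total Optional number of posterior draws behind `pr_slab`.  When
#'   the probability estimate is exactly 0 or 1 the Bayes factor is infinite;
#'   `s_total` attaches the finite evidential bound `BF > s_total` that S
#'   draws can actually support.
#' @return A list of class `"bf_pair"` with elements `bf_0u`, `bf_u0`, and
#'   `bound` (`NA` unless one side is infinite and `s_total` was given).
#' @examples
#' bf_from_posterior_prob(0.25, 0.5)  # BF_0u = 3
#' bf_from_posterior_prob(0.90, 0.5)  # BF_u0 = 9
#' @export
bf_from_posterior_prob <- function(pr_slab, prior_inclusion = 0.5,
                                   s_total = NULL) {
  stopifnot(length(pr_slab) == 1L, length(prior_inclusion) == 1L)
  if (!is.finite(pr_slab) || pr_slab < 0 || pr_slab > 1)
    stop("`pr_slab` must be in [0, 1]", call. = FALSE)
  check_prob_open("prior_inclusion", prior_inclusion)
  prior_odds <- (1 - prior_inclusion) / prior_inclusion
  bound <- NA_real_
  if (pr_slab == 0) {
    bf_0u <- Inf; bf_u0 <- 0
    if (!is.null(s_total)) bound <- s_total
  } else if (pr_slab == 1) {
    bf_0u <- 0; bf_u0 <- Inf
    if (!is.null(s_total)) bound <- s_total
  } else {
    bf_0u <- ((1 - pr_slab) / pr_slab) / prior_odds
    bf_u0 <- 1 / bf_0u
  }
  structure(list(bf_0u = bf_0u, bf_u0 = bf_u0, bound = bound),
            class = "bf_pair")
}

#' @export
print.bf_pair <- function(x, ...) {
  cat("Bayes factors (spike = common variance, slab = unrestricted)\n")
  cat(sprintf("  BF_0u = %s   BF_u0 = %s\n",
              format(x$bf_0u, digits = 4), format(x$bf_u0, digits = 4)))
  if (!is.na(x$bound))
    cat(sprintf("  probability estimate degenerate: BF > %g given the draw count\n",
                x$bound))
  invisible(x)
}

#' Per-person membership Bayes factor
#'
#' Bayes factor that person i belongs to the common-variance model, from the
#' posterior probability that their scale random effect was excluded
#' (`delta_i = 0`), corrected for the prior odds.  With equal prior odds it
#' is `Pr(eta0i = eta0 | Y) / (1 - Pr(eta0i = eta0 | Y))`.
#'
#' @param pr_common_i Posterior probability that person i sits in the spike,
#'   in `[0, 1]`.  Vectorized.
#' @param prior_inclusion Prior slab inclusion probability `pi`, in `(0, 1)`.
#' @param s_total Optional draw count; degenerate probabilities report the
#'   bound `BF > s_total` via the `"bound"` attribute.
#' @return Numeric vector of Bayes factors `BF_0ui` (possibly `Inf`/0), with
#'   attribute `bound` when `s_total` is supplied.
#' @examples
#' member_bf(0.75, 0.5)  # 3
#' @export
member_bf <- function(pr_common_i, prior_inclusion = 0.5, s_total = NULL) {
  if (any(!is.finite(pr_common_i)) || any(pr_common_i < 0 | pr_common_i > 1))
    stop("`pr_common_i` must be in [0, 1]", call. = FALSE)
  check_prob_open("prior_inclusion", prior_inclusion)
  prior_odds_common <- prior_inclusion / (1 - prior_inclusion)
  bf <- (pr_common_i / (1 - pr_common_i)) * prior_odds_common
  bf[pr_common_i == 1] <- Inf
  bf[pr_common_i == 0] <- 0
  if (!is.null(s_total) && any(pr_common_i %in% c(0, 1)))
    attr(bf, "bound") <- s_total
  bf
}

#' Per-person normal log-likelihood
#'
#' Sum over a person's trials of the normal log density with mean `beta0i`
#' and variance `exp(eta0i)` (the exponent keeps the residual variance
#' positive; `exp(eta0i)` is a variance, not a standard deviation).
#'
#' @param y Numeric vector of the person's trial outcomes.
#' @param beta0i Person mean (location intercept).
#' @param eta0i Person log residual variance (scale intercept).
#' @return The log-likelihood (scalar).
#' @export
loglik_person <- function(y, beta0i, eta0i) {
  if (length(y) == 0L || any(!is.finite(y)))
    stop("`y` must be non-empty and finite", call. = FALSE)
  eta0i <- clamp_eta(eta0i)
  sum(stats::dnorm(y, mean = beta0i, sd = exp(eta0i / 2), log = TRUE))
}

clamp_eta <- function(eta, limit = 30) {
  if (any(abs(eta) > limit)) {
    warning(sprintf("eta0i clamped to +/-%g inside exponential", limit))
    eta <- pmin(pmax(eta, -limit), limit)
  }
  eta
}

#' Joint log prior density of a parameter state
#'
#' Sums the log prior densities of all model parameters under a
#' [prior_spec()]: normal priors for the fixed effects and the Fisher-z
#' latent correlation, half-Student-t for the between-person SDs, standard
#' normal for the latent random-effect vectors, and Bernoulli mass for the
#' inclusion indicator(s).
#'
#' @param state Named list with elements `beta0`, `eta0`, `tau_mu`,
#'   `tau_sigma`, `z_f`, `z_mu`, `z_sigma`, `delta` (scalar for the global
#'   test, vector for the membership model).
#' @param priors A [prior_spec()].
#' @return Scalar log density (`-Inf` for negative SDs).
#' @export
log_prior <- function(state, priors = prior_spec()) {
  stopifnot(inherits(priors, "prior_spec"))
  if (state$tau_mu < 0 || state$tau_sigma < 0) return(-Inf)
  lp <- stats::dnorm(state$beta0, priors$beta0_loc, priors$beta0_scale, log = TRUE) +
    stats::dnorm(state$eta0, priors$eta0_loc, priors$eta0_scale, log = TRUE) +
    dhalf_t(state$tau_mu, priors$tau_mu_df, priors$tau_mu_scale, log = TRUE) +
    dhalf_t(state$tau_sigma, priors$tau_sigma_df, priors$tau_sigma_scale, log = TRUE) +
    stats::dnorm(state$z_f, priors$rho_fisher_loc, priors$rho_fisher_scale, log = TRUE) +
    sum(stats::dnorm(state$z_mu, log = TRUE)) +
    sum(stats::dnorm(state$z_sigma, log = TRUE))
  d <- state$delta
  lp + sum(ifelse(d == 1, log(priors$pi), log(1 - priors$pi)))
}

#' Half-Student-t density
#'
#' Density of `|scale * T|` with `T` Student-t on `df` degrees of freedom:
#' twice the scaled t density, folded onto the positive half-line.
#'
#' @param x Quantiles (density is 0 for `x < 0`).
#' @param df Degrees of freedom (> 0).
#' @param scale Scale (> 0).
#' @param log Return the log density?
#' @return Density values.
#' @keywords internal
#' @export
dhalf_t <- function(x, df = 10, scale = 1, log = FALSE) {
  stopifnot(df > 0, scale > 0)
  ld <- ifelse(x < 0, -Inf,
               log(2) + stats::dt(x / scale, df, log = TRUE) - log(scale))
  if (log) ld else exp(ld)
}

rhalf_t <- function(n, df = 10, scale = 1) abs(stats::rt(n, df)) * scale

#' Fisher z transform and its inverse
#'
#' `fisher_z()` maps a correlation in (-1, 1) to the real line (`atanh`);
#' `inv_fisher_z()` maps back (`tanh`).  The model places a normal prior on
#' the transformed location-scale correlation.
#'
#' @param rho Correlation in (-1, 1).
#' @param z Real number.
#' @return Transformed values.
#' @export
fisher_z <- function(rho) atanh(rho)

#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) tanh(z)

check_prob_open <- function(name, p) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop(sprintf("`%s` must be a single value strictly between 0 and 1", name),
         call. = FALSE)
  invisible(p)
}
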