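#' Posterior model probabilities and Bayes factors
#'
#' Estimates posterior model probabilities as the proportion of retained
#' MCMC draws spent in each mixture component, and converts them to Bayes
#' factors with the prior-odds correction.  For the global test
#' (`pick_group`) this is the probability of the unrestricted
#' (varying-variance) model, `Pr(Mu | Y) = mean(delta_s)`; for the
#' membership model it is one probability per person.  Monte Carlo standard
#' errors use the effective sample size of the indicator chain.
#'
#' @param fit A [fit_melsm()] result from the `pick_group` or `membership`
#'   variant.
#' @param prior_inclusion Prior inclusion probability used for the
#'   prior-odds correction; defaults to the `pi` the model was fitted with.
#' @return An object of class `"melsm_evidence"`.  For `pick_group`:
#'   `pr_slab`, `bf_0u`, `bf_u0`, `bf_bound`, `mc_se`, `s_total`.  For
#'   `membership`: a data.frame `person` with per-person `pr_slab`,
#'   `pr_common`, `bf_0ui`, `mc_se`.
#' @export
model_evidence <- function(fit, prior_inclusion = fit$priors$pi) {
  stopifnot(inherits(fit, "melsm_fit"))
  if (fit$variant == "plain_melsm")
    stop("the plain MELSM carries no model-comparison indicator; ",
         "fit with variant 'pick_group' or 'membership'", call. = FALSE)
  check_prob_open("prior_inclusion", prior_inclusion)
  dd <- delta_draws(fit)
  S <- NROW(dd)

  if (fit$variant == "pick_group") {
    p <- mean(dd)
    ess <- binary_ess(fit, "delta")
    mc_se <- if (p %in% c(0, 1)) 0 else sqrt(p * (1 - p) / ess)
    bf <- bf_from_posterior_prob(p, prior_inclusion, s_total = S)
    out <- list(variant = "pick_group", pr_slab = p,
                bf_0u = bf$bf_0u, bf_u0 = bf$bf_u0, bf_bound = bf$bound,
                mc_se = mc_se, ess = ess, s_total = S,
                prior_inclusion = prior_inclusion)
  } else {
    p <- colMeans(dd)
    ess <- vapply(paste0("delta[", fit$person_id, "]"),
                  function(nm) binary_ess(fit, nm), 0.0)
    mc_se <- ifelse(p %in% c(0, 1), 0, sqrt(p * (1 - p) / ess))
    bf <- member_bf(1 - p, prior_inclusion, s_total = S)
    out <- list(variant = "membership",
                person = data.frame(person_id = fit$person_id,
                                    pr_slab = unname(p),
                                    pr_common = unname(1 - p),
                                    bf_0ui = as.numeric(bf),
                                    mc_se = unname(mc_se),
                                    stringsAsFactors = FALSE),
                bf_bound = attr(bf, "bound"), s_total = S,
                prior_inclusion = prior_inclusion)
  }
  structure(out, class = "melsm_evidence")
}

# ESS of a (possibly binary) parameter, summed over chains; constant chains
# contribute their length (they carry no autocorrelation information).
binary_ess <- function(fit, par) {
  sum(vapply(fit$draws, function(m) {
    v <- m[, par]
    if (stats::var(v) == 0) return(length(v))
    as.numeric(coda::effectiveSize(coda::mcmc(v)))
  }, 0.0))
}

#' @export
print.melsm_evidence <- function(x, ...) {
  if (x$variant == "pick_group") {
    cat("Common-variance test (spike-and-slab on tau_sigma)\n")
    cat(sprintf("  Pr(Mu | Y) = %.4f  (MC-SE %.4f, %d draws)\n",
                x$pr_slab, x$mc_se, x$s_total))
    cat(sprintf("  BF_0u = %s   BF_u0 = %s\n",
                format(x$bf_0u, digits = 4), format(x$bf_u0, digits = 4)))
    if (!is.na(x$bf_bound))
      cat(sprintf("  degenerate probability estimate: BF > %g\n", x$bf_bound))
  } else {
    cat("Membership model (per-person spike-and-slab)\n")
    cat(sprintf("  %d persons, %d draws; Pr(common) range [%.3f, %.3f]\n",
                nrow(x$person), x$s_total,
                min(x$person$pr_common), max(x$person$pr_common)))
    print(utils::head(x$person, 6))
    if (nrow(x$person) > 6) cat(sprintf("  ... %d more persons\n",
                                        nrow(x$person) - 6))
  }
  invisible(x)
}
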