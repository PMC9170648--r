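#' Convergence diagnostics for an MCMC fit
#'
#' Split R-hat and effective sample size for the continuous model
#' parameters, acceptance rates of the random-walk blocks, and the number
#' of inclusion-indicator transitions per chain.  Warnings are raised when
#' any split R-hat exceeds 1.05 or when an indicator never switches (the
#' posterior model probability is then only bounded, not estimated).
#'
#' @param fit A [fit_melsm()] result.
#' @param pars Parameters to diagnose; defaults to the five global ones.
#' @return Object of class `"melsm_diag"`: data.frame `summary` (parameter,
#'   `rhat`, `ess`), `accept` rates per chain, `delta_switches` per chain.
#' @export
diagnostics <- function(fit, pars = c("beta0", "eta0", "tau_mu",
                                      "tau_sigma", "rho")) {
  stopifnot(inherits(fit, "melsm_fit"))
  single <- length(fit$draws) < 2
  if (single)
    warning("single chain: split R-hat omitted")
  sm <- data.frame(parameter = pars,
                   rhat = NA_real_, ess = NA_real_,
                   stringsAsFactors = FALSE)
  for (k in seq_along(pars)) {
    chains <- lapply(fit$draws, function(m) m[, pars[k]])
    if (!single) sm$rhat[k] <- split_rhat(chains)
    sm$ess[k] <- sum(vapply(chains, function(v) {
      if (stats::var(v) == 0) return(length(v))
      as.numeric(coda::effectiveSize(coda::mcmc(v)))
    }, 0.0))
  }
  switches <- NULL
  if (fit$variant != "plain_melsm") {
    dcols <- grep("^delta", colnames(fit$draws[[1]]), value = TRUE)
    switches <- vapply(fit$draws, function(m)
      sum(apply(m[, dcols, drop = FALSE], 2,
                function(v) sum(diff(v) != 0))), 0)
    if (all(switches == 0))
      warning("inclusion indicator never switched; ",
              "model probabilities are bounded, not estimated")
  }
  bad <- sm$parameter[!is.na(sm$rhat) & sm$rhat > 1.05]
  if (length(bad))
    warning("split R-hat > 1.05 for: ", paste(bad, collapse = ", "))
  structure(list(summary = sm, accept = fit$accept,
                 delta_switches = switches),
            class = "melsm_diag")
}

# Classic split R-hat: halve each chain, compare between- and within-half
# variances.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    L <- floor(length(v) / 2)
    list(v[seq_len(L)], v[L + seq_len(L)])
  }), recursive = FALSE)
  L <- length(halves[[1]])
  means <- vapply(halves, mean, 0.0)
  vars <- vapply(halves, stats::var, 0.0)
  W <- mean(vars)
  B <- L * stats::var(means)
  if (W == 0) return(1)
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' @export
print.melsm_diag <- function(x, ...) {
  cat("MCMC diagnostics\n")
  print(transform(x$summary, rhat = round(rhat, 3), ess = round(ess)))
  if (!is.null(x$delta_switches))
    cat("indicator switches per chain:",
        paste(x$delta_switches, collapse = ", "), "\n")
  invisible(x)
}
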