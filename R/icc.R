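#' Posterior summaries of common and varying ICCs
#'
#' Computes, per retained draw, the common ICC
#' `tau_mu^2 / (tau_mu^2 + exp(eta0))` and each person's varying ICC
#' `tau_mu^2 / (tau_mu^2 + exp(eta0i))`, then summarizes them by posterior
#' mean and equal-tailed credible interval.  Persons whose interval excludes
#' the posterior mean of the common ICC are flagged; within-person SDs are
#' summarized as the posterior mean of `exp(eta0i / 2)`.
#'
#' @param fit A [fit_melsm()] result (any variant).
#' @param level Credible-interval level, default 0.90 (equal-tailed).
#' @return An object of class `"icc_result"`: `common` (mean, lo, hi),
#'   `person` (one row per person: `icc_mean`, `icc_lo`, `icc_hi`,
#'   `sd_mean`, `excludes_common`), `prop_flagged`, `level`, and the
#'   [fold_ratios()] of the posterior-mean summaries.
#' @export
icc_summary <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "melsm_fit"), level > 0, level < 1)
  d <- as.matrix(fit)
  a <- (1 - level) / 2
  t2 <- d[, "tau_mu"] ^ 2
  common <- t2 / (t2 + exp(pmin(pmax(d[, "eta0"], -30), 30)))
  eta <- eta_draws(fit)
  picc <- t2 / (t2 + exp(pmin(pmax(eta, -30), 30)))
  qs <- apply(picc, 2, stats::quantile, probs = c(a, 1 - a))
  common_mean <- mean(common)
  person <- data.frame(
    person_id = fit$person_id,
    icc_mean = colMeans(picc),
    icc_lo = qs[1, ], icc_hi = qs[2, ],
    sd_mean = colMeans(exp(eta / 2)),
    stringsAsFactors = FALSE, row.names = NULL)
  person$excludes_common <- person$icc_lo > common_mean |
    person$icc_hi < common_mean
  cq <- stats::quantile(common, probs = c(a, 1 - a))
  structure(list(
    common = c(mean = common_mean, lo = unname(cq[1]), hi = unname(cq[2])),
    person = person,
    prop_flagged = mean(person$excludes_common),
    level = level,
    folds = fold_ratios(person)),
    class = "icc_result")
}

#' Maximum-to-minimum fold ratio
#'
#' `max(x) / min(x)` for a vector of positive summaries, the usual way of
#' expressing how many times larger the most extreme person is than the
#' least extreme (e.g., "a 3.41-fold difference in within-person SDs").
#'
#' @param x Positive numeric vector (length >= 2).
#' @return The fold ratio (`Inf`, with a warning, when `min(x)` is 0).
#' @examples
#' fold_ratio(c(321, 94))  # 3.41
#' @export
fold_ratio <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need >= 2 finite values", call. = FALSE)
  if (any(x < 0)) stop("fold ratios need non-negative values", call. = FALSE)
  if (min(x) == 0) {
    warning("minimum is 0; fold ratio is infinite")
    return(Inf)
  }
  max(x) / min(x)
}

#' Fold-ratio summaries of person-level estimates
#'
#' Max/min ratios of the per-person posterior-mean within-person SDs, the
#' same ratio on the variance scale (its square), and of the posterior-mean
#' ICCs.
#'
#' @param person_summaries A data.frame with columns `sd_mean` and
#'   `icc_mean` (as produced by [icc_summary()]), or an `icc_result`.
#' @return Named list: `fold_sd`, `fold_var`, `fold_icc`.
#' @export
fold_ratios <- function(person_summaries) {
  if (inherits(person_summaries, "icc_result"))
    person_summaries <- person_summaries$person
  stopifnot(is.data.frame(person_summaries),
            all(c("sd_mean", "icc_mean") %in% names(person_summaries)),
            nrow(person_summaries) >= 2)
  fs <- fold_ratio(person_summaries$sd_mean)
  list(fold_sd = fs, fold_var = fs ^ 2,
       fold_icc = fold_ratio(person_summaries$icc_mean))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("Common ICC: %.3f [%.3f, %.3f] (%.0f%% CrI)\n",
              x$common["mean"], x$common["lo"], x$common["hi"],
              100 * x$level))
  cat(sprintf("Varying ICCs: %.3f to %.3f (%.2f-fold); within-person SDs %.2f-fold (%.2f-fold as variances)\n",
              min(x$person$icc_mean), max(x$person$icc_mean),
              x$folds$fold_icc, x$folds$fold_sd, x$folds$fold_var))
  cat(sprintf("%.0f%% of persons have a CrI excluding the common-ICC mean\n",
              100 * x$prop_flagged))
  invisible(x)
}
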