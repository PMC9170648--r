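#' Simulate trial data from the location-scale model
#'
#' Generates long-format trial data with exactly the statistical structure
#' the models assume: person random effects `(u0i, u1i)` drawn bivariate
#' normal with SDs `tau_mu`, `tau_sigma` and correlation `rho`, outcomes
#' `y_ij ~ N(beta0 + u0i, exp(eta0 + u1i))` where the exponential is the
#' residual *variance*.  A `member_fraction` share of persons (selected by a
#' seeded Bernoulli draw) has `u1i` forced to exactly 0, emulating the
#' membership regime in which those persons share the common within-person
#' variance.
#'
#' The defaults mimic a classical Stroop reaction-time task measured in
#' seconds: mean RT about 0.7 s, average within-person variance
#' `exp(-3.2)` (SD about 0.2 s), between-person SD of means 0.1 s, and a
#' modest positive mean-variance correlation.
#'
#' @param n Number of persons (>= 2).
#' @param J Trials per person (>= 2).
#' @param beta0 Fixed location intercept (outcome units).
#' @param eta0 Fixed scale intercept (log-variance units).
#' @param tau_mu Between-person SD of location intercepts (>= 0).
#' @param tau_sigma Between-person SD of scale intercepts (>= 0).
#' @param rho Location-scale random-effect correlation, `|rho| < 1`.
#' @param member_fraction Expected share of persons with `u1i = 0` exactly,
#'   in `[0, 1]`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `"melsm_sim"`: `data` (a [trial_data()]) and
#'   `truth` (generating parameters, per-person `u0i`, `u1i`, membership
#'   flags, and per-person true ICCs).
#' @examples
#' sim <- simulate_melsm(n = 10, J = 20, seed = 1)
#' head(sim$data)
#' @export
simulate_melsm <- function(n = 40, J = 100, beta0 = 0.7, eta0 = -3.2,
                           tau_mu = 0.1, tau_sigma = 0.4, rho = 0.3,
                           member_fraction = 0, seed = 1) {
  stopifnot(n >= 2, J >= 2, tau_mu >= 0, tau_sigma >= 0,
            member_fraction >= 0, member_fraction <= 1)
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  # bivariate normal via Cholesky: u1 | u0 mixes in sqrt(1-rho^2)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  u0 <- tau_mu * z1
  u1 <- tau_sigma * (rho * z1 + sqrt(1 - rho ^ 2) * z2)
  member <- stats::runif(n) < member_fraction
  u1[member] <- 0

  ids <- sprintf("p%03d", seq_len(n))
  y <- stats::rnorm(n * J,
                    mean = rep(beta0 + u0, each = J),
                    sd = rep(exp((eta0 + u1) / 2), each = J))
  data <- data.frame(person_id = rep(ids, each = J),
                     trial = rep(seq_len(J) - 1L, times = n),
                     y = y, stringsAsFactors = FALSE)
  truth <- list(beta0 = beta0, eta0 = eta0, tau_mu = tau_mu,
                tau_sigma = tau_sigma, rho = rho,
                member_fraction = member_fraction, n = n, J = J,
                seed = as.integer(seed),
                person_id = ids, u0i = u0, u1i = u1, member = member,
                icc = varying_icc(tau_mu ^ 2, eta0, u1))
  structure(list(data = trial_data(data), truth = truth),
            class = "melsm_sim")
}

#' @export
print.melsm_sim <- function(x, ...) {
  t <- x$truth
  cat(sprintf(
    "Simulated MELSM data: n = %d, J = %d (seed %d)\n", t$n, t$J, t$seed))
  cat(sprintf(
    "  beta0 = %g, eta0 = %g, tau_mu = %g, tau_sigma = %g, rho = %g\n",
    t$beta0, t$eta0, t$tau_mu, t$tau_sigma, t$rho))
  cat(sprintf("  %d of %d persons share the common variance exactly\n",
              sum(t$member), t$n))
  invisible(x)
}

#' Remove implausible reaction times
#'
#' Applies the standard reaction-time cleaning rule: trials with `y` below
#' `lower` or above `upper` seconds are removed.  Removal uses strict
#' inequalities, so trials exactly at the bounds are retained; set
#' `strict = FALSE` to drop the boundary values too.  Optionally restricts
#' to correct responses.
#'
#' @param data A [trial_data()] or data.frame with `person_id` and `y` in
#'   seconds.
#' @param lower,upper Retention bounds in seconds (defaults 0.2 and 2).
#' @param require_correct Drop rows with `correct` not `TRUE` (requires a
#'   `correct` column)?
#' @param strict If `TRUE` (default) only `y < lower` or `y > upper` are
#'   removed; if `FALSE` the bounds themselves are removed as well.
#' @return The retained rows, with attribute `"removed"`: a data.frame of
#'   per-person removal counts.  Warns when a person is left with fewer than
#'   2 trials; errors when nothing is retained.
#' @examples
#' d <- data.frame(person_id = "a", y = c(0.15, 0.2, 0.7, 2, 2.5))
#' clean_rt(d)  # keeps 0.2, 0.7 and 2
#' @export
clean_rt <- function(data, lower = 0.2, upper = 2.0, require_correct = FALSE,
                     strict = TRUE) {
  stopifnot(is.data.frame(data), lower < upper)
  keep <- if (strict) data$y >= lower & data$y <= upper
          else data$y > lower & data$y < upper
  if (require_correct) {
    if (!"correct" %in% names(data))
      stop("`require_correct = TRUE` needs a `correct` column", call. = FALSE)
    keep <- keep & data$correct %in% TRUE
  }
  ids <- unique(data$person_id)
  f <- factor(data$person_id, levels = ids)
  removed <- data.frame(
    person_id = as.character(ids),
    n_removed = as.integer(tapply(!keep, f, sum)),
    n_retained = as.integer(tapply(keep, f, sum)),
    stringsAsFactors = FALSE)
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("cleaning removed every trial", call. = FALSE)
  short <- removed$person_id[removed$n_retained < 2]
  if (length(short))
    warning(sprintf("persons left with < 2 trials after cleaning: %s",
                    paste(short, collapse = ", ")))
  attr(out, "removed") <- removed
  out
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
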