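#' Prior-sensitivity grid for the membership model
#'
#' Refits the membership model over a grid of prior model probabilities for
#' the common-variance model, `Pr(M0) = 1 - pi`, crossed with slab scales
#' (the half-Student-t scale of the prior on `tau_sigma`; larger scales give
#' a more diffuse slab, which is known to favour the spike).  Each cell is
#' classified with the posterior-odds rule and the class proportions are
#' tabulated, together with every person's posterior probability trajectory
#' across the grid.
#'
#' @param data A [trial_data()] (or data.frame).
#' @param priors Baseline [prior_spec()]; `pi` and `tau_sigma_scale` are
#'   overridden per cell.
#' @param control A [sampler_spec()]; the variant is forced to
#'   `"membership"` and per-cell seeds are derived from `control$seed`.
#' @param prior_m0 Grid of prior probabilities for the common-variance
#'   model.
#' @param slab_scale Grid of slab scales.
#' @param slab_df Slab degrees of freedom (fixed across the grid).
#' @param threshold Posterior-odds threshold for classification (default 3).
#' @return Object of class `"melsm_sensitivity"`: `cells` (one row per grid
#'   cell with class proportions), `trajectories` (person x cell posterior
#'   probabilities of the common model), and `failures` (cells whose fit
#'   errored, recorded and skipped).
#' @export
sensitivity_grid <- function(data, priors = prior_spec(),
                             control = sampler_spec(model_variant = "membership"),
                             prior_m0 = c(0.2, 0.5, 0.8),
                             slab_scale = 1, slab_df = 10,
                             threshold = 3) {
  stopifnot(length(prior_m0) >= 1, length(slab_scale) >= 1)
  if (any(prior_m0 <= 0 | prior_m0 >= 1))
    stop("`prior_m0` values must be strictly inside (0, 1)", call. = FALSE)
  if (any(slab_scale <= 0)) stop("`slab_scale` must be positive", call. = FALSE)
  control$model_variant <- "membership"
  if (!inherits(data, "trial_data")) data <- trial_data(data)

  grid <- expand.grid(prior_m0 = prior_m0, slab_scale = slab_scale,
                      KEEP.OUT.ATTRS = FALSE)
  cells <- grid
  cells$prop_common <- cells$prop_varying <- cells$prop_undecided <- NA_real_
  traj <- NULL
  failures <- list()

  for (k in seq_len(nrow(grid))) {
    pri <- priors
    pri$pi <- 1 - grid$prior_m0[k]
    pri$tau_sigma_scale <- grid$slab_scale[k]
    pri$tau_sigma_df <- slab_df
    ctl <- control
    ctl$seed <- as.integer((control$seed + 104729 * k) %% .Machine$integer.max)
    res <- tryCatch({
      fit <- fit_melsm(data, priors = pri, control = ctl)
      ev <- model_evidence(fit)
      cl <- classify_members(ev, rule = "posterior_odds",
                             threshold = threshold)
      list(ev = ev, cl = cl)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        list(cell = grid[k, ], message = conditionMessage(res))
      next
    }
    pr <- res$cl$counts / nrow(res$cl$person)
    cells$prop_common[k] <- pr[["common"]]
    cells$prop_varying[k] <- pr[["varying"]]
    cells$prop_undecided[k] <- pr[["undecided"]]
    if (is.null(traj))
      traj <- data.frame(person_id = res$ev$person$person_id,
                         stringsAsFactors = FALSE)
    traj[[sprintf("m0_%g_scale_%g", grid$prior_m0[k], grid$slab_scale[k])]] <-
      res$ev$person$pr_common
  }
  structure(list(cells = cells, trajectories = traj, failures = failures,
                 threshold = threshold),
            class = "melsm_sensitivity")
}

#' @export
print.melsm_sensitivity <- function(x, ...) {
  cat(sprintf("Prior-sensitivity grid (posterior-odds threshold %g)\n",
              x$threshold))
  print(transform(x$cells,
                  prop_common = round(prop_common, 3),
                  prop_varying = round(prop_varying, 3),
                  prop_undecided = round(prop_undecided, 3)))
  if (length(x$failures))
    cat(sprintf("%d cell(s) failed to fit\n", length(x$failures)))
  invisible(x)
}
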