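#' Read long-format trial data from CSV
#'
#' Reads a header CSV, renames columns according to `column_map`, coerces
#' the outcome to numeric, drops rows with non-finite outcomes (logging the
#' count), and returns a validated [trial_data()].  Person order is
#' first-appearance order in the file.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping the canonical names
#'   (`person_id`, `y`, and optionally `trial`, `condition`, `correct`) to
#'   the column names in the file.
#' @param quiet Suppress the dropped-row message?
#' @return A [trial_data()].
#' @export
read_trials <- function(path,
                        column_map = c(person_id = "person_id", y = "y"),
                        quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols))
    stop("input is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  cols <- lapply(names(column_map), function(nm) raw[[column_map[[nm]]]])
  names(cols) <- names(column_map)
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  out$y <- suppressWarnings(as.numeric(out$y))
  bad <- !is.finite(out$y)
  if (any(bad)) {
    if (!quiet)
      message(sprintf("dropped %d row(s) with non-finite outcome", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("no usable rows in ", path, call. = FALSE)
  trial_data(out)
}

#' Write trial data to CSV
#'
#' @param data A data.frame of trials.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Serialize posterior draws to CSV
#'
#' Writes one row per retained iteration with a leading `chain` column and
#' one column per named parameter, plus a JSON sidecar (`<path>.meta.json`)
#' holding the metadata needed to rebuild the fit: variant, person ids,
#' trial counts, priors, and sampler settings.
#'
#' @param fit A [fit_melsm()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_draws()]
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "melsm_fit"))
  tab <- do.call(rbind, lapply(seq_along(fit$draws), function(ch)
    cbind(chain = ch, fit$draws[[ch]])))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  meta <- list(variant = fit$variant, person_id = fit$person_id,
               J = fit$J, n = fit$n,
               priors = unclass(fit$priors),
               control = unclass(fit$control),
               chain_seeds = fit$chain_seeds,
               prior_only = isTRUE(fit$prior_only))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Reload serialized posterior draws
#'
#' Reconstructs a `melsm_fit` from the CSV and sidecar written by
#' [write_draws()]; evidence and ICC summaries computed from the reloaded
#' object are identical to those from the original fit.
#'
#' @param path CSV path previously given to [write_draws()].
#' @return A `melsm_fit`.
#' @export
read_draws <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(path) || !file.exists(meta_path))
    stop("draws file or metadata sidecar missing for ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  chains <- lapply(sort(unique(tab$chain)), function(ch) {
    m <- as.matrix(tab[tab$chain == ch, setdiff(names(tab), "chain"),
                       drop = FALSE])
    rownames(m) <- NULL
    m
  })
  priors <- do.call(prior_spec, meta$priors)
  control <- do.call(sampler_spec, meta$control)
  structure(list(draws = chains, variant = meta$variant,
                 person_id = meta$person_id, J = meta$J, n = meta$n,
                 priors = priors, control = control,
                 chain_seeds = meta$chain_seeds, accept = NULL,
                 fixed = NULL, prior_only = isTRUE(meta$prior_only)),
            class = "melsm_fit")
}
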