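#' Long-format trial data
#'
#' Validates a long-format repeated-measures table and attaches the class
#' `"trial_data"`.  The table needs one row per trial with a person
#' identifier and a real-valued outcome; a trial index and optional
#' `condition`/`correct` columns are carried along.  Person indexing is the
#' stable first-appearance order of `person_id`.
#'
#' @param data A data.frame with columns `person_id`, `y`, and optionally
#'   `trial`, `condition`, `correct`.
#' @param min_trials Minimum retained trials per person (default 2).
#' @return The validated data.frame with class `"trial_data"`.
#' @export
trial_data <- function(data, min_trials = 2L) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  for (col in c("person_id", "y"))
    if (!col %in% names(data))
      stop(sprintf("column `%s` is missing", col), call. = FALSE)
  if (!is.numeric(data$y)) stop("`y` must be numeric", call. = FALSE)
  if (any(!is.finite(data$y)))
    stop("`y` contains non-finite values; drop them first (see read_trials)",
         call. = FALSE)
  if (!"trial" %in% names(data)) {
    data$trial <- stats::ave(seq_len(nrow(data)), data$person_id,
                             FUN = seq_along) - 1L
  }
  counts <- table(factor(data$person_id, levels = unique(data$person_id)))
  if (any(counts < min_trials))
    stop(sprintf("every person needs >= %d trials; offending: %s",
                 min_trials,
                 paste(names(counts)[counts < min_trials], collapse = ", ")),
         call. = FALSE)
  class(data) <- unique(c("trial_data", class(data)))
  data
}

# Per-person sufficient statistics in first-appearance order:
# J_i, sum(y), sum(y^2).  The normal likelihood needs nothing else.
person_stats <- function(data) {
  ids <- unique(data$person_id)
  f <- factor(data$person_id, levels = ids)
  J <- as.integer(table(f))
  sy <- as.numeric(tapply(data$y, f, sum))
  ssy <- as.numeric(tapply(data$y ^ 2, f, function(v) sum(v)))
  list(person_id = as.character(ids), J = J, sumy = sy, ssy = ssy,
       n = length(ids))
}

#' @export
print.trial_data <- function(x, ...) {
  st <- person_stats(x)
  cat(sprintf("Trial data: %d persons, %d trials (%d-%d per person)\n",
              st$n, nrow(x), min(st$J), max(st$J)))
  NextMethod()
}
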