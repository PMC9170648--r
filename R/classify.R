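#' Classify persons into the common- or varying-variance model
#'
#' Turns membership-model evidence into per-person labels.  Three rules:
#'
#' * `"bf"` — prior-odds-corrected Bayes factor: `common` when
#'   `BF_0ui >= threshold`, `varying` when `BF_0ui <= 1/threshold`,
#'   otherwise `undecided` (a Bayes factor of 3 is the customary "positive
#'   evidence" reference point);
#' * `"posterior_odds"` — the same symmetric band applied to the raw
#'   posterior odds `Pr(common)/(1 - Pr(common))` (no prior-odds
#'   correction), the rule used for prior-sensitivity displays;
#' * `"median_probability"` — `common` iff `Pr(common) > 0.5`; no undecided
#'   class.
#'
#' @param evidence A membership [model_evidence()] result.
#' @param rule Decision rule (see above).
#' @param threshold Evidence threshold for the `bf` / `posterior_odds`
#'   rules (default 3).
#' @return An object of class `"member_classification"`: the per-person
#'   table with a `label` factor (`common`/`varying`/`undecided`), plus
#'   `counts` and `proportions`.
#' @export
classify_members <- function(evidence,
                             rule = c("bf", "posterior_odds",
                                      "median_probability"),
                             threshold = 3) {
  stopifnot(inherits(evidence, "melsm_evidence"))
  if (evidence$variant != "membership")
    stop("classification needs membership-model evidence", call. = FALSE)
  rule <- match.arg(rule)
  stopifnot(threshold > 0)
  p0 <- evidence$person$pr_common
  lab <- switch(rule,
    bf = {
      bf <- evidence$person$bf_0ui
      ifelse(bf >= threshold, "common",
             ifelse(bf <= 1 / threshold, "varying", "undecided"))
    },
    posterior_odds = {
      odds <- p0 / (1 - p0)
      odds[p0 == 1] <- Inf
      ifelse(odds >= threshold, "common",
             ifelse(odds <= 1 / threshold, "varying", "undecided"))
    },
    median_probability = ifelse(p0 > 0.5, "common", "varying"))
  person <- evidence$person
  person$label <- factor(lab, levels = c("common", "varying", "undecided"))
  counts <- table(person$label)
  structure(list(person = person, rule = rule, threshold = threshold,
                 counts = counts,
                 proportions = as.numeric(counts) / nrow(person)),
            class = "member_classification")
}

#' @export
print.member_classification <- function(x, ...) {
  cat(sprintf("Membership classification (rule: %s, threshold %g)\n",
              x$rule, x$threshold))
  n <- nrow(x$person)
  for (k in seq_along(x$counts))
    cat(sprintf("  %-9s %3d  (%.1f%%)\n", names(x$counts)[k], x$counts[k],
                100 * x$counts[k] / n))
  invisible(x)
}
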