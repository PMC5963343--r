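# RNA-stability quality control: RIN-based sample inclusion and the
# degradation-rate comparison from an accelerated (50 C) incubation
# time-course. Degradation is modeled log-linear in time on the base-2
# scale, matching the quantification module.

#' Partition samples by RNA integrity number
#'
#' Only samples with RIN strictly greater than `min_rin` are kept (the
#' inclusion rule is "higher than", so a sample at exactly the cutoff is
#' excluded). Samples with missing RIN are excluded with a warning. The
#' partition is exhaustive: every input sample lands in exactly one side.
#'
#' @param samples Sample metadata tibble with a `rin` column.
#' @param min_rin Inclusion cutoff (default 6).
#' @return A list with tibbles `kept` and `excluded`.
#' @export
filter_by_rin <- function(samples, min_rin = 6) {
  if (!"rin" %in% names(samples)) {
    abort_validation("`samples` must carry a `rin` column.")
  }
  missing <- is.na(samples$rin)
  if (any(missing)) {
    warn(sprintf(
      "%d sample(s) with missing RIN excluded.", sum(missing)
    ))
  }
  keep <- !missing & samples$rin > min_rin
  list(
    kept = samples[keep, , drop = FALSE],
    excluded = samples[!keep, , drop = FALSE]
  )
}

#' Convert a degradation time-course from Ct to relative amounts
#'
#' Anchors the series at 1 at time zero: `relative_amount = 2^(Ct_t0 - Ct_t)`.
#'
#' @param time_min Numeric vector of incubation times in minutes; must
#'   contain 0.
#' @param ct Detected Ct values at those times.
#' @return Numeric vector of relative amounts (1 at time zero).
#' @export
relative_amount_from_ct <- function(time_min, ct) {
  if (!0 %in% time_min) {
    abort_validation("The time-course must include time 0.")
  }
  if (anyNA(ct)) {
    abort_missing_assay("All time-course Ct values must be detected.")
  }
  2^(ct[match(0, time_min)] - ct)
}

#' Per-minute log2 degradation rate of a transcript
#'
#' Ordinary least-squares slope of `log2(relative_amount)` on incubation
#' time. On an exactly log-linear series the fit is exact (zero residual);
#' an RNA that halves every 60 minutes has rate `-1/60` per minute. A
#' positive fitted rate (amount growing with incubation) is flagged with a
#' warning but returned.
#'
#' @param time_min Incubation times in minutes, strictly increasing,
#'   including 0; at least 3 points.
#' @param relative_amount Positive amounts relative to time zero.
#' @return The fitted slope (per-minute log2 decay, `<= 0` expected), with
#'   attribute `r_squared`.
#' @examples
#' degradation_rate(c(0, 60, 120), c(1, 0.5, 0.25))
#' @export
degradation_rate <- function(time_min, relative_amount) {
  if (length(time_min) < 3L || length(relative_amount) != length(time_min)) {
    abort_insufficient_data(
      "A degradation series needs at least 3 matching timepoints."
    )
  }
  if (is.unsorted(time_min, strictly = TRUE)) {
    abort_validation("`time_min` must be strictly increasing.")
  }
  if (!0 %in% time_min) {
    abort_validation("The series must include time 0.")
  }
  if (any(is.na(relative_amount)) || any(relative_amount <= 0)) {
    abort_validation("Relative amounts must be positive.")
  }
  fit <- lm(log2(relative_amount) ~ time_min)
  rate <- unname(coef(fit)[2L])
  if (rate > 0) {
    warn(sprintf(
      "Positive degradation rate (%.4g/min): amount increases with time.",
      rate
    ))
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log2(relative_amount) - mean(log2(relative_amount)))^2)
  attr(rate, "r_squared") <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  rate
}

#' Compare degradation rates of a target and a reference transcript
#'
#' The ddCt normalization is trustworthy only if the target transcript does
#' not degrade faster than its housekeeping reference, or vice versa. The
#' check is symmetric on the absolute log2 rates: the pair is `comparable`
#' iff neither absolute rate exceeds `max_ratio` times the other. Two
#' perfectly stable transcripts (both rates zero) are comparable; a stable
#' one paired with a degrading one is not.
#'
#' @param rate_target,rate_reference Per-minute log2 decay rates, e.g. from
#'   [degradation_rate()].
#' @param max_ratio Largest tolerated rate ratio (default 2).
#' @param target_assay,reference_assay Optional names carried into the
#'   verdict.
#' @return An object of class `stability_verdict`: `comparable` (logical),
#'   `rate_ratio` (`rate_target / rate_reference`, `NA` if either is zero),
#'   and the inputs.
#' @export
compare_stability <- function(rate_target, rate_reference, max_ratio = 2,
                              target_assay = NA_character_,
                              reference_assay = NA_character_) {
  if (!is_scalar_number(rate_target) || !is_scalar_number(rate_reference)) {
    abort_validation("Both rates must be finite scalars.")
  }
  if (!is_scalar_number(max_ratio) || max_ratio < 1) {
    abort_validation("`max_ratio` must be a number >= 1.")
  }
  a <- abs(rate_target)
  b <- abs(rate_reference)
  comparable <- if (a == 0 && b == 0) {
    TRUE
  } else if (a == 0 || b == 0) {
    FALSE
  } else {
    max(a, b) / min(a, b) <= max_ratio
  }
  structure(
    list(
      target_assay = target_assay,
      reference_assay = reference_assay,
      rate_target = rate_target,
      rate_reference = rate_reference,
      rate_ratio = if (rate_reference != 0 && rate_target != 0) {
        rate_target / rate_reference
      } else {
        NA_real_
      },
      max_ratio = max_ratio,
      comparable = comparable
    ),
    class = "stability_verdict"
  )
}

#' @export
print.stability_verdict <- function(x, ...) {
  cat(sprintf(
    "<stability_verdict> %s vs %s: rates %.4g / %.4g per min -> %s\n",
    x$target_assay, x$reference_assay, x$rate_target, x$rate_reference,
    if (x$comparable) "comparable" else "NOT comparable"
  ))
  invisible(x)
}
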