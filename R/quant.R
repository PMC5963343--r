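# ddCt quantification core: replicate aggregation, standard curves,
# dCt / ddCt, 2^-ddCt with variance bounds, dual-reference averaging,
# the 0.5 / 1.5 significance rule and isoform abundance ratios.
#
# All exponentials are base 2, matching 2^-ddCt and the 2^n isoform ratio.

#' Aggregate technical replicates of one sample x assay x run
#'
#' Returns the mean and sample standard deviation of the detected Ct values;
#' undetected replicates are excluded and counted, never imputed. A single
#' detected replicate yields sd 0.
#'
#' @param ct Numeric vector of Ct values; `NA` marks an undetected well.
#' @return A list with `mean_ct`, `sd_ct`, `n` (detected) and `n_undetected`.
#' @examples
#' aggregate_replicates(c(23.8, 24.2, 24.0))
#' @export
aggregate_replicates <- function(ct) {
  detected <- ct[!is.na(ct)]
  if (length(detected) == 0L) {
    abort_missing_assay("All replicates undetected; no Ct available.")
  }
  list(
    mean_ct = mean(detected),
    sd_ct = if (length(detected) > 1L) sd(detected) else 0,
    n = length(detected),
    n_undetected = sum(is.na(ct))
  )
}

#' Per-sample mean Ct for every assay
#'
#' Aggregates hierarchically: technical replicates are averaged within each
#' run first, then run means are averaged, so runs with unequal replicate
#' counts carry equal weight. The reported `sd_ct` is the standard deviation
#' over all detected replicates, which folds run-to-run scatter into the
#' per-sample spread. Sample x assay cells where every replicate is
#' undetected are dropped with a warning.
#'
#' @param measurements Ct tibble as from [read_ct_table()].
#' @return Tibble with `sample_id`, `assay`, `mean_ct`, `sd_ct`,
#'   `n_replicates`.
#' @export
summarize_ct <- function(measurements) {
  all_missing <- measurements |>
    dplyr::group_by(.data$sample_id, .data$assay) |>
    dplyr::summarise(n_det = sum(!is.na(.data$ct)), .groups = "drop") |>
    dplyr::filter(.data$n_det == 0L)
  if (nrow(all_missing) > 0L) {
    warn(sprintf(
      "Dropping %d sample x assay cell(s) with no detected replicate.",
      nrow(all_missing)
    ))
  }

  run_means <- measurements |>
    dplyr::filter(!is.na(.data$ct)) |>
    dplyr::group_by(.data$sample_id, .data$assay, .data$run_id) |>
    dplyr::summarise(
      run_mean = mean(.data$ct),
      n_run = dplyr::n(),
      .groups = "drop"
    )

  spread <- measurements |>
    dplyr::filter(!is.na(.data$ct)) |>
    dplyr::group_by(.data$sample_id, .data$assay) |>
    dplyr::summarise(
      sd_ct = if (dplyr::n() > 1L) sd(.data$ct) else 0,
      n_replicates = dplyr::n(),
      .groups = "drop"
    )

  run_means |>
    dplyr::group_by(.data$sample_id, .data$assay) |>
    dplyr::summarise(mean_ct = mean(.data$run_mean), .groups = "drop") |>
    dplyr::left_join(spread, by = c("sample_id", "assay"))
}

#' Fit a standard curve and derive amplification efficiency
#'
#' Ordinary least-squares regression of Ct on log10 of the dilution factor of
#' a serially diluted control template. The amplification efficiency is
#' `E = 10^(-1/slope) - 1`; `E = 1` (perfect doubling) corresponds to a slope
#' of `-1/log10(2) = -3.321928`.
#'
#' @param log10_dilution Numeric vector, log10 of the dilution factors
#'   (e.g. 0, -1, -2 for a 10-fold series).
#' @param ct Numeric vector of Ct values, same length.
#' @param assay,run_id Identifiers carried into the result.
#' @return An object of class `standard_curve_fit` with `slope`, `intercept`,
#'   `r_squared` and `efficiency`.
#' @examples
#' d <- simulate_dilution_series(efficiency = 1, noise_sd = 0)
#' fit_standard_curve(d$log10_dilution, d$ct, assay = "GBAtv1", run_id = "r1")
#' @export
fit_standard_curve <- function(log10_dilution, ct, assay = NA_character_,
                               run_id = NA_character_) {
  keep <- !is.na(log10_dilution) & !is.na(ct)
  log10_dilution <- log10_dilution[keep]
  ct <- ct[keep]
  if (length(unique(log10_dilution)) < 3L) {
    abort_insufficient_data(
      "A standard curve needs at least 3 distinct dilution points."
    )
  }
  fit <- lm(ct ~ log10_dilution)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) {
    abort_qc(sprintf(
      "Standard-curve slope must be negative; got %.4g.", slope
    ))
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(
      assay = assay,
      run_id = run_id,
      slope = slope,
      intercept = unname(coef(fit)[1L]),
      r_squared = r2,
      efficiency = 10^(-1 / slope) - 1
    ),
    class = "standard_curve_fit"
  )
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<standard_curve_fit> %s / %s: slope %.4f, R2 %.4f, E %.3f\n",
    x$assay, x$run_id, x$slope, x$r_squared, x$efficiency
  ))
  invisible(x)
}

#' Check that target and reference amplification efficiencies are similar
#'
#' The equal-efficiency ddCt model assumes the target and reference assays
#' amplify at near-identical efficiency; this check compares the two fitted
#' efficiencies and fails (with a warning) when they differ by more than
#' `tolerance`, so downstream estimates can be flagged.
#'
#' @param fit_target,fit_reference [fit_standard_curve()] results.
#' @param tolerance Maximum allowed `|E_target - E_reference|` (default 0.1).
#' @return A list with `pass` (logical), `delta` (observed absolute
#'   difference), and the two efficiencies.
#' @export
check_efficiency_similarity <- function(fit_target, fit_reference,
                                        tolerance = 0.1) {
  if (!inherits(fit_target, "standard_curve_fit") ||
      !inherits(fit_reference, "standard_curve_fit")) {
    abort_qc("Both standard-curve fits are required for the efficiency check.")
  }
  delta <- abs(fit_target$efficiency - fit_reference$efficiency)
  pass <- delta <= tolerance
  if (!pass) {
    warn(sprintf(
      "Amplification efficiencies differ by %.3f (> %.3f): %s vs %s.",
      delta, tolerance, fit_target$assay, fit_reference$assay
    ))
  }
  list(
    pass = pass,
    delta = delta,
    efficiency_target = fit_target$efficiency,
    efficiency_reference = fit_reference$efficiency
  )
}

#' dCt: normalize a target mean Ct against a reference mean Ct
#'
#' @param mean_ct_target,mean_ct_reference Mean Ct values (cycles).
#' @return `mean_ct_target - mean_ct_reference`, vectorized.
#' @examples
#' compute_delta_ct(25, 20)
#' @export
compute_delta_ct <- function(mean_ct_target, mean_ct_reference) {
  if (anyNA(mean_ct_target) || anyNA(mean_ct_reference)) {
    abort_missing_assay("Both target and reference mean Ct must be present.")
  }
  mean_ct_target - mean_ct_reference
}

#' Per-sample dCt table for one target / reference pair
#'
#' @param measurements Ct tibble as from [read_ct_table()].
#' @param target,reference Assay names.
#' @return Tibble with `sample_id`, `target`, `reference`, `delta_ct`,
#'   `n_replicates` (the smaller of the target and reference counts). Samples
#'   lacking either assay are omitted.
#' @export
delta_ct_table <- function(measurements, target, reference) {
  summ <- summarize_ct(
    dplyr::filter(measurements, .data$assay %in% c(target, reference))
  )
  t_tab <- dplyr::filter(summ, .data$assay == target)
  r_tab <- dplyr::filter(summ, .data$assay == reference)
  joined <- dplyr::inner_join(
    dplyr::select(t_tab, "sample_id", mean_t = "mean_ct", n_t = "n_replicates"),
    dplyr::select(r_tab, "sample_id", mean_r = "mean_ct", n_r = "n_replicates"),
    by = "sample_id"
  )
  tibble::tibble(
    sample_id = joined$sample_id,
    target = target,
    reference = reference,
    delta_ct = joined$mean_t - joined$mean_r,
    n_replicates = pmin(joined$n_t, joined$n_r)
  )
}

#' ddCt between a case group and a control group
#'
#' `ddCt = mean(case dCt) - mean(control dCt)`. The standard deviation
#' attached to the ddCt is the sample standard deviation of the per-sample
#' case dCt values; the control group enters through its mean only. This is
#' the spread that the variance bounds `2^-(ddCt +/- SD)` propagate.
#'
#' @param case_dcts,control_dcts Numeric vectors of per-sample dCt values.
#' @return A list with `ddct`, `sd`, `n_case`, `n_control`.
#' @examples
#' compute_group_ddct(c(5.0, 5.2, 5.4), c(4.0, 4.0))
#' @export
compute_group_ddct <- function(case_dcts, control_dcts) {
  case_dcts <- case_dcts[!is.na(case_dcts)]
  control_dcts <- control_dcts[!is.na(control_dcts)]
  if (length(case_dcts) < 1L || length(control_dcts) < 1L) {
    abort_insufficient_data(
      "Both case and control dCt lists must be non-empty."
    )
  }
  list(
    ddct = mean(case_dcts) - mean(control_dcts),
    sd = if (length(case_dcts) > 1L) sd(case_dcts) else 0,
    n_case = length(case_dcts),
    n_control = length(control_dcts)
  )
}

#' Relative expression with variance bounds
#'
#' Point estimate `2^-ddCt`; the interval is obtained by evaluating the same
#' exponential at `ddCt + sd` (lower bound) and `ddCt - sd` (upper bound),
#' so `low <= point <= high` always, with equality iff `sd = 0`, and
#' `point^2 = low * high` exactly for a single-reference estimate.
#'
#' @param ddct ddCt in cycles (may be a vector).
#' @param sd Standard deviation attached to the ddCt, `>= 0` (recycled).
#' @return Tibble with columns `point`, `low`, `high`.
#' @examples
#' relative_expression(1.2, 0.2)
#' @export
relative_expression <- function(ddct, sd = 0) {
  if (any(is.na(ddct)) || any(is.na(sd)) || any(sd < 0)) {
    abort_validation("`ddct` must be finite and `sd` non-negative.")
  }
  tibble::tibble(
    point = 2^(-ddct),
    low = 2^(-(ddct + sd)),
    high = 2^(-(ddct - sd))
  )
}

#' Average relative-expression estimates over reference genes
#'
#' The analysis is run once per housekeeping gene and the final expression
#' change is the arithmetic mean of the per-reference point estimates and
#' bounds. After averaging, the geometric symmetry `point^2 = low * high`
#' holds only approximately.
#'
#' @param re Tibble with one row per reference gene, columns `point`, `low`,
#'   `high`, `reference`, and optionally constant identifier columns
#'   (`target`, `case_group`, `tissue`) which are checked and carried through.
#' @return One-row tibble with averaged `point`, `low`, `high` and a
#'   `references_used` string.
#' @export
combine_references <- function(re) {
  if (!is.data.frame(re) || nrow(re) < 1L) {
    abort_validation("Need at least one per-reference estimate.")
  }
  for (col in c("target", "case_group", "tissue")) {
    if (col %in% names(re) && length(unique(re[[col]])) > 1L) {
      abort_validation(sprintf(
        "All per-reference estimates must share the same `%s`.", col
      ))
    }
  }
  out <- tibble::tibble(
    point = mean(re$point),
    low = mean(re$low),
    high = mean(re$high),
    references_used = paste(
      if ("reference" %in% names(re)) re$reference else "unknown",
      collapse = "+"
    )
  )
  for (col in c("target", "case_group", "tissue")) {
    if (col %in% names(re)) out[[col]] <- re[[col]][1L]
  }
  out
}

#' Classify a relative-expression estimate
#'
#' Fold changes below 0.5 indicate decreased and above 1.5 increased
#' expression, but a change is accepted as significant only when the
#' relevant variance bound clears the threshold too: `decreased` iff
#' `point < 0.5` and `high <= 0.5`; `increased` iff `point > 1.5` and
#' `low >= 1.5`; otherwise `unchanged`. The point comparison is strict and
#' the bound comparison inclusive. Vectorized.
#'
#' @param point,low,high Fold-change point estimate and variance bounds.
#' @param thresholds A [classification_thresholds()] object.
#' @return Character vector in `c("decreased", "increased", "unchanged")`.
#' @examples
#' classify_change(0.41, 0.38, 0.44)  # decreased
#' classify_change(0.55, 0.43, 0.71)  # unchanged: upper bound crosses 0.5
#' @export
classify_change <- function(point, low, high,
                            thresholds = classification_thresholds()) {
  if (any(is.na(point) | is.na(low) | is.na(high)) ||
      any(low > point | point > high)) {
    abort_validation("Need finite bounds with low <= point <= high.")
  }
  dec <- point < thresholds$decrease & high <= thresholds$decrease
  inc <- point > thresholds$increase & low >= thresholds$increase
  dplyr::case_when(dec ~ "decreased", inc ~ "increased", .default = "unchanged")
}

#' Fold difference between two isoforms of the same sample
#'
#' Computed as `2^n` where `n` is the Ct difference between the minor (less
#' expressed, higher Ct) and the major transcript.
#'
#' @param ct_minor,ct_major Detected Ct values (cycles).
#' @return `2^(ct_minor - ct_major)`; `>= 1` when the minor transcript indeed
#'   has the higher Ct.
#' @examples
#' isoform_fold_difference(27.32, 24.0)
#' @export
isoform_fold_difference <- function(ct_minor, ct_major) {
  if (anyNA(ct_minor) || anyNA(ct_major)) {
    abort_missing_assay("Both Ct values must be detected.")
  }
  2^(ct_minor - ct_major)
}

#' Expression profile: relative expression per group x tissue x target
#'
#' Runs the full ddCt path for every disease group against the control group
#' of the same tissue: per-sample dCt for each reference gene, group ddCt
#' with its standard deviation, `2^-(ddCt +/- SD)` bounds per reference,
#' arithmetic averaging over references, and the 0.5 / 1.5 classification.
#'
#' @param measurements Ct tibble as from [read_ct_table()].
#' @param samples Sample metadata tibble as from [read_sample_metadata()];
#'   must cover every `sample_id` in `measurements`.
#' @param panel An [assay_panel()] naming targets and references.
#' @param thresholds A [classification_thresholds()] object.
#' @param control_group Group label of the controls (default `"CTRL"`).
#' @return Tibble with one row per group x tissue x target: `point`, `low`,
#'   `high`, `log2_point` (for plotting on the customary log scale),
#'   `references_used`, `n_case`, `n_control` and `classification`.
#' @export
expression_profile <- function(measurements, samples, panel,
                               thresholds = classification_thresholds(),
                               control_group = "CTRL") {
  missing_meta <- setdiff(unique(measurements$sample_id), samples$sample_id)
  if (length(missing_meta) > 0L) {
    abort_validation(sprintf(
      "No metadata for sample(s): %s",
      paste(head(missing_meta, 5L), collapse = ", ")
    ))
  }
  meta <- dplyr::select(samples, "sample_id", "tissue", "group")
  tissues <- unique(meta$tissue[meta$sample_id %in% measurements$sample_id])
  rows <- list()

  for (tis in tissues) {
    ids <- meta$sample_id[meta$tissue == tis]
    meas_t <- dplyr::filter(measurements, .data$sample_id %in% ids)
    groups_here <- unique(meta$group[meta$sample_id %in% meas_t$sample_id])
    control_ids <- meta$sample_id[meta$tissue == tis &
                                    meta$group == control_group]
    if (length(intersect(control_ids, meas_t$sample_id)) == 0L) {
      abort_insufficient_data(sprintf(
        "No %s samples with measurements for tissue `%s`.",
        control_group, tis
      ))
    }
    case_groups <- setdiff(groups_here, control_group)

    for (target in panel$targets) {
      dct_by_ref <- lapply(panel$references, function(ref) {
        delta_ct_table(meas_t, target, ref)
      })
      names(dct_by_ref) <- panel$references

      for (grp in case_groups) {
        grp_ids <- meta$sample_id[meta$tissue == tis & meta$group == grp]
        per_ref <- lapply(panel$references, function(ref) {
          dct <- dct_by_ref[[ref]]
          est <- compute_group_ddct(
            dct$delta_ct[dct$sample_id %in% grp_ids],
            dct$delta_ct[dct$sample_id %in% control_ids]
          )
          re <- relative_expression(est$ddct, est$sd)
          re$reference <- ref
          re$n_case <- est$n_case
          re$n_control <- est$n_control
          re
        })
        per_ref <- dplyr::bind_rows(per_ref)
        combined <- combine_references(per_ref)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = grp,
          tissue = tis,
          target = target,
          point = combined$point,
          low = combined$low,
          high = combined$high,
          log2_point = log2(combined$point),
          references_used = combined$references_used,
          n_case = min(per_ref$n_case),
          n_control = min(per_ref$n_control),
          classification = classify_change(
            combined$point, combined$low, combined$high, thresholds
          )
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
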