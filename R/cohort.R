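# Cohort stratification and per-patient expression: patients are compared
# individually against the control-group mean dCt, split by age at disease
# onset or disease duration, and tested with Welch t-tests and
# expression-covariate regression on the log2 scale.

#' Per-patient relative expression against the control-group mean
#'
#' Each patient's dCt is compared to the mean dCt of the entire control
#' group: `rq = 2^-(dCt_patient - mean(dCt_controls))`. For a control
#' individual evaluated against its own group, the geometric mean of the rq
#' values across the group is exactly 1 (single reference gene).
#'
#' @param patient_dct Numeric vector of per-patient dCt values.
#' @param control_dcts Numeric vector of control dCt values (non-empty).
#' @return Numeric vector of fold changes, one per patient.
#' @examples
#' per_patient_expression(c(5, 6), c(5, 5, 5))
#' @export
per_patient_expression <- function(patient_dct, control_dcts) {
  control_dcts <- control_dcts[!is.na(control_dcts)]
  if (length(control_dcts) < 1L) {
    abort_insufficient_data("The control dCt list must be non-empty.")
  }
  2^(-(patient_dct - mean(control_dcts)))
}

#' Per-patient expression table for one target
#'
#' Computes each patient's rq per reference gene via
#' [per_patient_expression()], averages arithmetically over the references,
#' and joins the clinical covariates needed for stratified analyses.
#'
#' @param measurements Ct tibble as from [read_ct_table()].
#' @param samples Sample metadata tibble; the control group supplies the
#'   baseline dCt mean.
#' @param panel An [assay_panel()].
#' @param target Target assay name (must be in `panel$targets`).
#' @param control_group Control group label (default `"CTRL"`).
#' @return Tibble with `sample_id`, `subject_id`, `group`, `target`, `rq`,
#'   and covariates `age_years`, `sex`, `age_at_onset_years`,
#'   `disease_duration_years`.
#' @export
patient_expression_table <- function(measurements, samples, panel, target,
                                     control_group = "CTRL") {
  if (!target %in% panel$targets) {
    abort_validation(sprintf("`%s` is not a target of the panel.", target))
  }
  control_ids <- samples$sample_id[samples$group == control_group]
  per_ref <- lapply(panel$references, function(ref) {
    dct <- delta_ct_table(measurements, target, ref)
    ctrl <- dct$delta_ct[dct$sample_id %in% control_ids]
    if (length(ctrl) < 1L) {
      abort_insufficient_data(sprintf(
        "No control dCt available for reference `%s`.", ref
      ))
    }
    tibble::tibble(
      sample_id = dct$sample_id,
      rq = per_patient_expression(dct$delta_ct, ctrl)
    )
  })
  ref_wide <- Reduce(function(a, b) {
    dplyr::inner_join(a, b, by = "sample_id")
  }, per_ref)
  rq_mat <- as.matrix(ref_wide[, -1L, drop = FALSE])

  out <- tibble::tibble(
    sample_id = ref_wide$sample_id,
    target = target,
    rq = rowMeans(rq_mat)
  )
  dplyr::inner_join(
    out,
    dplyr::select(
      samples, "sample_id", "subject_id", "group", "age_years", "sex",
      "age_at_onset_years", "disease_duration_years"
    ),
    by = "sample_id"
  )
}

#' Stratify patients by age at onset or disease duration
#'
#' Age at onset: `early` iff onset is at `cut` years (default 65) or before,
#' `late` from `cut + 1` on. Disease duration: `short` iff strictly less
#' than `cut` years (default 6), `long` at `cut` or more. Patients missing
#' the stratification variable are dropped with a warning; over the
#' remaining patients the split is exhaustive and mutually exclusive.
#'
#' @param patients Sample metadata tibble (typically disease groups only).
#' @param variable `"age_at_onset"` or `"disease_duration"`.
#' @param cut Cutpoint in years; defaults to 65 for onset, 6 for duration.
#' @return The input tibble, less rows with a missing variable, with an
#'   added `stratum` column.
#' @export
stratify <- function(patients,
                     variable = c("age_at_onset", "disease_duration"),
                     cut = NULL) {
  variable <- match.arg(variable)
  col <- paste0(variable, "_years")
  if (is.null(cut)) cut <- if (variable == "age_at_onset") 65 else 6
  if (!is_scalar_number(cut) || cut <= 0) {
    abort_validation("`cut` must be a positive number.")
  }
  values <- patients[[col]]
  if (anyNA(values)) {
    warn(sprintf(
      "%d patient(s) with missing %s dropped from stratification.",
      sum(is.na(values)), col
    ))
  }
  kept <- patients[!is.na(values), , drop = FALSE]
  v <- kept[[col]]
  kept$stratum <- if (variable == "age_at_onset") {
    ifelse(v <= cut, "early", "late")
  } else {
    ifelse(v < cut, "short", "long")
  }
  attr(kept, "stratum_definition") <- list(variable = variable, cut = cut)
  kept
}

#' Welch t-test between two strata
#'
#' Two-sided unequal-variance (Welch) t-test, the safer default when group
#' sizes differ. When both groups have zero variance: equal means give
#' `t = 0, p = 1` by convention; unequal means give an infinite statistic
#' and `p = 0`.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 non-missing
#'   values.
#' @return A list with `t_statistic`, `p_value`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`.
#' @export
compare_strata <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L) {
    abort_insufficient_data("Each stratum needs at least 2 values.")
  }
  base <- list(
    n_a = length(values_a), n_b = length(values_b),
    mean_a = mean(values_a), mean_b = mean(values_b)
  )
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(c(list(t_statistic = 0, p_value = 1), base))
    }
    return(c(
      list(
        t_statistic = sign(mean(values_a) - mean(values_b)) * Inf,
        p_value = 0
      ),
      base
    ))
  }
  tt <- t.test(values_a, values_b, var.equal = FALSE)
  c(
    list(
      t_statistic = unname(tt$statistic),
      p_value = tt$p.value
    ),
    base
  )
}

#' Regress expression on a clinical covariate
#'
#' Ordinary least squares of `log2(rq)` on the covariate (expression changes
#' are multiplicative, so the log scale is the default; set
#' `log_scale = FALSE` to regress the raw fold change). Returns the slope
#' per year, intercept, the (signed) correlation coefficient and the
#' two-sided p-value for the slope.
#'
#' @param rq Positive per-patient fold changes.
#' @param covariate Covariate values, same length (years).
#' @param log_scale Regress `log2(rq)` (default) or raw `rq`.
#' @return An object of class `regression_result`: `slope`, `intercept`,
#'   `r`, `p_value`, `n`.
#' @export
regress_expression <- function(rq, covariate, log_scale = TRUE) {
  keep <- !is.na(rq) & !is.na(covariate)
  rq <- rq[keep]
  covariate <- covariate[keep]
  if (length(rq) < 3L) {
    abort_insufficient_data("Regression needs at least 3 patients.")
  }
  if (any(rq <= 0)) {
    abort_validation("`rq` must be positive.")
  }
  if (length(unique(covariate)) < 2L) {
    abort_degenerate_design("The covariate is constant across patients.")
  }
  y <- if (log_scale) log2(rq) else rq
  fit <- lm(y ~ covariate)
  coefs <- summary(fit)$coefficients
  r <- if (sd(y) == 0) 0 else stats::cor(covariate, y)
  structure(
    list(
      slope = unname(coefs[2L, 1L]),
      intercept = unname(coefs[1L, 1L]),
      r = r,
      p_value = unname(coefs[2L, 4L]),
      n = length(y),
      log_scale = log_scale
    ),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> slope %.4g/year, r %.3f, p %.3g (n = %d, %s scale)\n",
    x$slope, x$r, x$p_value, x$n, if (x$log_scale) "log2" else "linear"
  ))
  invisible(x)
}

#' Stratified expression analysis for one target
#'
#' Splits the patients of `case_groups` by onset or duration, estimates each
#' stratum's relative expression against the controls through the standard
#' ddCt path (per-reference, then averaged), and contrasts the two strata
#' directly: the stratum with the larger point estimate serves as the
#' baseline, so the between-stratum estimate is the fold change of the
#' lower-expressing stratum and is classified with the same 0.5 / 1.5 rule.
#' The clinical make-up of the strata is summarized with a Welch t-test on
#' the complementary covariate (duration when stratifying by onset, and
#' vice versa).
#'
#' @param measurements Ct tibble.
#' @param samples Sample metadata tibble.
#' @param panel An [assay_panel()].
#' @param target Target assay name.
#' @param variable `"age_at_onset"` or `"disease_duration"`.
#' @param cut Cutpoint in years (see [stratify()]).
#' @param case_groups Group labels to stratify; default: every non-control
#'   group present.
#' @param thresholds A [classification_thresholds()] object.
#' @param control_group Control group label.
#' @return An object of class `stratified_comparison`: `strata` (per-stratum
#'   n / mean / range of the complementary covariate), `clinical_test`
#'   (Welch t-test on that covariate), `per_stratum` (relative expression of
#'   each stratum vs controls), and `between` (the stratum-vs-stratum
#'   estimate with its baseline).
#' @export
stratified_expression <- function(measurements, samples, panel, target,
                                  variable = c("age_at_onset",
                                               "disease_duration"),
                                  cut = NULL,
                                  case_groups = NULL,
                                  thresholds = classification_thresholds(),
                                  control_group = "CTRL") {
  variable <- match.arg(variable)
  if (is.null(case_groups)) {
    case_groups <- setdiff(unique(samples$group), control_group)
  }
  patients <- dplyr::filter(samples, .data$group %in% case_groups)
  if (nrow(patients) == 0L) {
    abort_insufficient_data("No patients in the requested case groups.")
  }
  strat <- stratify(patients, variable, cut)
  levels <- if (variable == "age_at_onset") {
    c("early", "late")
  } else {
    c("short", "long")
  }
  by_stratum <- split(strat$sample_id, factor(strat$stratum, levels))
  if (any(lengths(by_stratum) == 0L)) {
    abort_insufficient_data(sprintf(
      "Empty stratum: %s.",
      paste(levels[lengths(by_stratum) == 0L], collapse = ", ")
    ))
  }
  control_ids <- samples$sample_id[samples$group == control_group]

  dct_by_ref <- lapply(panel$references, function(ref) {
    delta_ct_table(measurements, target, ref)
  })
  names(dct_by_ref) <- panel$references

  stratum_estimate <- function(case_ids, baseline_ids) {
    per_ref <- dplyr::bind_rows(lapply(panel$references, function(ref) {
      dct <- dct_by_ref[[ref]]
      est <- compute_group_ddct(
        dct$delta_ct[dct$sample_id %in% case_ids],
        dct$delta_ct[dct$sample_id %in% baseline_ids]
      )
      re <- relative_expression(est$ddct, est$sd)
      re$reference <- ref
      re
    }))
    combined <- combine_references(per_ref)
    combined$classification <- classify_change(
      combined$point, combined$low, combined$high, thresholds
    )
    combined
  }

  per_stratum <- dplyr::bind_rows(lapply(levels, function(lv) {
    est <- stratum_estimate(by_stratum[[lv]], control_ids)
    tibble::tibble(
      stratum = lv, n = length(by_stratum[[lv]]),
      point = est$point, low = est$low, high = est$high,
      references_used = est$references_used,
      classification = est$classification
    )
  }))

  # Stratum-vs-stratum contrast: baseline is the higher-expressing stratum.
  baseline_level <- per_stratum$stratum[which.max(per_stratum$point)]
  case_level <- setdiff(levels, baseline_level)
  between_est <- stratum_estimate(
    by_stratum[[case_level]], by_stratum[[baseline_level]]
  )
  between <- tibble::tibble(
    case_stratum = case_level,
    baseline_stratum = baseline_level,
    point = between_est$point, low = between_est$low,
    high = between_est$high,
    references_used = between_est$references_used,
    classification = between_est$classification
  )

  other_col <- if (variable == "age_at_onset") {
    "disease_duration_years"
  } else {
    "age_at_onset_years"
  }
  strata_summary <- strat |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[other_col]], na.rm = TRUE),
      min = suppressWarnings(min(.data[[other_col]], na.rm = TRUE)),
      max = suppressWarnings(max(.data[[other_col]], na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::mutate(variable = other_col, .before = 1L)
  clinical_test <- tryCatch(
    compare_strata(
      strat[[other_col]][strat$stratum == levels[1L]],
      strat[[other_col]][strat$stratum == levels[2L]]
    ),
    ctquant_error = function(e) NULL
  )

  structure(
    list(
      target = target,
      variable = variable,
      cut = attr(strat, "stratum_definition")$cut,
      strata = strata_summary,
      clinical_test = clinical_test,
      per_stratum = per_stratum,
      between = between
    ),
    class = "stratified_comparison"
  )
}

#' @export
print.stratified_comparison <- function(x, ...) {
  cat(sprintf(
    "<stratified_comparison> %s by %s (cut %g)\n", x$target, x$variable, x$cut
  ))
  for (i in seq_len(nrow(x$per_stratum))) {
    row <- x$per_stratum[i, ]
    cat(sprintf(
      "  %s (n = %d): %.2f (%.2f-%.2f) %s\n",
      row$stratum, row$n, row$point, row$low, row$high, row$classification
    ))
  }
  b <- x$between
  cat(sprintf(
    "  %s vs %s: %.2f (%.2f-%.2f) %s\n",
    b$case_stratum, b$baseline_stratum, b$point, b$low, b$high,
    b$classification
  ))
  if (!is.null(x$clinical_test)) {
    cat(sprintf(
      "  %s across strata: t = %.3f, p = %.3g\n",
      x$strata$variable[1L], x$clinical_test$t_statistic,
      x$clinical_test$p_value
    ))
  }
  invisible(x)
}

#' Flatten a stratified comparison into a tidy tibble
#'
#' One row per stratum estimate plus one for the between-stratum contrast;
#' suitable for [write_report()].
#'
#' @param x A `stratified_comparison`.
#' @return A tibble.
#' @export
as_comparison_table <- function(x) {
  stopifnot(inherits(x, "stratified_comparison"))
  per <- dplyr::mutate(
    x$per_stratum,
    variable = x$variable, target = x$target, contrast = "vs_control",
    .before = 1L
  )
  btw <- tibble::tibble(
    variable = x$variable, target = x$target, contrast = "between_strata",
    stratum = paste(x$between$case_stratum, "vs", x$between$baseline_stratum),
    n = NA_integer_,
    point = x$between$point, low = x$between$low, high = x$between$high,
    references_used = x$between$references_used,
    classification = x$between$classification
  )
  dplyr::bind_rows(per, btw)
}
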