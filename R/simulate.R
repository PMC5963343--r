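# Synthetic Ct-data generation with known ground truth.
#
# The generative model mirrors the quantification model it is used to test:
# Ct(sample, assay, run, rep) = baseline_ct[assay] - log2(fold) +
#   run_offset[run] + N(0, replicate_sd), run_offset ~ N(0, run_sd).
# Reference-gene folds are fixed at 1, and cohort Ct values use ideal
# base-2 amplification; efficiency deviations enter only the dilution-series
# generator, matching the pipeline's equal-efficiency assumption.

default_baseline_ct <- c(
  GBAtv1 = 26, GBAtv2 = 24, GBAtv5 = 28,
  ACTB = 19, GUSB = 25, PBGD = 26
)

# Truncated-normal draw via the inverse-CDF on a restricted uniform, so each
# value consumes exactly one RNG draw (keeps generation reproducible and
# order-stable).
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  p <- stats::runif(
    n, stats::pnorm(lower, mean, sd), stats::pnorm(upper, mean, sd)
  )
  stats::qnorm(p, mean, sd)
}

param_for_group <- function(param, group) {
  if (length(param) == 1L && is.null(names(param))) return(unname(param))
  if (!group %in% names(param)) {
    abort_validation(sprintf("No value of a per-group parameter for `%s`.",
                             group))
  }
  unname(param[[group]])
}

#' Build a simulation configuration
#'
#' Defines the cohort shape (groups and sizes), tissues, assay panel, true
#' per-(group, tissue, target) fold changes versus control, Ct noise levels,
#' run structure and, optionally, a linear covariate link from age at onset
#' or disease duration to log2 expression.
#'
#' @param groups Named integer vector of subjects per group; must include
#'   `CTRL`.
#' @param tissues Character vector of tissues; every subject contributes one
#'   sample per tissue.
#' @param panel An [assay_panel()].
#' @param cohort_arm `"brain"` or `"blood"`.
#' @param true_fold Tibble with columns `group`, `tissue`, `target`, `fold`
#'   giving true fold changes vs control; unlisted combinations default to 1.
#' @param baseline_ct Named vector of baseline Ct per assay (cycles); must
#'   cover every assay in the panel.
#' @param replicate_sd Technical replicate noise in Ct cycles (default 0.25).
#' @param run_sd Between-run offset SD in cycles (default 0.15).
#' @param n_runs Independent runs per assay (default 2).
#' @param n_replicates Technical replicates per run (default 2, minimum 2).
#' @param efficiency Named vector of per-assay amplification efficiencies
#'   used by the dilution-series generator (default 1 for all).
#' @param covariate_model Optional list with `target`, `covariate`
#'   (`"age_at_onset"` or `"disease_duration"`), `slope` (per year on log2
#'   expression), `center` (years), `noise_sd` (log2 units, default 0) and
#'   optionally `groups` (which groups the link applies to).
#' @param onset_mean,onset_sd Age-at-onset distribution (years); may be a
#'   named per-group vector.
#' @param duration_mean,duration_sd Disease-duration distribution (years);
#'   may be a named per-group vector.
#' @param rin_mean,rin_sd RIN distribution, truncated to [1, 10].
#' @param seed Optional integer; when set, [simulate_cohort()] is fully
#'   reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(groups,
                              tissues,
                              panel,
                              cohort_arm = "blood",
                              true_fold = NULL,
                              baseline_ct = default_baseline_ct,
                              replicate_sd = 0.25,
                              run_sd = 0.15,
                              n_runs = 2L,
                              n_replicates = 2L,
                              efficiency = NULL,
                              covariate_model = NULL,
                              onset_mean = 67, onset_sd = 5,
                              duration_mean = 6, duration_sd = 3,
                              rin_mean = 7.8, rin_sd = 0.8,
                              seed = NULL) {
  if (is.null(names(groups)) || any(groups < 1L)) {
    abort_validation("`groups` must be a named vector of sizes >= 1.")
  }
  if (!"CTRL" %in% names(groups)) {
    abort_validation("The CTRL group is required.")
  }
  if (!inherits(panel, "assay_panel")) {
    abort_validation("`panel` must be an assay_panel.")
  }
  assays <- c(panel$targets, panel$references)
  missing_baseline <- setdiff(assays, names(baseline_ct))
  if (length(missing_baseline) > 0L) {
    abort_validation(sprintf(
      "`baseline_ct` lacks assay(s): %s",
      paste(missing_baseline, collapse = ", ")
    ))
  }
  if (replicate_sd < 0 || run_sd < 0) {
    abort_validation("Noise SDs must be non-negative.")
  }
  if (n_runs < 1L || n_replicates < 2L) {
    abort_validation("Need n_runs >= 1 and n_replicates >= 2.")
  }
  if (is.null(efficiency)) {
    efficiency <- setNames(rep(1, length(assays)), assays)
  }
  if (any(efficiency <= 0)) {
    abort_validation("Efficiencies must be positive.")
  }

  full_grid <- tidyr::expand_grid(
    group = setdiff(names(groups), "CTRL"),
    tissue = tissues,
    target = panel$targets
  )
  full_grid$fold <- 1
  if (!is.null(true_fold)) {
    need <- c("group", "tissue", "target", "fold")
    if (!all(need %in% names(true_fold))) {
      abort_validation(
        "`true_fold` needs columns group, tissue, target, fold."
      )
    }
    if (any(true_fold$fold <= 0)) {
      abort_validation("True folds must be positive.")
    }
    key_full <- paste(full_grid$group, full_grid$tissue, full_grid$target)
    key_user <- paste(true_fold$group, true_fold$tissue, true_fold$target)
    unknown <- !key_user %in% key_full
    if (any(unknown)) {
      abort_validation(sprintf(
        "`true_fold` rows outside the cohort design: %s",
        paste(key_user[unknown], collapse = "; ")
      ))
    }
    idx <- match(key_full, key_user)
    full_grid$fold[!is.na(idx)] <- true_fold$fold[idx[!is.na(idx)]]
  }

  if (!is.null(covariate_model)) {
    ok <- is.list(covariate_model) &&
      all(c("target", "covariate", "slope", "center") %in%
            names(covariate_model)) &&
      covariate_model$covariate %in% c("age_at_onset", "disease_duration") &&
      covariate_model$target %in% panel$targets
    if (!ok) {
      abort_validation(
        "`covariate_model` needs target, covariate, slope, center."
      )
    }
    covariate_model$noise_sd <- covariate_model$noise_sd %||% 0
    if (covariate_model$noise_sd < 0) {
      abort_validation("`covariate_model$noise_sd` must be non-negative.")
    }
  }
  if (any(c(onset_mean, duration_mean) < 0)) {
    abort_validation("Covariate means must be non-negative.")
  }

  structure(
    list(
      groups = groups, tissues = tissues, panel = panel,
      cohort_arm = cohort_arm, true_fold = full_grid,
      baseline_ct = baseline_ct, replicate_sd = replicate_sd,
      run_sd = run_sd, n_runs = as.integer(n_runs),
      n_replicates = as.integer(n_replicates), efficiency = efficiency,
      covariate_model = covariate_model,
      onset_mean = onset_mean, onset_sd = onset_sd,
      duration_mean = duration_mean, duration_sd = duration_sd,
      rin_mean = rin_mean, rin_sd = rin_sd, seed = seed
    ),
    class = "simulation_config"
  )
}

#' Default blood-arm cohort configuration
#'
#' Emulates a two-disease blood cohort (20 DLB, 26 PD, 17 controls) with the
#' GBA isoform panel normalized against ACTB and PBGD. By default GBAtv1 is
#' suppressed to 0.41 of control levels in DLB and 0.35 in PD while GBAtv2
#' and GBAtv5 are unchanged; age-at-onset means are 68 (DLB) and 65.3 (PD)
#' years, disease durations 5.9 and 6.5 years.
#'
#' @param seed Optional integer seed.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
blood_cohort_config <- function(seed = NULL, ...) {
  defaults <- list(
    groups = c(DLB = 20L, PD = 26L, CTRL = 17L),
    tissues = "blood",
    panel = blood_panel(),
    cohort_arm = "blood",
    true_fold = tibble::tibble(
      group = c("DLB", "PD"),
      tissue = "blood",
      target = "GBAtv1",
      fold = c(0.41, 0.35)
    ),
    onset_mean = c(DLB = 68, PD = 65.3), onset_sd = 4,
    duration_mean = c(DLB = 5.9, PD = 6.5), duration_sd = 2.5,
    seed = seed
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(simulation_config, defaults)
}

#' Default brain-arm cohort configuration
#'
#' Emulates the brain cohort (8 pDLB, 12 cDLB, 12 PDND, 13 PDD, 17 controls)
#' across temporal cortex and caudate nucleus with ACTB and GUSB as
#' references. Default true folds encode the suppressed-isoform pattern of
#' the disease groups: GBAtv1 at 0.38 (pDLB) and 0.27 (cDLB) in temporal
#' cortex with GBAtv5 at 0.35 in pDLB, and in the caudate nucleus GBAtv1 at
#' 0.41 (pDLB, PDD) and 0.44 (cDLB) with GBAtv5 at 0.36 in PDD.
#'
#' @inheritParams blood_cohort_config
#' @return A `simulation_config`.
#' @export
brain_cohort_config <- function(seed = NULL, ...) {
  folds <- tibble::tribble(
    ~group, ~tissue,           ~target,  ~fold,
    "pDLB", "temporal_cortex", "GBAtv1", 0.38,
    "cDLB", "temporal_cortex", "GBAtv1", 0.27,
    "pDLB", "temporal_cortex", "GBAtv5", 0.35,
    "PDD",  "caudate_nucleus", "GBAtv1", 0.41,
    "pDLB", "caudate_nucleus", "GBAtv1", 0.41,
    "cDLB", "caudate_nucleus", "GBAtv1", 0.44,
    "PDD",  "caudate_nucleus", "GBAtv5", 0.36
  )
  defaults <- list(
    groups = c(pDLB = 8L, cDLB = 12L, PDND = 12L, PDD = 13L, CTRL = 17L),
    tissues = c("temporal_cortex", "caudate_nucleus"),
    panel = brain_panel(),
    cohort_arm = "brain",
    true_fold = folds,
    onset_mean = 68, onset_sd = 5,
    duration_mean = 7, duration_sd = 3,
    seed = seed
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(simulation_config, defaults)
}

#' Simulate clinical covariates for one disease group
#'
#' Age at onset and disease duration are drawn from truncated normal
#' distributions, age at sampling/death is onset + duration, and sex is
#' drawn uniformly. Controls (`group = "CTRL"`) receive age only.
#'
#' @param n Number of subjects.
#' @param group Group label.
#' @param onset_mean,onset_sd,duration_mean,duration_sd Distribution
#'   parameters in years.
#' @return Tibble with `age_at_onset_years`, `disease_duration_years`,
#'   `age_years`, `sex`.
#' @export
simulate_covariates <- function(n, group, onset_mean = 67, onset_sd = 5,
                                duration_mean = 6, duration_sd = 3) {
  if (n < 1L) abort_validation("`n` must be at least 1.")
  if (duration_mean < 0 || onset_mean < 0) {
    abort_validation("Covariate means must be non-negative.")
  }
  if (group == "CTRL") {
    return(tibble::tibble(
      age_at_onset_years = NA_real_,
      disease_duration_years = NA_real_,
      age_years = round(rtrunc_norm(n, 72, 6, 55, 90), 1L),
      sex = sample(c("M", "F"), n, replace = TRUE)
    ))
  }
  onset <- round(rtrunc_norm(n, onset_mean, onset_sd, 40, 90), 1L)
  duration <- round(rtrunc_norm(n, duration_mean, duration_sd, 0.5, 20), 1L)
  tibble::tibble(
    age_at_onset_years = onset,
    disease_duration_years = duration,
    age_years = onset + duration,
    sex = sample(c("M", "F"), n, replace = TRUE)
  )
}

#' Simulate a full qPCR cohort with known ground truth
#'
#' Generates sample metadata, long-format Ct measurements and the ground
#' truth they were produced from. Ct values follow
#' `baseline_ct[assay] - log2(fold) + run_offset + replicate noise`; the
#' reference genes have fold 1 everywhere, and patient folds optionally
#' depend linearly (on the log2 scale) on age at onset or disease duration
#' through `config$covariate_model`. With `config$seed` set, the output is
#' identical across calls.
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_cohort` with `samples` (metadata
#'   tibble), `measurements` (Ct tibble) and `truth` (list: `sample_fold`
#'   with the realized per-sample per-target folds and dCt offsets,
#'   `group_fold` with the design folds, `covariate_model`).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort_validation("`config` must be a simulation_config.")
  }
  if (!is.null(config$seed)) {
    return(withr::with_seed(config$seed, simulate_cohort_impl(config)))
  }
  simulate_cohort_impl(config)
}

simulate_cohort_impl <- function(config) {
  panel <- config$panel
  assays <- c(panel$targets, panel$references)
  cm <- config$covariate_model

  subjects <- dplyr::bind_rows(lapply(names(config$groups), function(grp) {
    n <- config$groups[[grp]]
    cov <- if (grp == "CTRL") {
      simulate_covariates(n, grp)
    } else {
      simulate_covariates(
        n, grp,
        onset_mean = param_for_group(config$onset_mean, grp),
        onset_sd = param_for_group(config$onset_sd, grp),
        duration_mean = param_for_group(config$duration_mean, grp),
        duration_sd = param_for_group(config$duration_sd, grp)
      )
    }
    cov$subject_id <- sprintf("%s_%02d", grp, seq_len(n))
    cov$group <- grp
    cov
  }))

  samples <- tidyr::expand_grid(
    subject_id = subjects$subject_id, tissue = config$tissues
  ) |>
    dplyr::left_join(subjects, by = "subject_id") |>
    dplyr::mutate(
      sample_id = paste(.data$subject_id, .data$tissue, sep = "."),
      cohort_arm = config$cohort_arm,
      post_mortem_time_hours = NA_real_,
      rin = NA_real_
    ) |>
    dplyr::select(
      "sample_id", "subject_id", "cohort_arm", "tissue", "group",
      "age_years", "sex", "age_at_onset_years", "disease_duration_years",
      "post_mortem_time_hours", "rin"
    )
  samples$rin <- round(
    rtrunc_norm(nrow(samples), config$rin_mean, config$rin_sd, 1, 10), 1L
  )
  if (config$cohort_arm == "brain") {
    samples$post_mortem_time_hours <- round(
      rtrunc_norm(nrow(samples), 9, 4, 2, 24), 1L
    )
  }

  # Realized fold per sample x target: design fold times the covariate link.
  sample_fold <- tidyr::expand_grid(
    sample_id = samples$sample_id, target = panel$targets
  ) |>
    dplyr::left_join(
      dplyr::select(samples, "sample_id", "group", "tissue",
                    "age_at_onset_years", "disease_duration_years"),
      by = "sample_id"
    ) |>
    dplyr::left_join(config$true_fold,
                     by = c("group", "tissue", "target")) |>
    dplyr::mutate(fold = dplyr::coalesce(.data$fold, 1))
  if (!is.null(cm)) {
    cov_col <- paste0(cm$covariate, "_years")
    grp_ok <- if (is.null(cm$groups)) {
      rep(TRUE, nrow(sample_fold))
    } else {
      sample_fold$group %in% cm$groups
    }
    applies <- sample_fold$target == cm$target &
      sample_fold$group != "CTRL" & grp_ok &
      !is.na(sample_fold[[cov_col]])
    link_noise <- rnorm(nrow(sample_fold), 0, cm$noise_sd)
    shift <- cm$slope * (sample_fold[[cov_col]] - cm$center) + link_noise
    sample_fold$fold[applies] <-
      sample_fold$fold[applies] * 2^(shift[applies])
  }
  sample_fold <- dplyr::select(
    sample_fold, "sample_id", "target", "fold"
  ) |>
    dplyr::mutate(true_dct_offset = -log2(.data$fold))

  run_ids <- sprintf("run%d", seq_len(config$n_runs))
  run_offsets <- setNames(rnorm(config$n_runs, 0, config$run_sd), run_ids)

  grid <- tidyr::expand_grid(
    sample_id = samples$sample_id,
    assay = assays,
    run_id = run_ids,
    replicate = seq_len(config$n_replicates)
  )
  fold_lookup <- setNames(
    sample_fold$fold, paste(sample_fold$sample_id, sample_fold$target)
  )
  fold <- unname(fold_lookup[paste(grid$sample_id, grid$assay)])
  fold[is.na(fold)] <- 1  # reference genes
  ct <- unname(config$baseline_ct[grid$assay]) - log2(fold) +
    unname(run_offsets[grid$run_id]) +
    rnorm(nrow(grid), 0, config$replicate_sd)
  measurements <- tibble::tibble(
    sample_id = grid$sample_id,
    assay = grid$assay,
    run_id = grid$run_id,
    replicate = as.integer(grid$replicate),
    ct = ct
  )

  structure(
    list(
      samples = samples,
      measurements = measurements,
      truth = list(
        sample_fold = sample_fold,
        group_fold = config$true_fold,
        covariate_model = cm
      )
    ),
    class = "simulated_cohort"
  )
}

#' Simulate a serial-dilution standard-curve series
#'
#' Ct at dilution `d` is `baseline_ct - log10(d) / log10(1 + efficiency)`
#' plus optional cycle noise, so fitting the series with
#' [fit_standard_curve()] recovers the generating efficiency exactly in the
#' noiseless case (slope `-3.321928` for `E = 1`).
#'
#' @param assay Assay name carried into the output.
#' @param efficiency True amplification efficiency (> 0; 1 = doubling).
#' @param baseline_ct Ct of the undiluted template (cycles).
#' @param n_points Number of dilution points (>= 3).
#' @param step_log10 Dilution step in log10 units (default 1 = 10-fold).
#' @param noise_sd Ct noise SD in cycles (default 0).
#' @param run_id Run identifier.
#' @param seed Optional integer seed.
#' @return Tibble with `assay`, `run_id`, `log10_dilution`, `ct`.
#' @export
simulate_dilution_series <- function(assay = "GBAtv1", efficiency = 1,
                                     baseline_ct = 25, n_points = 5L,
                                     step_log10 = 1, noise_sd = 0,
                                     run_id = "run1", seed = NULL) {
  if (!is_scalar_number(efficiency) || efficiency <= 0) {
    abort_validation("`efficiency` must be positive.")
  }
  if (n_points < 3L) {
    abort_validation("A dilution series needs at least 3 points.")
  }
  if (step_log10 <= 0 || noise_sd < 0) {
    abort_validation("`step_log10` must be positive and `noise_sd` >= 0.")
  }
  gen <- function() {
    log10_dilution <- -(seq_len(n_points) - 1L) * step_log10
    tibble::tibble(
      assay = assay,
      run_id = run_id,
      log10_dilution = log10_dilution,
      ct = baseline_ct - log10_dilution / log10(1 + efficiency) +
        rnorm(n_points, 0, noise_sd)
    )
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}

#' Simulate an accelerated-degradation time-course
#'
#' Relative transcript amount at incubation time `t` is `2^(rate * t)` with
#' optional multiplicative log2 noise (time 0 is anchored exactly at 1), and
#' the RIN track declines monotonically with incubation time.
#'
#' @param rates Named numeric vector of per-minute log2 decay rates
#'   (all `<= 0`), one per assay.
#' @param timepoints_min Incubation times in minutes (default
#'   `c(0, 15, 30, 60, 120, 240)`).
#' @param noise_sd Log2-scale noise SD (default 0).
#' @param rin_start Starting RIN (default 8).
#' @param seed Optional integer seed.
#' @return Tibble with `assay`, `time_min`, `relative_amount`, `rin`.
#' @export
simulate_degradation_experiment <- function(rates,
                                            timepoints_min =
                                              c(0, 15, 30, 60, 120, 240),
                                            noise_sd = 0,
                                            rin_start = 8,
                                            seed = NULL) {
  if (is.null(names(rates)) || length(rates) < 1L) {
    abort_validation("`rates` must be a named vector.")
  }
  if (any(rates > 0)) {
    abort_validation("Degradation rates must be <= 0.")
  }
  if (length(timepoints_min) < 3L || is.unsorted(timepoints_min,
                                                 strictly = TRUE) ||
      timepoints_min[1L] != 0) {
    abort_validation(
      "`timepoints_min` must be >= 3 strictly increasing times starting at 0."
    )
  }
  if (noise_sd < 0) abort_validation("`noise_sd` must be >= 0.")
  gen <- function() {
    out <- dplyr::bind_rows(lapply(names(rates), function(a) {
      noise <- c(0, rnorm(length(timepoints_min) - 1L, 0, noise_sd))
      tibble::tibble(
        assay = a,
        time_min = timepoints_min,
        relative_amount = 2^(rates[[a]] * timepoints_min + noise),
        rin = pmax(1, rin_start - 0.012 * timepoints_min)
      )
    }))
    out
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}
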