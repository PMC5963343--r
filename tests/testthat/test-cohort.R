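test_that("per-patient expression compares against the control-group mean", {
  expect_equal(per_patient_expression(5, c(5, 5, 5)), 1.0)
  expect_equal(per_patient_expression(6, c(5, 5, 5)), 0.5)
  expect_equal(per_patient_expression(c(4, 5, 6), c(5, 5)), c(2, 1, 0.5))
  expect_error(per_patient_expression(5, numeric(0)),
               class = "ctquant_insufficient_data_error")
})

test_that("control individuals have geometric mean rq of 1 (single reference)", {
  set.seed(501)
  for (i in 1:10) {
    ctrl_dct <- rnorm(8, 5, 0.5)
    rq <- per_patient_expression(ctrl_dct, ctrl_dct)
    expect_equal(exp(mean(log(rq))), 1, tolerance = 1e-12)
  }
})

test_that("stratification cutpoints match the clinical definitions", {
  patients <- tibble::tibble(
    sample_id = sprintf("p%d", 1:5),
    age_at_onset_years = c(65, 66, 60, 70, NA),
    disease_duration_years = c(5, 6, 2, 10, 3)
  )
  expect_warning(on <- stratify(patients, "age_at_onset"), "missing")
  expect_equal(on$stratum, c("early", "late", "early", "late"))

  du <- stratify(patients, "disease_duration")
  expect_equal(du$stratum[du$sample_id %in% c("p1", "p3", "p5")],
               c("short", "short", "short"))  # 5, 2, 3 < 6
  expect_equal(du$stratum[du$sample_id == "p2"], "long")  # exactly 6 -> long

  # Exhaustive and mutually exclusive over non-missing values.
  expect_equal(nrow(on), sum(!is.na(patients$age_at_onset_years)))
  expect_true(all(on$stratum %in% c("early", "late")))
  expect_error(stratify(patients, "age_at_onset", cut = -1),
               class = "ctquant_validation_error")
})

test_that("stratum comparison is a two-sided Welch t-test with conventions", {
  same <- compare_strata(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- compare_strata(c(0, 0, 0, 0), c(10, 10, 10, 10.0001))
  expect_lt(sep$p_value, 0.001)

  const_eq <- compare_strata(c(2, 2), c(2, 2))
  expect_equal(const_eq$p_value, 1)
  const_ne <- compare_strata(c(2, 2), c(3, 3))
  expect_equal(const_ne$p_value, 0)

  expect_error(compare_strata(5, c(1, 2)),
               class = "ctquant_insufficient_data_error")

  # p is invariant under group swap; t flips sign.
  set.seed(502)
  for (i in 1:10) {
    a <- rnorm(6)
    b <- rnorm(9, 0.5)
    ab <- compare_strata(a, b)
    ba <- compare_strata(b, a)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
    expect_equal(ab$t_statistic, -ba$t_statistic, tolerance = 1e-12)
  }
})

test_that("expression-covariate regression fits log2(rq) by OLS", {
  onset <- 60:69
  rq <- 2^(0.1 * onset - 7)
  fit <- suppressWarnings(regress_expression(rq, onset))
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, -7, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-12)

  flat <- suppressWarnings(regress_expression(rep(0.8, 10), onset))
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  expect_error(regress_expression(c(1, 2), c(60, 61)),
               class = "ctquant_insufficient_data_error")
  expect_error(regress_expression(c(1, 2, 3), c(60, 60, 60)),
               class = "ctquant_degenerate_design_error")
})

test_that("regression recovers the true slope within 2 SE in >=95% of draws", {
  # Data are generated from the linear model the regression assumes, so the
  # true sampling SE of the slope is known exactly:
  # sd(noise) / sqrt(sum((x - mean(x))^2)).
  set.seed(503)
  n_rep <- 500L
  noise_sd <- 0.4
  hits <- 0L
  for (i in seq_len(n_rep)) {
    onset <- runif(15, 55, 80)
    log2rq <- 0.1 * (onset - 65) + rnorm(15, 0, noise_sd)
    fit <- regress_expression(2^log2rq, onset)
    slope_se <- noise_sd / sqrt(sum((onset - mean(onset))^2))
    if (abs(fit$slope - 0.1) <= 2 * slope_se) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("patient expression table averages references and joins covariates", {
  cfg <- small_config(fold = 0.4, seed = 504, n_per_group = 6L,
                      replicate_sd = 0, run_sd = 0)
  sim <- simulate_cohort(cfg)
  tab <- patient_expression_table(sim$measurements, sim$samples, cfg$panel,
                                  "GBAtv1")
  expect_equal(nrow(tab), nrow(sim$samples))
  pd <- tab$rq[tab$group == "PD"]
  expect_equal(pd, rep(0.4, 6), tolerance = 1e-12)
  expect_true(all(c("age_at_onset_years", "disease_duration_years") %in%
                    names(tab)))
  expect_error(
    patient_expression_table(sim$measurements, sim$samples, cfg$panel,
                             "NOPE"),
    class = "ctquant_validation_error"
  )
})

test_that("covariate-linked simulation round-trips through regression", {
  cfg <- small_config(
    fold = 0.4, seed = 505, n_per_group = 10L,
    replicate_sd = 0, run_sd = 0,
    covariate_model = list(
      target = "GBAtv1", covariate = "age_at_onset",
      slope = 0.1, center = 65, noise_sd = 0
    )
  )
  sim <- simulate_cohort(cfg)
  tab <- patient_expression_table(sim$measurements, sim$samples, cfg$panel,
                                  "GBAtv1")
  pd <- tab[tab$group == "PD", ]
  fit <- suppressWarnings(regress_expression(pd$rq, pd$age_at_onset_years))
  expect_equal(fit$slope, 0.1, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
})

test_that("stratified expression contrasts the strata against the larger one", {
  # Two strata with different true folds, injected through an onset link
  # that is flat within strata: build by giving the two strata different
  # group folds instead -- simulate two cohorts and merge.
  cfg <- simulation_config(
    groups = c(PD = 12L, CTRL = 10L),
    tissues = "blood",
    panel = assay_panel("GBAtv1", c("ACTB", "PBGD")),
    true_fold = tibble::tibble(group = "PD", tissue = "blood",
                               target = "GBAtv1", fold = 0.5),
    replicate_sd = 0, run_sd = 0,
    seed = 506
  )
  sim <- simulate_cohort(cfg)
  samples <- sim$samples
  meas <- sim$measurements
  # Push the early-onset patients to fold 0.2 (1.3219 extra cycles on the
  # target), leaving late-onset at 0.5: true between-stratum fold is 0.4.
  pd <- samples[samples$group == "PD", ]
  pd_onset <- ifelse(seq_len(nrow(pd)) <= 6, 60, 70)
  samples$age_at_onset_years[samples$group == "PD"] <- pd_onset
  samples$disease_duration_years[samples$group == "PD"] <- 5
  samples$age_years[samples$group == "PD"] <- pd_onset + 5
  early_ids <- pd$sample_id[pd_onset <= 65]
  bump <- meas$sample_id %in% early_ids & meas$assay == "GBAtv1"
  meas$ct[bump] <- meas$ct[bump] + log2(0.5 / 0.2)

  res <- stratified_expression(meas, samples, cfg$panel, "GBAtv1",
                               variable = "age_at_onset")
  expect_equal(res$per_stratum$point[res$per_stratum$stratum == "early"],
               0.2, tolerance = 1e-9)
  expect_equal(res$per_stratum$point[res$per_stratum$stratum == "late"],
               0.5, tolerance = 1e-9)
  expect_equal(res$between$baseline_stratum, "late")
  expect_equal(res$between$point, 0.4, tolerance = 1e-9)
  expect_equal(res$between$classification, "decreased")

  # Null contrast: both strata at the same fold -> unchanged.
  res_null <- stratified_expression(sim$measurements, samples, cfg$panel,
                                    "GBAtv1", variable = "age_at_onset")
  expect_equal(res_null$between$point, 1, tolerance = 1e-9)
  expect_equal(res_null$between$classification, "unchanged")

  # Empty stratum errors.
  samples_all_early <- samples
  samples_all_early$age_at_onset_years[samples$group == "PD"] <- 60
  expect_error(
    stratified_expression(meas, samples_all_early, cfg$panel, "GBAtv1",
                          variable = "age_at_onset"),
    class = "ctquant_insufficient_data_error"
  )

  # Tidy flattening keeps all three contrasts.
  flat <- as_comparison_table(res)
  expect_equal(nrow(flat), 3L)
  expect_setequal(flat$contrast, c("vs_control", "between_strata"))
})
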