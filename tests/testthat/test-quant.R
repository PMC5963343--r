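test_that("replicate aggregation returns mean and sample SD of detected wells", {
  agg <- aggregate_replicates(c(24.0, 24.0))
  expect_equal(agg$mean_ct, 24.0)
  expect_equal(agg$sd_ct, 0.0)
  expect_equal(agg$n, 2L)

  agg <- aggregate_replicates(c(23.8, 24.2, 24.0))
  expect_equal(agg$mean_ct, 24.0)
  expect_equal(agg$sd_ct, 0.2)

  agg <- aggregate_replicates(c(24.0, NA, 24.4))
  expect_equal(agg$mean_ct, 24.2)
  expect_equal(agg$n_undetected, 1L)

  expect_error(aggregate_replicates(c(NA_real_, NA_real_)),
               class = "ctquant_missing_assay_error")
})

test_that("per-sample Ct summary averages within runs before across runs", {
  # run1 has 3 detected replicates, run2 only 1: hierarchical aggregation
  # weights the two runs equally, a flat mean would not.
  meas <- tibble::tibble(
    sample_id = "s1", assay = "GBAtv1",
    run_id = c("run1", "run1", "run1", "run2"),
    replicate = c(1L, 2L, 3L, 1L),
    ct = c(24.0, 24.2, 24.4, 25.0)
  )
  summ <- summarize_ct(meas)
  expect_equal(summ$mean_ct, (24.2 + 25.0) / 2)
  expect_equal(summ$n_replicates, 4L)

  meas$ct[4] <- NA
  summ2 <- summarize_ct(meas)  # run2 contributes nothing, cell survives
  expect_equal(nrow(summ2), 1L)
  expect_equal(summ2$mean_ct, 24.2)

  # A cell whose every replicate is undetected is dropped with a warning.
  meas2 <- tibble::add_row(meas, sample_id = "s1", assay = "GUSB",
                           run_id = "run1", replicate = 1L, ct = NA)
  expect_warning(summ3 <- summarize_ct(meas2), "no detected")
  expect_equal(summ3$assay, "GBAtv1")
})

test_that("standard curves recover amplification efficiency from the slope", {
  # Perfect doubling: slope -1/log10(2).
  d <- simulate_dilution_series(efficiency = 1, noise_sd = 0)
  fit <- fit_standard_curve(d$log10_dilution, d$ct, "GBAtv1", "run1")
  expect_equal(fit$slope, -3.321928, tolerance = 1e-6)
  expect_equal(fit$efficiency, 1.0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)

  # Frozen: E = 10^(1/3.6) - 1 for a slope of exactly -3.6.
  ct <- 25 + (0:4) * 3.6
  fit2 <- fit_standard_curve(-(0:4), ct)
  expect_equal(fit2$efficiency, 0.8957357, tolerance = 1e-6)

  expect_error(fit_standard_curve(c(0, -1), c(25, 28.3)),
               class = "ctquant_insufficient_data_error")
  expect_error(fit_standard_curve(c(0, -1, -2), c(25, 24, 23)),
               class = "ctquant_qc_error")  # positive-slope curve
})

test_that("efficiency similarity check compares |E_target - E_reference|", {
  # Build fits directly from exact series.
  fit_for <- function(e, assay) {
    slope <- -1 / log10(1 + e)
    fit_standard_curve(-(0:3), 25 + -(0:3) * slope, assay, "r1")
  }
  f100 <- fit_for(1.00, "GBAtv1")
  f095 <- fit_for(0.95, "ACTB")
  f085 <- fit_for(0.85, "ACTB")

  res <- check_efficiency_similarity(f100, f095, tolerance = 0.1)
  expect_true(res$pass)
  expect_equal(res$delta, 0.05, tolerance = 1e-9)

  expect_warning(
    res2 <- check_efficiency_similarity(f100, f085, tolerance = 0.1),
    "differ"
  )
  expect_false(res2$pass)
  expect_equal(res2$delta, 0.15, tolerance = 1e-9)

  res3 <- check_efficiency_similarity(f100, f100, tolerance = 0.1)
  expect_true(res3$pass)
  expect_equal(res3$delta, 0)

  expect_error(check_efficiency_similarity(f100, NULL),
               class = "ctquant_qc_error")
})

test_that("dCt and group ddCt follow their definitional formulas", {
  expect_equal(compute_delta_ct(25.0, 20.0), 5.0)
  expect_equal(compute_delta_ct(20.0, 20.0), 0.0)
  expect_equal(compute_delta_ct(19.0, 22.5), -3.5)
  expect_error(compute_delta_ct(NA, 20), class = "ctquant_missing_assay_error")

  est <- compute_group_ddct(c(5.0, 5.2, 5.4), c(4.0, 4.0))
  expect_equal(est$ddct, 1.2)
  expect_equal(est$sd, 0.2)
  expect_equal(est$n_case, 3L)

  same <- compute_group_ddct(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$ddct, 0)

  expect_error(compute_group_ddct(numeric(0), 4.0),
               class = "ctquant_insufficient_data_error")
})

test_that("relative expression bounds come from 2^-(ddCt +/- SD)", {
  expect_equal(
    unlist(relative_expression(0, 0)),
    c(point = 1, low = 1, high = 1)
  )
  re <- relative_expression(1.2, 0.2)
  expect_equal(re$point, 0.4352753, tolerance = 1e-6)
  expect_equal(re$low, 0.3789291, tolerance = 1e-6)
  expect_equal(re$high, 0.5, tolerance = 1e-12)

  expect_equal(relative_expression(-1, 0)$point, 2.0)
  expect_error(relative_expression(1, -0.1),
               class = "ctquant_validation_error")
})

test_that("reference averaging is the arithmetic mean of the components", {
  one <- tibble::tibble(point = 0.4, low = 0.35, high = 0.46,
                        reference = "ACTB")
  expect_equal(combine_references(one)$point, 0.4)
  expect_equal(combine_references(one)$references_used, "ACTB")

  two <- tibble::tibble(
    point = c(0.4, 0.5), low = c(0.35, 0.45), high = c(0.46, 0.56),
    reference = c("ACTB", "GUSB"), target = "GBAtv1"
  )
  comb <- combine_references(two)
  expect_equal(comb$point, 0.45)
  expect_equal(comb$low, 0.40)
  expect_equal(comb$references_used, "ACTB+GUSB")

  mismatched <- tibble::tibble(
    point = c(0.4, 0.5), low = c(0.3, 0.4), high = c(0.5, 0.6),
    reference = c("ACTB", "GUSB"), target = c("GBAtv1", "GBAtv2")
  )
  expect_error(combine_references(mismatched),
               class = "ctquant_validation_error")
})

test_that("the 0.5/1.5 rule requires both the point and the bound to clear", {
  thr <- classification_thresholds()
  expect_equal(classify_change(0.41, 0.38, 0.44, thr), "decreased")
  expect_equal(classify_change(0.64, 0.58, 0.73, thr), "unchanged")
  expect_equal(classify_change(1.90, 1.54, 2.66, thr), "increased")
  expect_equal(classify_change(0.55, 0.43, 0.71, thr), "unchanged")
  expect_equal(classify_change(1.0, 1.0, 1.0, thr), "unchanged")
  # Bound comparisons are inclusive, point comparisons strict.
  expect_equal(classify_change(0.49, 0.48, 0.50, thr), "decreased")
  expect_equal(classify_change(0.50, 0.49, 0.50, thr), "unchanged")
  expect_equal(classify_change(1.51, 1.50, 1.52, thr), "increased")

  expect_error(classification_thresholds(decrease = 1.2),
               class = "ctquant_validation_error")
})

test_that("isoform abundance ratios are 2^(Ct difference)", {
  expect_equal(isoform_fold_difference(24, 24), 1.0)
  expect_equal(isoform_fold_difference(25, 24), 2.0)
  expect_equal(isoform_fold_difference(27.32, 24), 9.986644, tolerance = 1e-6)
  expect_error(isoform_fold_difference(NA, 24),
               class = "ctquant_missing_assay_error")
})

test_that("expression profile recovers noiseless ground truth exactly", {
  cfg <- small_config(fold = 0.3, seed = 11, n_per_group = 4L,
                      replicate_sd = 0, run_sd = 0)
  sim <- simulate_cohort(cfg)
  prof <- expression_profile(sim$measurements, sim$samples, cfg$panel)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$point, 0.3, tolerance = 1e-12)
  expect_equal(prof$classification, "decreased")
  expect_equal(prof$log2_point, log2(0.3), tolerance = 1e-12)

  null_cfg <- small_config(fold = 1, seed = 12, n_per_group = 4L,
                           replicate_sd = 0, run_sd = 0)
  null_sim <- simulate_cohort(null_cfg)
  null_prof <- expression_profile(null_sim$measurements, null_sim$samples,
                                  null_cfg$panel)
  expect_equal(null_prof$point, 1, tolerance = 1e-12)
  expect_equal(null_prof$classification, "unchanged")
})

test_that("expression profile demands controls in every tissue", {
  cfg <- small_config(seed = 13, n_per_group = 3L)
  sim <- simulate_cohort(cfg)
  no_ctrl <- dplyr::filter(sim$samples, group != "CTRL")
  meas <- dplyr::filter(sim$measurements,
                        sample_id %in% no_ctrl$sample_id)
  expect_error(expression_profile(meas, no_ctrl, cfg$panel),
               class = "ctquant_insufficient_data_error")

  orphan <- sim$measurements
  orphan$sample_id[1] <- "ghost"
  expect_error(expression_profile(orphan, sim$samples, cfg$panel),
               class = "ctquant_validation_error")
})

test_that("pipeline point estimates equal the brute-force oracle", {
  set.seed(301)
  for (i in 1:10) {
    ds <- random_small_dataset()
    prof <- expression_profile(ds$measurements, ds$samples, ds$panel)
    oracle <- oracle_point_estimate(
      ds$measurements, ds$case_ids, ds$control_ids, "GBAtv1",
      c("ACTB", "GUSB")
    )
    expect_equal(prof$point, oracle, tolerance = 1e-12)
  }
})

test_that("quantification invariants hold on randomized inputs", {
  set.seed(302)
  for (i in 1:25) {
    ddct <- runif(1, -4, 4)
    s <- runif(1, 0, 1.5)
    re <- relative_expression(ddct, s)
    # Bound ordering, equality iff sd = 0.
    expect_true(re$low <= re$point && re$point <= re$high)
    if (s > 0) expect_true(re$low < re$high)
    # Exactness on the log scale and geometric symmetry (single reference).
    expect_equal(log2(re$point), -ddct, tolerance = 1e-12)
    expect_equal(re$point^2, re$low * re$high, tolerance = 1e-12)
    # Monotonicity of the point estimate in ddCt.
    expect_lt(relative_expression(ddct + 0.5, s)$point, re$point)
    # Mutual exclusion of the calls is structural: exactly one label.
    expect_true(classify_change(re$point, re$low, re$high) %in%
                  c("decreased", "increased", "unchanged"))
  }
})

test_that("adding a constant to every Ct leaves the analysis unchanged", {
  set.seed(303)
  ds <- random_small_dataset()
  prof <- expression_profile(ds$measurements, ds$samples, ds$panel)
  shifted <- ds$measurements
  shifted$ct <- shifted$ct + 3.7
  prof_shift <- expression_profile(shifted, ds$samples, ds$panel)
  expect_equal(prof_shift$point, prof$point, tolerance = 1e-12)
  expect_equal(prof_shift$low, prof$low, tolerance = 1e-12)
  expect_equal(prof_shift$high, prof$high, tolerance = 1e-12)
  expect_identical(prof_shift$classification, prof$classification)
})
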