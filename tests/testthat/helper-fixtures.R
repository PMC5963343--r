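# Shared fixture builders: everything is generated in code at test time.

write_ct_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("sample_id,assay,run_id,replicate,ct", lines), path)
  path
}

write_meta_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  header <- paste(
    "sample_id,subject_id,cohort_arm,tissue,group,age_years,sex",
    "age_at_onset_years,disease_duration_years,post_mortem_time_hours,rin",
    sep = ","
  )
  writeLines(c(header, lines), path)
  path
}

# A random small Ct table (one tissue, one target, two references) plus the
# matching metadata, for oracle-equivalence checks.
random_small_dataset <- function(n_case = 5L, n_control = 5L) {
  panel <- assay_panel("GBAtv1", c("ACTB", "GUSB"))
  ids <- c(sprintf("case%02d", seq_len(n_case)),
           sprintf("ctrl%02d", seq_len(n_control)))
  grid <- expand.grid(
    sample_id = ids,
    assay = c("GBAtv1", "ACTB", "GUSB"),
    run_id = c("run1", "run2"),
    replicate = 1:2,
    stringsAsFactors = FALSE
  )
  grid$ct <- runif(nrow(grid), 18, 32)
  samples <- tibble::tibble(
    sample_id = ids,
    subject_id = ids,
    cohort_arm = "blood",
    tissue = "blood",
    group = rep(c("PD", "CTRL"), c(n_case, n_control)),
    age_years = 70,
    sex = "unknown",
    age_at_onset_years = rep(c(65, NA), c(n_case, n_control)),
    disease_duration_years = rep(c(5, NA), c(n_case, n_control)),
    post_mortem_time_hours = NA_real_,
    rin = 8
  )
  list(
    measurements = tibble::as_tibble(grid),
    samples = samples,
    panel = panel,
    case_ids = ids[seq_len(n_case)],
    control_ids = ids[n_case + seq_len(n_control)]
  )
}

# A small two-group noiseless-capable simulation configuration used across
# test files; noise arguments flow through to simulation_config().
small_config <- function(fold = 0.4, seed = 1L, n_per_group = 20L, ...) {
  simulation_config(
    groups = c(PD = n_per_group, CTRL = n_per_group),
    tissues = "blood",
    panel = assay_panel("GBAtv1", c("ACTB", "PBGD")),
    true_fold = tibble::tibble(
      group = "PD", tissue = "blood", target = "GBAtv1", fold = fold
    ),
    seed = seed,
    ...
  )
}
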