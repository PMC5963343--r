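# Long-format tabular I/O for Ct measurements and sample metadata.
# CSV dialect: comma separated, UTF-8, header row required, "." decimal.
# Tab-separated input is accepted via `sep = "\t"`.

UNDETECTED_TOKENS <- c("Undetermined", "undetermined", "NA", "")

VALID_GROUPS <- c("CTRL", "pDLB", "cDLB", "PDND", "PDD", "DLB", "PD")

ct_required_cols <- c("sample_id", "assay", "run_id", "replicate", "ct")

sample_numeric_cols <- c(
  "age_years", "age_at_onset_years", "disease_duration_years",
  "post_mortem_time_hours", "rin"
)
sample_known_cols <- c(
  "sample_id", "subject_id", "cohort_arm", "tissue", "group", "sex",
  sample_numeric_cols
)

read_delim_strict <- function(path, sep) {
  if (!file.exists(path)) {
    abort_io(sprintf("File not found: %s", path))
  }
  readr::read_delim(
    path,
    delim = sep,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = ".", grouping_mark = ""),
    na = character(),
    trim_ws = TRUE,
    progress = FALSE,
    show_col_types = FALSE
  )
}

#' Read a long-format Ct measurement table
#'
#' Expects one row per technical replicate with columns `sample_id`, `assay`,
#' `run_id`, `replicate` and `ct`. Undetected wells (tokens `"Undetermined"`,
#' `"NA"` or an empty field) are kept as a first-class undetected flag,
#' represented as `NA` in the numeric `ct` column — they are never replaced
#' by a numeric cap, so means over detected replicates are not biased.
#'
#' @param path Path to a CSV (or TSV, see `sep`) file.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return A tibble with columns `sample_id`, `assay`, `run_id` (character),
#'   `replicate` (integer) and `ct` (double, `NA` = undetected).
#' @export
read_ct_table <- function(path, sep = ",") {
  raw <- read_delim_strict(path, sep)
  missing_cols <- setdiff(ct_required_cols, names(raw))
  if (length(missing_cols) > 0L) {
    abort_format(sprintf(
      "Ct table is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }

  replicate <- suppressWarnings(as.integer(raw$replicate))
  if (anyNA(replicate) || any(replicate < 1L)) {
    abort_format("`replicate` must be a positive integer for every row.")
  }

  ct_chr <- raw$ct
  undetected <- ct_chr %in% UNDETECTED_TOKENS
  ct <- rep(NA_real_, length(ct_chr))
  parsed <- suppressWarnings(as.numeric(ct_chr[!undetected]))
  if (anyNA(parsed)) {
    bad <- unique(ct_chr[!undetected][is.na(parsed)])
    abort_format(sprintf(
      "Unparseable ct value(s): %s", paste(head(bad, 5L), collapse = ", ")
    ))
  }
  ct[!undetected] <- parsed
  out_of_range <- !is.na(ct) & (ct <= 0 | ct > 45)
  if (any(out_of_range)) {
    abort_validation(sprintf(
      "%d ct value(s) outside (0, 45] cycles.", sum(out_of_range)
    ))
  }

  out <- tibble::tibble(
    sample_id = raw$sample_id,
    assay = raw$assay,
    run_id = raw$run_id,
    replicate = replicate,
    ct = ct
  )

  key <- paste(out$sample_id, out$assay, out$run_id, out$replicate, sep = "|")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    abort_validation(sprintf(
      "Duplicate (sample_id, assay, run_id, replicate) key(s): %s",
      paste(head(dups, 5L), collapse = "; ")
    ))
  }
  out
}

#' Write a Ct measurement table
#'
#' Inverse of [read_ct_table()]: undetected measurements are written as
#' `"Undetermined"` so a write/read round trip is the identity.
#'
#' @param measurements Tibble as returned by [read_ct_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(measurements, path) {
  readr::write_csv(measurements, path, na = "Undetermined", progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Parses and validates one row per sample: identifiers, cohort arm, tissue,
#' diagnostic group, demographics, clinical covariates (age at onset and
#' disease duration, missing for controls), post-mortem time and RIN.
#' Unknown columns are ignored with a warning.
#'
#' Validated invariants: age at onset cannot exceed age; when age, onset and
#' duration are all present they must be mutually consistent within one year;
#' control samples cannot carry onset or duration; RIN must lie in [1, 10].
#'
#' @param path Path to a CSV (or TSV) file.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return A tibble of validated sample records.
#' @export
read_sample_metadata <- function(path, sep = ",") {
  raw <- read_delim_strict(path, sep)
  required <- c("sample_id", "tissue", "group")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    abort_format(sprintf(
      "Sample metadata is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  unknown <- setdiff(names(raw), sample_known_cols)
  if (length(unknown) > 0L) {
    warn(sprintf(
      "Ignoring unknown metadata column(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }

  n <- nrow(raw)
  get_chr <- function(col, default = NA_character_) {
    if (col %in% names(raw)) {
      x <- raw[[col]]
      x[x %in% c("", "NA")] <- NA_character_
      x
    } else {
      rep(default, n)
    }
  }
  get_num <- function(col) {
    if (col %in% names(raw)) {
      x <- get_chr(col)
      out <- suppressWarnings(as.numeric(x))
      if (any(!is.na(x) & is.na(out))) {
        abort_format(sprintf("Unparseable numeric value in column `%s`.", col))
      }
      out
    } else {
      rep(NA_real_, n)
    }
  }

  out <- tibble::tibble(
    sample_id = raw$sample_id,
    subject_id = get_chr("subject_id"),
    cohort_arm = get_chr("cohort_arm"),
    tissue = get_chr("tissue"),
    group = get_chr("group"),
    age_years = get_num("age_years"),
    sex = get_chr("sex", "unknown"),
    age_at_onset_years = get_num("age_at_onset_years"),
    disease_duration_years = get_num("disease_duration_years"),
    post_mortem_time_hours = get_num("post_mortem_time_hours"),
    rin = get_num("rin")
  )
  out$subject_id[is.na(out$subject_id)] <- out$sample_id[is.na(out$subject_id)]
  out$sex[is.na(out$sex)] <- "unknown"

  validate_sample_records(out)
  out
}

validate_sample_records <- function(samples) {
  bad_group <- !samples$group %in% VALID_GROUPS
  if (any(bad_group)) {
    abort_validation(sprintf(
      "Unknown group label(s): %s",
      paste(unique(samples$group[bad_group]), collapse = ", ")
    ))
  }
  bad_sex <- !samples$sex %in% c("M", "F", "unknown")
  if (any(bad_sex)) {
    abort_validation("`sex` must be one of M, F, unknown.")
  }
  with_onset <- !is.na(samples$age_at_onset_years) & !is.na(samples$age_years)
  if (any(with_onset &
          samples$age_at_onset_years > samples$age_years)) {
    offending <- samples$sample_id[with_onset &
      samples$age_at_onset_years > samples$age_years]
    abort_validation(sprintf(
      "age_at_onset_years exceeds age_years for sample(s): %s",
      paste(offending, collapse = ", ")
    ))
  }
  full <- !is.na(samples$age_years) & !is.na(samples$age_at_onset_years) &
    !is.na(samples$disease_duration_years)
  inconsistent <- full & abs(
    samples$age_years -
      (samples$age_at_onset_years + samples$disease_duration_years)
  ) > 1
  if (any(inconsistent)) {
    abort_validation(sprintf(
      "age, onset and duration inconsistent (> 1 year) for sample(s): %s",
      paste(samples$sample_id[inconsistent], collapse = ", ")
    ))
  }
  ctrl_with_clinical <- samples$group == "CTRL" &
    (!is.na(samples$age_at_onset_years) |
       !is.na(samples$disease_duration_years))
  if (any(ctrl_with_clinical)) {
    abort_validation(sprintf(
      "Control sample(s) carry onset/duration: %s",
      paste(samples$sample_id[ctrl_with_clinical], collapse = ", ")
    ))
  }
  bad_rin <- !is.na(samples$rin) & (samples$rin < 1 | samples$rin > 10)
  if (any(bad_rin)) {
    abort_validation("RIN values must lie in [1, 10].")
  }
  neg <- c("age_years", "age_at_onset_years", "disease_duration_years",
           "post_mortem_time_hours")
  for (col in neg) {
    if (any(!is.na(samples[[col]]) & samples[[col]] < 0)) {
      abort_validation(sprintf("`%s` must be non-negative.", col))
    }
  }
  invisible(samples)
}

#' Write analysis reports
#'
#' Emits a tidy CSV of relative-expression rows, a CSV of stratified
#' comparisons, and a plain-text run log recording the seed and a hash of the
#' configuration so a run can be matched to its outputs. Reruns with the same
#' inputs produce byte-identical data CSVs.
#'
#' @param profile Tibble of relative-expression rows, e.g. from
#'   [expression_profile()]. May have zero rows.
#' @param comparisons Optional tibble of stratified comparisons (zero rows
#'   allowed). When `NULL` an empty skeleton is written.
#' @param path Output directory, created if needed.
#' @param seed Optional integer recorded in the run log.
#' @param config Optional list recorded in the run log as a hash.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(profile, comparisons = NULL, path, seed = NULL,
                         config = NULL) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok || file.access(path, mode = 2L) != 0L) {
    abort_io(sprintf("Cannot write to directory: %s", path))
  }
  if (is.null(comparisons)) {
    comparisons <- tibble::tibble(
      variable = character(), stratum = character(), n = integer(),
      point = double(), low = double(), high = double(),
      classification = character()
    )
  }
  profile_path <- file.path(path, "expression_profile.csv")
  comparisons_path <- file.path(path, "stratified_comparisons.csv")
  log_path <- file.path(path, "run_log.txt")

  readr::write_csv(profile, profile_path, progress = FALSE)
  readr::write_csv(comparisons, comparisons_path, progress = FALSE)

  log_lines <- c(
    sprintf("ctquant %s", as.character(utils::packageVersion("ctquant"))),
    sprintf("seed: %s", if (is.null(seed)) "none" else format(seed)),
    sprintf("config_hash: %s",
            if (is.null(config)) "none" else rlang::hash(config)),
    sprintf("profile_rows: %d", nrow(profile)),
    sprintf("comparison_rows: %d", nrow(comparisons))
  )
  writeLines(log_lines, log_path)

  invisible(c(
    profile = profile_path,
    comparisons = comparisons_path,
    log = log_path
  ))
}
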