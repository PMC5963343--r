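# Independent brute-force recomputation of the ddCt pipeline, written with
# explicit loops over the definitional formulas. Used only as an oracle;
# shares no code with the package implementation.

oracle_mean_ct <- function(measurements, sid, assay_name) {
  rows <- measurements[measurements$sample_id == sid &
                         measurements$assay == assay_name, ]
  run_means <- c()
  for (run in unique(rows$run_id)) {
    ct <- rows$ct[rows$run_id == run]
    ct <- ct[!is.na(ct)]
    if (length(ct) > 0) run_means <- c(run_means, sum(ct) / length(ct))
  }
  if (length(run_means) == 0) return(NA_real_)
  sum(run_means) / length(run_means)
}

oracle_group_dcts <- function(measurements, ids, target, reference) {
  dcts <- c()
  for (sid in ids) {
    mt <- oracle_mean_ct(measurements, sid, target)
    mr <- oracle_mean_ct(measurements, sid, reference)
    if (!is.na(mt) && !is.na(mr)) dcts <- c(dcts, mt - mr)
  }
  dcts
}

# Combined-reference point estimate for one case group vs controls:
# mean over references of 2^-(mean case dCt - mean control dCt).
oracle_point_estimate <- function(measurements, case_ids, control_ids,
                                  target, references) {
  points <- c()
  for (ref in references) {
    case_dct <- oracle_group_dcts(measurements, case_ids, target, ref)
    ctrl_dct <- oracle_group_dcts(measurements, control_ids, target, ref)
    ddct <- sum(case_dct) / length(case_dct) -
      sum(ctrl_dct) / length(ctrl_dct)
    points <- c(points, 2^(-ddct))
  }
  sum(points) / length(points)
}
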