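---
title: "Relative quantification of transcript isoforms with ctquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative quantification of transcript isoforms with ctquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctquant)
```

## The problem

Real-time PCR with isoform-specific primers is the workhorse for asking
whether a specific transcript variant — here the glucocerebrosidase (GBA)
variants GBAtv1, GBAtv2 and GBAtv5 in Lewy body disease cohorts — is
differentially expressed between patient groups and controls, in brain
tissue and in blood. `ctquant` implements the complete analysis path from a
long-format Ct table to classified expression changes, together with the
quality-control and cohort-stratification analyses that surround it, and a
synthetic-data generator so that every stage can be validated against known
ground truth.

## The quantification model

The relative-quantification core is the comparative-Ct (ddCt) method under
the equal-efficiency assumption:

* **Replicate aggregation.** Each sample x assay is measured in technical
  replicates within each of (typically) two independent runs. Replicates
  are averaged within a run first, then run means are averaged, so runs
  with unequal numbers of detected replicates contribute equally.
  Undetected wells are a first-class flag and are excluded from means, not
  capped at a pseudo-Ct — a cap would bias means downward by an amount
  that depends on the instrument's cycle limit, which the data do not
  determine.
* **Normalization.** Per sample, `dCt = mean Ct(target) - mean Ct(reference)`
  for each housekeeping reference gene (brain: ACTB and GUSB; blood: ACTB
  and PBGD).
* **Group contrast.** `ddCt = mean(case dCt) - mean(control dCt)` and the
  point estimate of the expression change is `2^-ddCt`.
* **Variance bounds.** The standard deviation attached to the ddCt is the
  sample standard deviation of the per-sample *case* dCt values; the
  control group enters through its mean only. Because the Ct scale is
  exponential, the spread is propagated by evaluating the same exponential
  at `ddCt + SD` and `ddCt - SD`, giving an asymmetric interval
  `(2^-(ddCt+SD), 2^-(ddCt-SD))` with the point estimate as its geometric
  midpoint.
* **Dual-reference averaging.** The analysis is run once per reference gene
  and the final expression change is the arithmetic mean of the
  per-reference points and bounds. After averaging, the geometric
  symmetry `point^2 = low x high` holds only approximately; it is exact
  for each single-reference estimate.
* **Classification.** A change is accepted as significant only when both
  the point estimate and the relevant bound clear the threshold:
  *decreased* iff `point < 0.5` and `high <= 0.5`; *increased* iff
  `point > 1.5` and `low >= 1.5`; otherwise *unchanged*. The point
  comparison is strict and the bound comparison inclusive, so an estimate
  whose bound sits exactly on the threshold still qualifies.

```{r classify}
classify_change(0.41, 0.38, 0.44)  # point and upper bound both below 0.5
classify_change(0.55, 0.43, 0.71)  # upper bound crosses 0.5: not accepted
classify_change(1.90, 1.54, 2.66)  # lower bound clears 1.5
```

Where the choice of the SD was genuinely open — whether it should span
biological samples, runs, or both — we attach the between-sample SD of the
case dCt values, with run-to-run scatter already folded into each sample's
mean through the hierarchical aggregation. This is the spread that
dominates group contrasts in cohort data and it makes the bounds shrink as
technical precision improves, which is the behaviour the significance rule
needs.

### Standard curves and the equal-efficiency assumption

Per-run serial dilutions of a common cDNA template yield a standard curve
`Ct ~ log10(dilution)`; its slope gives the amplification efficiency
`E = 10^(-1/slope) - 1`, with `E = 1` (perfect doubling) at slope
`-1/log10(2) = -3.3219`. The ddCt form used here assumes target and
reference amplify with similar efficiency; `check_efficiency_similarity()`
enforces `|E_target - E_reference| <= 0.1` by default (configurable via
`classification_thresholds()`), warning and flagging rather than aborting,
because a failed check invalidates interpretation, not arithmetic.
Efficiency-corrected quantification for dissimilar efficiencies is a
deliberate non-goal.

### Isoform abundance ratios

Within one sample, the relative abundance of two isoforms is `2^n` with `n`
the Ct difference between the minor and the major transcript
(`isoform_fold_difference()`); a 3.32-cycle gap is a roughly ten-fold
difference.

## Stability quality control

Post-mortem brain RNA cannot be assumed intact. Two gates are provided:

* **RIN filter.** `filter_by_rin()` keeps samples with RIN strictly above
  6 (the inclusion rule is "higher than", so 6.0 is excluded); missing RIN
  excludes with a warning.
* **Degradation-rate comparability.** In an accelerated degradation
  experiment (incubation at 50°C with aliquots at 0, 15, 30, 60, 120 and
  240 minutes), the relative amount of each transcript is tracked as
  `2^(Ct_t0 - Ct_t)` and modeled log-linear in time; the per-minute log2
  slope is the degradation rate. The original assessment is qualitative —
  no transcript should degrade appreciably faster than the references — so
  we operationalize "similar stability" as a symmetric bounded-ratio
  criterion: comparable iff neither absolute rate exceeds twice the other
  (`max_ratio = 2`, configurable). This threshold is our declared
  operationalization, not a published constant: a two-fold rate difference
  over a four-hour incubation is roughly the point where differential decay
  would start to mimic the smallest expression changes the 0.5/1.5 rule can
  call.

## Cohort stratification and per-patient expression

For per-patient analyses, each patient's dCt is contrasted against the
*mean* dCt of the entire control group, `rq = 2^-(dCt_i - mean(dCt_ctrl))`,
then reference-averaged. Patients are stratified by age at disease onset
(early: onset at 65 years or before; late: 66 or later) or by disease
duration (short: under 6 years; long: 6 or more). Between-stratum
contrasts reuse the ddCt machinery with the higher-expressing stratum as
the baseline, so the contrast reads as the fold change of the
lower-expressing stratum and is classified with the same 0.5/1.5 rule.

Two analysis choices were open and are set as follows:

* **Welch t-test** for between-stratum comparisons of clinical variables:
  stratum sizes are routinely unequal (6 vs 14 in typical onset splits)
  and the unequal-variance form costs little when variances happen to be
  equal.
* **Regression on log2(rq)** for expression-covariate association:
  expression changes are multiplicative, so the linear model is placed on
  the log scale (switchable with `log_scale = FALSE`). Patients with a
  missing covariate are excluded from that analysis, never imputed.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the package targets: a blood
arm with 20 DLB, 26 PD and 17 control subjects, and a brain arm with
8 pure-DLB, 12 common-DLB, 12 PD-without-dementia, 13 PD-with-dementia and
17 control donors sampled in temporal cortex and caudate nucleus. The
generative model is the quantification model read backwards:

```
Ct(sample, assay, run, rep) = baseline_ct[assay] - log2(fold) +
                              run_offset(run) + e
run_offset ~ N(0, run_sd),  e ~ N(0, replicate_sd)
```

with reference-gene folds fixed at 1. Defaults: technical noise
`replicate_sd = 0.25` cycles and `run_sd = 0.15` cycles (typical
SYBR-green assay precision), two runs of two replicates, baseline Cts in
the 19-28 cycle range reflecting the observed abundance ordering of the
assays. Default true folds encode the suppressed-isoform pattern under
study (e.g. blood GBAtv1 at 0.41 in DLB and 0.35 in PD of control levels;
unlisted combinations are 1). Age at onset and disease duration come from
truncated normal distributions (onset means 68 and 65.3 years, durations
5.9 and 6.5 years in the blood arm), and an optional linear covariate link
adds `slope x (covariate - center)` log2 units to each patient's fold.
Amplification-efficiency deviations enter only the dilution-series
generator; cohort Cts use ideal base-2 amplification, matching the
pipeline's equal-efficiency assumption (mismatch scenarios can be built
explicitly for robustness checks).

What the generator deliberately does **not** emulate: amplification-curve
shapes and threshold setting, GBA/GBAP1 pseudogene cross-amplification,
reference-gene instability across disease states, RIN-correlated Ct shifts
and plate-position effects. Passing tests therefore demonstrate that the
pipeline computes its estimators correctly and recovers truth under its
own model assumptions — not that those assumptions hold in any particular
wet-lab dataset.

```{r recovery}
cfg <- blood_cohort_config(seed = 7)
sim <- simulate_cohort(cfg)
prof <- expression_profile(sim$measurements, sim$samples, cfg$panel)
prof[prof$target == "GBAtv1", c("group", "point", "low", "high",
                                "classification")]
```

## Numerical choices and degenerate inputs

* All exponentials are base 2; `log2(point) = -ddCt` holds to machine
  precision, and a constant shift of every Ct cancels exactly in all dCt,
  ddCt and classifications.
* Sample standard deviations use the n-1 denominator throughout; a single
  detected replicate yields SD 0 rather than NA so that downstream bounds
  degenerate gracefully to the point estimate.
* Undetected wells: excluded from aggregation; a sample x assay cell with
  no detected replicate at all is dropped with a warning at table level
  and is an error when a single aggregate is requested explicitly.
* Degenerate statistics: two zero-variance groups with equal means give
  `t = 0, p = 1` by convention (and `p = 0` with unequal means); a
  constant covariate is a degenerate-design error, not a silent NA.
* Standard curves require at least three distinct dilutions and a negative
  slope; fewer points or a non-negative slope are classed errors.
* Validation problem sizes: oracle-equivalence checks run on 10-sample
  tables against an explicit-loop reimplementation at 1e-12; Monte-Carlo
  recovery uses 200 cohorts of 20 subjects per group, enough to pin the
  mean recovered fold to within ±0.05 of truth at the default noise level.

## Known limitations

* Equal-efficiency ddCt only; no Pfaffl-style efficiency correction, no
  absolute quantification, no melt-curve analysis.
* The significance rule is a fixed-threshold decision rule, not a
  hypothesis test with a controlled error rate; it is reproduced here
  because it is the rule under study. Notably, published interval triples
  exist whose upper bound crosses 0.5 although they were reported as
  significant decreases; applied strictly, the rule returns *unchanged*
  for those, and the test suite marks them as rule-inconsistent fixtures
  rather than forcing agreement.
* No multiple-testing correction across strata or targets, matching the
  analysis the package reproduces.
* The undetected-well policy (exclude, never impute) is a documented
  choice; with many undetected wells in one group, estimates can be based
  on few samples and the `n_case` / `n_control` columns should be checked.
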