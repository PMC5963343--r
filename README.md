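# ctquant

Relative quantification of transcript isoforms from real-time PCR Ct data,
for expression studies that compare patient groups against controls with
the comparative-Ct (ddCt) method — e.g. isoform-specific profiling of the
glucocerebrosidase (GBA) transcript variants GBAtv1/tv2/tv5 in brain and
blood of Lewy body disease cohorts. The package is aimed at analysts who
have long-format Ct exports (sample x assay x run x replicate) plus sample
metadata, and who need the full path from raw Ct values to classified
expression changes, including the QC and cohort analyses around it.

## The method

For each sample, the target Ct is normalized against a housekeeping gene,
dCt = Ct(target) − Ct(reference), after averaging technical replicates
within runs and run means across runs. A case group is contrasted with
controls by

    ddCt = mean(dCt_case) − mean(dCt_control),    fold change = 2^−ddCt

Because the Ct scale is exponential, the spread is propagated by
evaluating the same exponential at ddCt ± SD, where SD is the standard
deviation of the per-sample case dCt values, giving the asymmetric
interval (2^−(ddCt+SD), 2^−(ddCt−SD)). The analysis is run once per
reference gene (two per tissue context: ACTB+GUSB in brain, ACTB+PBGD in
blood) and the final estimate is the arithmetic mean of the per-reference
points and bounds.

A change is accepted as significant only when both the point estimate and
the relevant bound clear the fold-change threshold:

* **decreased** iff point < 0.5 and upper bound ≤ 0.5
* **increased** iff point > 1.5 and lower bound ≥ 1.5
* otherwise **unchanged**

Supporting modules cover amplification-efficiency standard curves
(E = 10^(−1/slope) − 1), RIN-based sample inclusion (RIN > 6), transcript
degradation-rate comparability from 50°C incubation time-courses,
patient-level expression versus the control-group mean, stratification by
age at onset (≤65 vs ≥66 years) and disease duration (<6 vs ≥6 years) with
Welch t-tests and log2-scale regression, and a synthetic Ct generator with
known ground truth. See the methods vignette
(`vignettes/ddct-methods.Rmd`) for the model, assumptions and design
decisions.

## Worked example

Simulate a blood cohort at the package's default study conditions
(20 DLB, 26 PD, 17 controls; GBAtv1 suppressed to 0.41 and 0.35 of control
levels, GBAtv2/tv5 unchanged) and run the full pipeline:

```r
library(ctquant)

cfg  <- blood_cohort_config(seed = 7)
sim  <- simulate_cohort(cfg)
prof <- expression_profile(sim$measurements, sim$samples, cfg$panel)
prof[, c("group", "target", "point", "low", "high", "classification")]
#>   group target point   low  high classification
#> 1   DLB GBAtv1 0.417 0.359 0.485      decreased
#> 2    PD GBAtv1 0.347 0.311 0.388      decreased
#> 3   DLB GBAtv2 1.068 0.935 1.220      unchanged
#> 4    PD GBAtv2 1.069 0.935 1.223      unchanged
#> 5   DLB GBAtv5 1.073 0.951 1.210      unchanged
#> 6    PD GBAtv5 1.054 0.921 1.206      unchanged
```

Each row is one group x target contrast against controls: the fold-change
point estimate 2^−ddCt with its ddCt ± SD bounds, averaged over the two
reference genes, and the 0.5/1.5 call. The recovered folds (0.417, 0.347)
match the generator's ground truth (0.41, 0.35) within sampling noise, and
only the truly suppressed isoform is called.

Stratified analysis of GBAtv1 in the PD patients by disease duration:

```r
stratified_expression(sim$measurements, sim$samples, cfg$panel, "GBAtv1",
                      variable = "disease_duration", case_groups = "PD")
#> <stratified_comparison> GBAtv1 by disease_duration (cut 6)
#>   short (n = 13): 0.34 (0.31-0.37) decreased
#>   long (n = 13): 0.36 (0.32-0.40) decreased
#>   short vs long: 0.94 (0.86-1.04) unchanged
#>   age_at_onset_years across strata: t = 0.182, p = 0.857
```

Both duration strata are suppressed versus controls; the between-stratum
contrast (computed with the higher-expressing stratum as baseline) is
unchanged, as expected here since the generator applied the same fold to
all PD patients.

A noiseless standard curve recovers its generating efficiency exactly:

```r
d <- simulate_dilution_series(efficiency = 0.9, noise_sd = 0)
fit_standard_curve(d$log10_dilution, d$ct, "GBAtv1", "run1")
#> <standard_curve_fit> GBAtv1 / run1: slope -3.5874, R2 1.0000, E 0.900
```

Real data enter through `read_ct_table()` and `read_sample_metadata()`
(strict long-format CSV with classed validation errors), and results leave
through `write_report()`.

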