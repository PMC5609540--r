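# endoxpred

Infer tamoxifen-to-endoxifen metabolic capacity from CYP2D6 star-allele
genotype, and quantify how well competing genotype-to-phenotype
translation schemes predict clinically meaningful endoxifen exposure.

## The scientific problem

Tamoxifen is bioactivated to its dominant active metabolite,
(Z)-endoxifen (E), from N-desmethyl-tamoxifen (DMT) mainly by the highly
polymorphic enzyme CYP2D6. Patients whose plasma endoxifen stays below a
clinical threshold of 5.9 ng/mL (15.8 nM) have reduced benefit, so
genotype-based prediction of endoxifen exposure is a candidate tool for
upfront treatment decisions (dose escalation, or switching to an
aromatase inhibitor). The obstacle is not genotyping but *translation*:
the same CYP2D6 diplotype is binned into different metabolizer phenotypes
by different published schemes, with materially different predictive
value.

The package implements the whole inference chain:

* **Activity scoring.** Alleles classified as null (PM: \*3–\*7, score
  0), reduced (IM: \*9, \*10, \*41, score 0.5), full (EM: \*1, \*2, \*35,
  score 1; duplicated EM = 2, ultra-rapid). The diplotype activity score
  is the allele sum: `AS(*1/*41) = 1 + 0.5 = 1.5`. A second dialect
  downgrades \*10 to 0.25: `AS(*1/*10) = 1.25`.
* **Five phenotype schemes** (Codeine, TAM1–TAM4) as declarative
  category → {UM, EM, IM, SM, PM} tables, including TAM4's
  slow-metabolizer (SM) class for \*10-containing reduced-activity
  diplotypes.
* **Robust association.** For endpoints log E and log E/DMT, variance
  explained by diplotype or by each scheme is estimated with an M-type
  IRLS fit (Tukey bisquare, 95% Gaussian efficiency, CYP2C9/CYP3A5
  genotype covariates); the robust adjusted R² gets percentile bootstrap
  intervals, and nested scheme models are compared with a robust
  analysis of deviance.
* **Threshold classification.** ROC analysis over the seven-level
  diplotype activity ordering (EM/UM 3 > EM/EM 2 > EM/IM 1.5 > EM/PM 1 >
  IM/IM 0.75 > IM/PM 0.5 > PM/PM 0), Youden-optimal cutoff, and
  bootstrap intervals for sensitivity, specificity and the genotype-test
  FDR = FP/(FP+TP).
* **A calibrated synthetic cohort generator** that emulates the
  statistical structure of a multi-ethnic tamoxifen pharmacokinetic
  study (diplotype composition, log-normal metabolite cascade, covariate
  effects, compliance filter), so every stage is testable without
  patient data.

## Worked example

```r
library(endoxpred)

parse_diplotype(c("*1/*41", "*4/*10", "*1x2/*1"))
#>   diplotype allele_a allele_b category refined  label as_standard as_star10 roc_activity
#> 1    *1/*41       *1      *41    EM/IM    <NA>  EM/IM         1.5      1.50          1.5
#> 2    *4/*10       *4      *10    IM/PM  PM/*10 PM/*10         0.5      0.25          0.5
#> 3   *1x2/*1       *1       *1    EM/UM    <NA>  EM/UM         3.0      3.00          3.0

co <- simulate_cohort(cohort_config(), n = 900, seed = 42)
#> 897 patients (3 removed by the 150 nM tamoxifen compliance filter)

bootstrap_r2_ci(co, "E_over_DMT", "diplotype", replicates = 500, seed = 1)
#> Variance explained (E_over_DMT ~ diplotype): robust adj. R2 = 74.4%
#>   bootstrap median 74.9% (95% CI 71.2-78.2%), 500 replicates (0 failed), n = 897

bootstrap_r2_ci(co, "E_over_DMT", "Codeine", replicates = 500, seed = 1)
#> Variance explained (E_over_DMT ~ phenotype_Codeine): robust adj. R2 = 59.1%
#>   bootstrap median 60.0% (95% CI 54.4-64.9%), 500 replicates (0 failed), n = 897

out <- binarize_outcome(co)          # E >= 5.9 ng/mL is "above"
best <- youden_optimal_cutoff(roc_diplotype_ranks(out))
bootstrap_metric_ci(out, best$cutoff, replicates = 2000, seed = 1)
#> Diplotype threshold classifier at cutoff >= IM/IM (> 0.5)
#>   sensitivity 96.9% (95% CI 95.7-98.1%)
#>   specificity 68.4% (95% CI 60.5-75.7%)
#>   FDR 6.2% (95% CI 4.8-7.6%)
#>   test-positive fraction 85.8% | 2000 bootstrap replicates
```

Reading the numbers: the full diplotype factor explains ~74% of the
variance of the log metabolic ratio in this synthetic cohort (its
calibration target is 0.75), while collapsing diplotypes to the
codeine-based phenotype throws away ~15 points of explained variance —
the cost of a binning designed for a different substrate. The classifier
row says that declaring every patient with diplotype activity above 0.5
"likely above threshold" catches ~97% of the patients who truly reach
5.9 ng/mL, while ~6% of test-positive patients do not reach it.

`run_pipeline()` chains all stages (cohort → frequency table →
per-scheme association → scheme comparisons → classification) and writes
CSV/JSON artifacts stamped with a config hash;
`inst/scripts/endoxpred-cli.R` exposes `generate`, `score`, `associate`,
`classify` and `run` subcommands over the same functions.

## Scope

Calling star alleles from sequencing data, hybrid-gene detection,
alleles outside the panel (\*17, \*29), CYP3A4\*22 adjustment, and
clinical outcome modelling are out of scope. See the methods vignette
(`vignettes/endoxifen-prediction.Rmd`) for the model assumptions, the
generator calibration, and the design decisions.
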