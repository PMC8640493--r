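# brgpi

Rank-based gene-pair signatures of immunotherapy benefit in non-small cell
lung cancer (NSCLC), for biostatisticians and computational biologists
evaluating progression-free-survival (PFS) biomarkers under anti-PD-1
checkpoint blockade.

Absolute expression biomarkers travel poorly across measurement platforms
(RNA-seq counts, TPM, immunohistochemistry scores). This package implements
the normalization-free alternative: the unit feature is the within-sample
relative-expression indicator of an oriented gene pair,

```
s_ab(i) = 1  if  x_a(i) > x_b(i),   else 0      (ties score 0)
```

which is invariant to any strictly increasing per-sample transformation of
the data. A signature is a weighted sum of such indicators,

```
score(i) = Σ_k β_k s_k(i)
```

with weights β taken from a joint multivariate Cox fit, and patients are
split into low/high risk at a cutoff chosen on an IPCW time-dependent ROC
curve at 12 months (Youden's J). The package provides:

* the full discovery pipeline (`brgpi()`): pair enumeration, constancy
  filtering, univariate Cox screening, forward stepwise AIC selection,
  Youden cutoff;
* the frozen published four-pair NSCLC signature
  (`published_signature()`): 1.521·[CCL2|VEGFA] + 1.257·[CDK1|CXCL9]
  − 1.495·[HLA-DOB|LCK] + 1.812·[IL12A|TBX21], cutoff 0.317;
* the evaluation battery (`evaluate_cohort()`): time-dependent ROC/AUC,
  Kaplan–Meier + log-rank by index group, univariate/multivariate Cox
  against clinical covariates, response-group score comparisons
  (CR/PR vs SD vs PD, response vs non-response, PD vs non-PD),
  pathology/PD-L1 stratification and the index × PD-L1 three-group
  analysis;
* a synthetic-cohort generator (`generate_cohort()`) with planted pair
  signatures, proportional-hazards PFS, calibrated censoring, RECIST
  response and PD-L1 labels, plus per-sample monotone "platform"
  distortions for invariance testing;
* a command-line pipeline (`brgpi_cli()` / `inst/cli/brgpi.R`) with
  `simulate`, `encode`, `train`, `score`, `evaluate` subcommands.

## Worked example

Simulate a cohort carrying the published signature as planted truth (here
deliberately on the `rank` platform — the method never sees the scale), and
evaluate the frozen published index on it:

```r
library(brgpi)

co  <- generate_cohort(sim_config(n_samples = 150, n_genes = 20, seed = 42,
                                  censor_rate = 0.2, platform = "rank"))
sig <- published_signature()
evaluate_cohort(co, sig)
#> Cohort evaluation (n = 150, 112 events)
#>   index groups: low = 51, high = 99 (cutoff 0.317)
#>   AUC at 12 months: 0.920
#>   log-rank low vs high: chisq = 64.6, p = 9.33e-16
#>   score vs response (CR/PR, SD, PD): Kruskal-Wallis p = 1.19e-13
#>   index x PD-L1 three-group log-rank p = 3.26e-09
```

Reading the output: the 12-month time-dependent AUC of 0.920 says the index
ranks patients who progress within a year above those who do not; the
log-rank p compares PFS between the 51 index-low and 99 index-high
patients; the Kruskal–Wallis p confirms scores rise across response
categories (worst in progressive disease).

Re-discovering a signature from the same cohort recovers the planted pairs
with coefficients near their planted values:

```r
brgpi(co)
#> Gene-pair index:
#>   score = +2.17 x [IL12A|TBX21] +1.701 x [CCL2|VEGFA] -1.322 x [HLA-DOB|LCK] +1.186 x [CDK1|CXCL9]
#>   cutoff: 1.867084 (high iff score > cutoff), horizon: 12 months
#>   provenance: forward stepwise AIC selection (4 of 34 candidates)
```

The same flow is available from a shell (file dialects are documented in
the function help: expression TSV with a `gene_id` column, clinical CSV
with header `sample_id,pfs_months,event,response,pdl1,pathology,sex`,
signature and report as JSON):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "brgpi.R", package = "brgpi"))')
Rscript $CLI simulate --n-samples 150 --seed 42 --out-dir cohort/
Rscript $CLI encode   --expression cohort/expression.tsv --out indicators.tsv
Rscript $CLI train    --expression cohort/expression.tsv --clinical cohort/clinical.csv --out signature.json
Rscript $CLI score    --signature signature.json --indicators indicators.tsv --out scores.csv
Rscript $CLI evaluate --signature signature.json --expression cohort/expression.tsv \
                      --clinical cohort/clinical.csv --out report.json
```

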