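# diliternary

Ternary metabolomic phenotyping of drug-induced liver injury (DILI).

Clinical practice phenotypes a DILI episode from two liver enzymes via the
R score, R = (ALT/ULN_ALT)/(ALP/ULN_ALP) with ULN_ALT = 56 U/L and
ULN_ALP = 147 U/L: cholestatic if R < 2, mixed if 2 ≤ R < 5, hepatocellular
if R ≥ 5, and recovered once both enzymes are below their limits. Two
enzymes cannot resolve the continuum between the injury poles, and patients
whose chemistry has normalised may still carry a perturbed metabolome.

`diliternary` implements a metabolome-based decomposition for analysts
working with untargeted LC-MS plasma peak tables from DILI cohorts. Three
one-vs-rest PLS-DA models — cholestatic vs rest, hepatocellular vs rest,
recovered vs rest — are trained on the peak table; their three predictions
per sample are clipped and normalised onto the 2-simplex and read as
percentages of each phenotype:

    y = (y_C, y_H, y_R)  →  (c, h, r) = max(y, 0) / Σ max(y, 0)

so a sample at (0.30, 0.30, 0.40) is 30 % cholestatic, 30 % hepatocellular,
40 % recovered. Around this core the package provides:

* QC-based support-vector-regression drift correction within batches
  (QC-SVRC, RBF kernel, LOO-selected penalty),
* blank/missingness feature filtering, half-minimum imputation, log10 +
  autoscaling with train-only parameters,
* Welch t-test + Benjamini–Hochberg univariate screening,
* subject-wise double cross-validation with latent-variable selection
  (one-standard-error rule) and VIP ≥ 1 two-stage refitting,
* residual-DILI flagging in clinically recovered samples, longitudinal
  transition annotation, and ternary plots,
* a synthetic-cohort generator with ground-truth phenotype mixtures, so the
  whole pipeline is testable without patient data.

## Worked example

```r
library(diliternary)

sim <- simulate_cohort(sim_config(seed = 1))   # 60 patients, 828 features
res <- run_ternary_pipeline(sim$cohort, seed = 1)
print(res)
#> <dili_pipeline> 187 study samples, 828 features after filtering
#>   clinical counts: cholestatic=81, hepatocellular=45, mixed=11, recovered=48, unclassifiable=2
#>   double-CV balanced accuracy: 0.984
#>   residual-DILI flags among recovered samples: 22
```

The clinical counts are the rule-based labels; the balanced accuracy is the
pooled out-of-sample estimate from subject-wise nested cross-validation
(patients, never samples, are held out); the residual flags are clinically
recovered samples whose metabolome still projects ≥ 20 % onto an injury
pole. Per-sample results live in `res$predictions`:

```r
head(res$predictions[, c("sample_id", "label", "c", "h", "r", "residual_level")], 3)
#>         sample_id     label         c         h         r residual_level
#> P031-t2   P031-t2     mixed 0.2390433 0.5018951 0.2590616           none
#> P011-t3   P011-t3 recovered 0.1236481 0.1877107 0.6886412           none
#> P005-t4   P005-t4 recovered 0.1738322 0.1992615 0.6269062           none
```

and `render_ternary(res$predictions, "cohort.png")` draws the simplex with
the conventional colours (green cholestatic, orange hepatocellular, white
mixed, blue recovered) and timepoint numerals inside the markers. For real
data, point `read_cohort_manifest()` at a YAML manifest naming the peak
table and clinical CSV/TSV files.

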