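---
title: "Ternary metabolomic phenotyping of drug-induced liver injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ternary metabolomic phenotyping of drug-induced liver injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diliternary)
```

## The problem

Idiosyncratic drug-induced liver injury (DILI) is conventionally phenotyped
from two liver enzymes. The R score,

$$R = \frac{\mathrm{ALT}/\mathrm{ULN}_{\mathrm{ALT}}}
          {\mathrm{ALP}/\mathrm{ULN}_{\mathrm{ALP}}},$$

with upper limits of normal ULN~ALT~ = 56 U/L and ULN~ALP~ = 147 U/L, splits
episodes into cholestatic (R < 2), mixed (2 ≤ R < 5), and hepatocellular
(R ≥ 5) injury, and a patient is called recovered once both enzymes fall
below their limits. Two enzymes compress a continuum of liver damage into
four boxes: intermediate mixtures are poorly resolved, and samples whose
chemistry has normalised may still carry a perturbed metabolome.

This package implements a metabolome-based alternative. Three one-vs-rest
PLS-DA models — one per phenotype *pole*: cholestatic (C), hepatocellular
(H), recovered (R) — are trained on an annotated LC-MS peak table. Their
three predictions for a sample are projected onto the 2-simplex and read as
percentages: a sample at (0.30, 0.30, 0.40) is 30 % cholestatic, 30 %
hepatocellular, 40 % recovered. The simplex view supports three clinical
readouts:

* **Phenotype mixtures.** Samples between the poles are quantified rather
  than forced into a box.
* **Residual DILI.** A clinically recovered sample whose C or H coordinate
  is still ≥ 0.20 (minor) or ≥ 0.40 (major) is flagged.
* **Transitions.** Consecutive samples of one patient are annotated as
  moving toward recovery, shifting H→C or C→H, or stable.

## Pipeline stages and their assumptions

### Within-batch drift correction (QC-SVRC)

LC-MS intensities drift smoothly with injection order. `qc_svrc_correct()`
fits, per feature and batch, an ε-insensitive support vector regression
(radial basis function kernel) of pooled-QC intensity on injection order and
rescales every sample by `reference / trend(injection)`, the reference being
the median QC intensity. Assumptions: QCs are interleaved often enough to
sample the drift (default `min_qc = 5` per batch), and drift is a
feature-wise multiplicative effect. Hyperparameters are data-driven:

* ε = 10 % of the feature's median QC intensity — QC repeatability better
  than that is not worth modelling;
* penalty C chosen from \{10^0^ … 10^4^\} × median QC intensity by
  leave-one-out RMSE over the QCs — with only a handful of QCs per batch,
  LOO is the only resampling with acceptable variance;
* RBF width γ = inverse median pairwise squared injection-order distance.

Numerically, the response is divided by the reference level before fitting
(an exact reparametrisation — cost and ε scale linearly with the response)
because the SVR solver's absolute stopping rule converges much faster near
unit scale; the grid search uses a relaxed tolerance (0.01) and the final
refit the default (0.001). Features with too few QCs, or whose fitted trend
is not strictly positive, pass through unchanged and are flagged
(`skipped_insufficient_qc` / `skipped_degenerate`). Correction never touches
missingness and cannot create negative intensities. Whether between-batch
level alignment should follow is left to the analyst; the correction itself
is strictly within-batch, so batches may be processed in any order.

### Filtering, imputation, scaling

`filter_features()` removes background features (mean study intensity below
3× the mean blank intensity) and features missing in over half the study
samples. `impute_and_scale()` imputes missing and non-positive cells by half
the feature's minimum observed training value, log10-transforms, and
autoscales. All parameters are estimated on the training rows only and
applied frozen to any other rows — this is what keeps cross-validation
honest, so every resampling loop in the package refits the scaler inside the
fold. Zeros on disk are treated as measured zeros, not missing: the
distinction changes imputation, so the readers preserve it (`NA`/empty cell
means missing).

### Univariate screen

`univariate_screen()` reports per-feature Welch t-tests
(unequal variances) with Benjamini–Hochberg adjustment across features and
flags q < 0.05. The screen is reported for interpretation; the model's
feature selection is VIP-based (below), because importance under the
multivariate model and marginal separation answer different questions.

### PLS-DA core

`fit_pls()` implements PLS1 via NIPALS with X-deflation. For a univariate
response the weight vector of each component is the normalised covariance
direction X′y, so fitting is deterministic. The response (+1 target / −1
rest) is centred, not scaled. After A components the regression vector is
b = W(P′W)^{−1}q; score vectors are mutually orthogonal (tested to 1e−8) and
at full rank the fit coincides with least squares (tested to 1e−6).
Variable importance in projection is

$$\mathrm{VIP}_j =
  \sqrt{p \sum_a \mathrm{SSY}_a (w_{ja}/\lVert w_a \rVert)^2 \Big/
        \sum_a \mathrm{SSY}_a },$$

with SSY~a~ the response sum of squares captured by component a; the mean of
the squared VIPs is exactly 1, pinning the scale and motivating the
conventional VIP ≥ 1 selection threshold.

### One-vs-rest ensemble and double cross-validation

`train_ensemble()` fits the three pole models. Per model:

1. The number of latent variables is chosen by subject-wise inner CV
   (default 5 folds) over 1…`max_lv` (default 8), taking the smallest count
   within one standard error of the best accuracy. The one-standard-error
   rule guards against the flat-maximum overfitting typical of PLS accuracy
   curves; plain argmax is available (`lv_rule = "max"`).
2. Stage 1 fits on all features; VIP is computed on this model, fitted to
   the full training partition rather than averaged over folds, because the
   selected set feeds a single refit.
3. Stage 2 recomputes the scaler on the VIP ≥ 1 features and refits.

Patients with any mixed-type sample are excluded from training entirely, as
are unclassifiable samples; both still receive predictions. No class
reweighting is applied; balanced accuracy is reported alongside raw
accuracy.

`double_cv_evaluate()` nests this whole recipe inside an outer subject-wise
loop: each outer fold holds out whole patients, the inner loop re-runs
scaling, complexity selection, and VIP selection from scratch on the outer
training partition, and each sample is predicted exactly once, by the model
that never saw its patient. A canary test in the suite plants a feature that
encodes the label only on held-out samples and checks that it cannot lift
outer accuracy — with fold-internal scaling the canary is constant on every
training partition and is dropped as zero-variance, which is exactly the
leak-freedom being asserted.

### Ternary mapping

The three models predict on the ±1 encoding; `predict()` on the ensemble
also returns the affine membership scale (ŷ + 1)/2, which is what the
simplex mapping consumes: for a sample that is genuinely a convex mixture of
the poles, a linear model trained on pure poles predicts approximately the
mixture weight itself on this scale. `to_ternary()` clips negative
components to zero and normalises to sum 1; a triple that is entirely
non-positive carries no phenotype signal and maps to the barycentre with a
`degenerate` flag. Softmax mapping is available for comparison
(`to_ternary_softmax()`) but compresses confident predictions, so
clip-normalise is the default and is the variant whose percentages read
like the conventional reporting. Residual-DILI thresholds (0.20 minor /
0.40 major on the larger injury coordinate) bracket the range in which
reported episodes describe a recovered patient as still matching an injury
phenotype; the transition threshold (0.15 per coordinate step) sits above
the coordinate-recovery error measured on synthetic cohorts (below), so
annotated transitions exceed estimation noise.

## The synthetic cohort generator

Because patient-level LC-MS data cannot ship with a package, every stage is
validated against `simulate_cohort()`, which generates the structure the
analysis assumes:

* **Latent mixtures.** Each patient starts at a pole or (for mixed
  patients) at a Dirichlet(4, 4, 2) draw over (C, H, R), and moves toward
  the recovered vertex by 10 % per timepoint; 2–4 samples per patient.
* **Metabolite blocks.** On the log2 scale, 40 cholestasis-informative and
  40 hepatocellular-informative features (of 828) shift by ±1.5 on average
  at the pure pole — most upward (bile-acid-like accumulation), 30 %
  downward (glycerophospholipid-like depletion); the recovered pole
  contributes no shift; residual noise SD 0.5.
* **Acquisition artefacts.** Two batches, per-feature linear drift up to
  ±0.3 log2 units across a batch, a pooled-QC injection every 8 study
  injections, 2 blanks per batch, 5 % missingness at random.
* **Clinical chemistry.** ALT/ULN = 0.5 + 8 w~H~ + 0.8 w~C~ + ε and
  ALP/ULN = 0.5 + 3 w~C~ + 0.8 w~H~ + ε with ε ~ N(0, 0.1); bilirubin
  analogous in w~C~ + w~H~. The cross-terms are deliberate: without them no
  mixture can have both enzymes above their limits together with
  2 ≤ R < 5, i.e. the clinical mixed class would be unreachable. The
  constants place pure poles in their rule-based classes with probability
  above 0.95 (asserted in the tests).

Defaults (60 patients; class mix 30 % pure cholestatic, 25 % pure
hepatocellular, 25 % recovered, 20 % mixed) give cohorts of roughly 180
samples — the scale of a single-centre longitudinal DILI study — and the
828-feature width of a typical annotated plasma peak table. The generator
does not emulate m/z structure, adducts, censored (intensity-dependent)
missingness, or drug-specific biology; passing tests demonstrate that the
pipeline recovers the latent mixture *under its own model assumptions*, not
that any particular clinical dataset will behave as well.

With the default conditions (effect 1.5, noise 0.5, 60 patients, 5
simulation seeds) the test suite requires mean double-CV balanced accuracy
≥ 0.90 and mean absolute error ≤ 0.15 between estimated ternary coordinates
and the true weights of held-out mixed-patient samples; with effect 0 or
patient-level label permutation the balanced accuracy must fall inside the
chance band around 1/3. The parameter-recovery runs simulate without drift
so they isolate the classification stages; drift correction is exercised on
its own fixtures (amplitude 0.5 linear drift must at least halve the median
QC RSD) and in the full pipeline run of `scripts/acceptance.R`. Structural
properties that need many replicates — fold integrity, determinism,
effect-size monotonicity of the cross-validated accuracy — run on a reduced
configuration (24 patients, 120 features) whose behaviour mirrors the
default one.

## Numerical and degenerate-input choices

* Injection orders must be unique within batch; validation errors name the
  offending identifiers.
* A peak table written by `write_peak_table()` re-reads bit-identically
  (17-significant-digit decimal round trip) and preserves missingness.
* Rule-based classification is evaluated in a fixed order (recovered →
  hepatocellular → cholestatic → mixed); combinations matching no rule are
  reported as `unclassifiable` rather than coerced — the enzyme rules are
  not exhaustive and silent coercion would bias the class counts. R exactly
  2 is mixed; R ≥ 5 (not > 5) is hepatocellular; both boundaries are
  configurable, and the recovery rule is reported in both readings (enzymes
  only, and enzymes + bilirubin < 1.2 mg/dL).
* Inner-CV folds containing a single class are skipped with a warning; the
  candidate-complexity cap is reduced to the training-matrix rank.
* Zero-variance features are excluded by the scaler and recorded; a VIP
  selection that empties the feature set raises an error suggesting a lower
  threshold instead of silently refitting on nothing.
* All fold deals and the generator are seed-deterministic; retraining with
  the same seed is bit-reproducible.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config(seed = 1))
res <- run_ternary_pipeline(sim$cohort, seed = 1)
print(res)
head(res$predictions[, c("sample_id", "label", "c", "h", "r",
                         "residual_level")])
render_ternary(res$predictions, "cohort.png")
```

`run_ternary_pipeline()` chains correction → filtering → labelling →
training → prediction → mapping → flags → transitions and, by default, the
nested cross-validation report. On a fresh cohort from a manifest, use
`read_cohort_manifest()`; set `corrected: true` in the manifest when the
peak table has already been drift-corrected upstream, in which case the
correction stage is skipped.

## Reference complexity values

When the analogous models were trained on the original deposited cohort of
278 samples × 828 annotated features, the reported complexities were 4
(cholestatic), 5 (hepatocellular), and 3 (recovered) latent variables with
291, 286, and 298 VIP-selected features respectively. These numbers are
recorded here purely as reference points: the package re-derives both
quantities from whatever data it is given and never hard-codes them.

## Known limitations

* The ternary decomposition inherits the linearity of PLS: strongly
  non-linear class boundaries would distort the membership scale.
* Clip-normalisation discards information when two of the three raw
  predictions are negative; such samples sit exactly on an edge or vertex
  of the simplex.
* The generator's missingness is completely at random, while real LC-MS
  missingness is intensity-dependent; half-minimum imputation is mildly
  optimistic in that regime.
* Between-batch level alignment (after within-batch correction) is not
  applied; multi-batch studies with large level offsets should center
  batches beforehand or rely on the autoscaling to absorb offsets.
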