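# midfuse

Mid-level data fusion of multi-sensor panels for herbal drug
authentication and species identification.

Quality control of herbal drugs increasingly replaces subjective sensory
inspection with instrument panels: an electronic nose (gas-sensor array),
an electronic tongue (taste sensors), an electronic eye (color-number
histograms) and near-infrared (NIR) spectra, measured on the same samples.
`midfuse` implements the complete mid-level fusion workflow for two tasks
on such panels — **authenticity** (authentic *Fritillariae cirrhosae*, FC,
vs counterfeit) and **species** (FU / FP / FD / FUS) — for chemometricians
and quality-control analysts who want the whole chain in one reproducible
package:

* **PLS-DA** on indicator-coded classes (NIPALS, X-deflation,
  B = W(PᵀW)⁻¹Qᵀ) with **VIP** selection: VIP_j = √(p · Σₐ SSYₐ (w_{ja}/‖wₐ‖)² / Σₐ SSYₐ),
  where SSYₐ = (tₐᵀtₐ)‖qₐ‖²; squared VIPs average to 1, so VIP > 1 flags
  influential variables.
* **PCA-DA** (principal components, then a pooled-covariance linear
  discriminant δ_k(s) = sᵀΣ⁻¹μ_k − ½μ_kᵀΣ⁻¹μ_k + ln π_k) with backward
  variable elimination on the univariate **Wilks' Λ = SSW/SST**, stopping
  when the leave-one-out accuracy drops.
* **CARS** (competitive adaptive reweighted sampling) for NIR wavelength
  selection: Monte-Carlo PLS fits, an exponentially decreasing forced
  retention schedule (r₁ = 1 down to r_N = 2/p), weight-proportional
  adaptive resampling, and RMSECV-minimizing subset choice.
* **Mid-level fusion**: selected features concatenated (EN, ET, EE, NIR)
  with per-column provenance and a single fused classifier.
* **Evaluation**: leave-one-out cross-validation, confusion matrices,
  accuracy / sensitivity / specificity / precision, ROC and AUC, Welch
  t-tests for model explanation.
* A **synthetic panel generator** with planted species markers and ground
  truth, used for parameter-recovery validation, plus a small command-line
  front-end (`inst/scripts/midfuse.R`) with `simulate` and `run`
  subcommands.

## Worked example

Simulate a four-block panel of 40 samples (10 per species) with weak
planted markers, run the authenticity pipeline, and inspect the report:

```r
library(midfuse)

cfg    <- sim_config(n_per_class = 10, p_nir = 300, delta = 1.2, seed = 42)
panel  <- generate_panel(cfg, task = "authenticity")
report <- run_pipeline(panel$dataset,
                       pipeline_config("authenticity", seed = 42,
                                       cars = cars_config(N = 50, seed = 42)))
report
#> <fusion_report: task=authenticity, blocks: EN+ET+EE+NIR>
#>   fused width 58 (1 latent variables); LOOCV: Ac = 0.9250  Se = 0.9667  Sp = 0.8000  Pre = 0.9355  (n = 40)
#>   AUC = 0.9900

report$confusion
#>              predicted
#> true          FC COUNTERFEIT
#>   FC          29           1
#>   COUNTERFEIT  2           8

head(report$explanation[, c("block", "variable", "vip", "high_contribution")], 3)
#>    block variable      vip high_contribution
#> 31   NIR  9806.02 2.014583              TRUE
#> 7     EE     cnv2 1.646634              TRUE
#> 14   EE    cnv34 1.610817              TRUE
```

Reading the numbers: per-block selection kept 58 fused variables (VIP > 1
for the sensor blocks, CARS for NIR); the fused PLS-DA model with one
latent variable classifies 37 of 40 samples correctly under leave-one-out
cross-validation (accuracy 0.925) — 29/30 authentic (sensitivity 0.967)
and 8/10 counterfeit (specificity 0.80) — with AUC 0.99. The explanation
table ranks fused variables by VIP; here NIR wavelengths and electronic-eye
bins dominate. The generator's ground truth confirms the selection: the
three planted e-nose markers (variables 4, 7, 8) are exactly the ones VIP
selected for that block:

```r
panel$truth$informative$EN     #> 4 7 8
report$selection$EN$indices    #> 4 7 8
```

The same dataset drives the species task with
`pipeline_config("species", ...)`, which switches the per-block selector to
Wilks' Λ backward elimination and the classifier to PCA-DA.

## Command line

```sh
Rscript inst/scripts/midfuse.R simulate --out data/ --seed 7
Rscript inst/scripts/midfuse.R run --data-dir data/ --out results/ \
    --task species --blocks EN,ET,EE,NIR
```

`simulate` writes block CSVs, labels, ground truth and a run manifest;
`run` writes the full report bundle (metrics, confusion, predictions,
selection, provenance, explanation, ROC and CARS trace tables).

See the methods vignette (`vignettes/midfuse-methods.Rmd`) for the models,
parameter meanings, numerical choices and the generator's scope.
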