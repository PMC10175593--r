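---
title: "Mid-level multi-sensor data fusion: models, parameters and design choices"
author: "midfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mid-level multi-sensor data fusion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midfuse)
```

## The problem

Authenticating a herbal drug and identifying its botanical species from
instrument panels is a standard task in pharmacognosy quality control. The
setting this package targets is a four-instrument panel measured on the same
set of samples:

* an **electronic nose** (EN): ~10 metal-oxide gas sensors, one response per
  sensor;
* an **electronic tongue** (ET): ~6 taste sensors;
* an **electronic eye** (EE): a color-number histogram with 65 bins, most of
  them nearly empty;
* **near-infrared spectra** (NIR): ~2075 absorbance readings on a
  12,000–4,000 cm⁻¹ grid.

Samples belong to one of four *Fritillaria* species — FU, FP and FD are
authentic *Fritillariae cirrhosae* (FC), while FUS is the counterfeit — and
two classification tasks follow: **authenticity** (FC vs counterfeit) and
**species** (four classes). No single instrument captures all of the
relevant chemistry, which motivates **mid-level data fusion**: select the
informative variables of each block, concatenate the selected features, and
fit one classifier on the fused matrix.

## Models

### PLS-DA (authenticity)

Partial least squares discriminant analysis regresses the mean-centered
class indicator matrix $Y$ ($n \times m$, one column per class) on the
pretreated data $X$. Components are extracted by NIPALS with X-deflation
only; the regression coefficients are $B = W(P^\top W)^{-1}Q^\top$. A new
sample is assigned the class with the largest predicted indicator; exact
ties go to the first class in coding order and are counted. Both classes get
an indicator column even in the binary task, which keeps the multi-class
case uniform and makes VIP symmetric in the classes.

Variable importance in projection weights each component's normalized
squared weights by the response sum of squares that component explains:

$$\mathrm{VIP}_j=\sqrt{p\,\frac{\sum_a \mathrm{SSY}_a\,(w_{ja}/\lVert
w_a\rVert)^2}{\sum_a \mathrm{SSY}_a}},\qquad
\mathrm{SSY}_a=(t_a^\top t_a)\,\lVert q_a\rVert^2 .$$

Squared VIPs average to one, so VIP > 1 flags variables contributing more
than average; that is the per-block selection rule for the authenticity
workflow.

### PCA-DA (species)

Principal components are computed on the pretreated matrix and a linear
discriminant classifier with pooled within-class covariance is fit on the
first $A$ scores:
$\delta_k(s)=s^\top\Sigma^{-1}\mu_k-\tfrac12\mu_k^\top\Sigma^{-1}\mu_k+
\ln\pi_k$. Every sample receives a class (no "unclassified" outcome). The
species workflow selects block variables by backward elimination on the
univariate **Wilks' lambda** $\Lambda = SSW/SST \in [0,1]$ (small = more
discriminating): the largest-$\Lambda$ variable is tentatively removed, the
model refit, and the removal undone — stopping the loop — as soon as the
leave-one-out accuracy drops below the best value seen.

$\Lambda$ is sometimes described loosely as a within-to-between variation
ratio; this package implements the standard within-to-total form, which is
bounded in $[0,1]$ and consistent with "smaller is more discriminating".

### CARS (NIR wavelength selection)

Competitive adaptive reweighted sampling runs $N = 100$ Monte-Carlo rounds.
Each round draws 80% of the samples, fits a mean-centered PLS model on the
currently retained wavelengths, and weights wavelength $j$ by the row norm
of its regression coefficients. Two forces shrink the retained set: forced
retention of the top-weight wavelengths down to the exponentially decreasing
count $\mathrm{round}(r_i\,p)$ with $r_i = a e^{-k i}$ calibrated so
$r_1 = 1$ and $r_N = 2/p$, followed by adaptive reweighted sampling
(weight-proportional draws with replacement; the retained set is the union
of the draws, so duplicates shrink it further). Each round's subset is
scored by 10-fold RMSECV on all samples, and the round with the minimal
RMSECV (earliest on ties — avoiding a bias toward the smallest subsets)
provides the selected wavelengths. The early rounds remove wavelengths
aggressively (fast selection), late rounds refine.

The inner PLS component count is chosen once on the full data by 10-fold
RMSECV and then held fixed, and the cross-validation fold assignment is
fixed across rounds so RMSECV values are comparable; both choices trade a
little adaptivity for stability and determinism. The response driving CARS
is the class indicator matrix; the species coding is the default because it
preserves the full class structure (the config can switch to the active
task's coding).

## The fusion pipeline

`run_pipeline()` chains the steps: per-block selection (VIP for
authenticity, $\Lambda$-stepwise for species, always CARS for NIR) →
column-wise concatenation in the fixed order EN, ET, EE, NIR with per-column
provenance → dimensionality choice by leave-one-out accuracy (smallest
count on ties) → final fit → leave-one-out evaluation (confusion matrix,
accuracy, sensitivity, specificity, precision, and ROC/AUC for binary
tasks) → explanation tables (VIP > 1 flags for authenticity; $\Lambda$ <
0.3 flags for species; Welch t-tests of each fused variable between the two
classes of a binary task).

By default variable selection is performed once on all samples and held
fixed during the evaluation LOOCV, matching the sequential
select-then-model procedure of the studies this package emulates. This
optimistically biases the reported accuracy; a nested mode
(`nested = TRUE`) refits the selection inside every fold at substantial
cost. Similarly, the automatic component counts are taken at the maximum of
the LOOCV accuracy curve, and the same curve value is reported — a
non-nested choice that is standard practice in this literature, not an
unbiased generalization estimate.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `vip_threshold` | 1.0 | VIP selection cut; 1 is the "above average" point forced by the normalization |
| `lambda_report_threshold` | 0.3 | report-level flag for highly discriminating fused variables; separate from the stepwise stopping rule |
| `max_lv` / `max_pc` | 10 | search caps for PLS components / retained PCs (also capped at $n-2$ resp. $n-g-1$ and the rank) |
| CARS `N`, `folds`, `ratio` | 100, 10, 0.8 | Monte-Carlo rounds, RMSECV folds, calibration sampling fraction |
| block pretreatment | mean centering | the only pretreatment the emulated workflow states |
| fused pretreatment | autoscaling | the blocks live on very different scales (counts vs absorbance); set `"center"` to mimic raw concatenation |
| `priors` (PCA-DA) | proportional | class priors; `"uniform"` is available and is what the null-calibration checks use (see below) |

## Numerical choices

* NIPALS starts each component from the indicator column with maximal
  variance (deterministic; there is no randomness anywhere in the PLS or
  PCA-DA fits) and iterates to a relative score change of $10^{-10}$, at
  most 500 iterations. When the cross-product matrix has near-tied
  eigenvalues — common on class-structured data — power iteration converges
  only geometrically; the component is then accepted at the iteration cap,
  since any vector in the near-tied subspace yields an equivalent fit.
  Rank-exhausted components are an error naming the component.
* Centering/scaling models are fit on training rows only and reused on test
  rows everywhere, including inside every cross-validation fold.
* Argmax ties in both classifiers go to the first class in coding order and
  are counted on the prediction object.
* Zero-variance columns are tolerated under plain centering (they receive
  zero weight) but are an error under autoscaling, naming the column.
  Missing values are rejected at the data boundary rather than imputed.
* All randomness (CARS sampling, RMSECV folds, the generator) flows through
  explicit seeds; a fixed seed reproduces every result bit for bit.

## The synthetic panel generator

Real panels of this kind are rarely published as raw matrices, so
`generate_panel()` creates panels with the statistical structure the
analysis assumes, plus ground truth for recovery testing. Defaults mirror
the emulated study design: 20 samples per species (n = 80), block widths
10/6/65/2075, three replicate measurements per sample that are averaged into
the analysis matrix.

Each block carries a few **planted marker variables**. A marker elevates
exactly one authentic species by `delta` noise standard deviations (default
`delta = 3`); all other classes, including the counterfeit FUS, sit at the
baseline. This mimics species-specific marker compounds, makes FUS the
"low on every marker" class, and — deliberately — makes the planted set
minimally redundant: removing any marker collapses its species onto FUS, so
a selection method that works should retain all markers. Electronic-eye
bins are near zero except the planted ones (sparse histogram); sensor
responses are clipped at zero. NIR spectra are a common linear baseline
plus Gaussian peaks (default width 60 cm⁻¹) with i.i.d. noise; a subset of
peaks has species-elevated amplitudes, and the informative wavelengths are
the grid points within one FWHM of those peak centers.

What the generator does **not** emulate: instrument drift and batch
effects, heavy-tailed or correlated sensor noise, within-class chemical
heterogeneity (geographic origin), and the actual alkaloid chemistry.
Passing recovery tests therefore demonstrates that the algorithms find the
kind of structure they are designed for — not that they would reach any
particular accuracy on real panels.

## Validation design and problem sizes

The package's study-level checks (see `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`) use the following problem sizes, chosen to make
each property measurable at desk scale:

* worked-example metrics are reconstructed from published per-class
  misclassification counts on 80 samples and must match the printed
  accuracies exactly;
* oracle equivalences (NIPALS vs least squares, PCA-DA vs direct LDA, AUC
  vs pair counting, the LOOCV driver vs a hand-coded loop) run on random
  20×8 instances;
* marker recovery runs 20 default panels (n = 80); CARS recovery runs 20
  panels of 60 samples × 200 wavelengths with five planted single-wavelength
  markers of 3σ — the recovery property does not depend on the grid size,
  and the reduced grid keeps the full validation suite fast;
* the fusion-benefit check uses `delta = 1` ("weak signal") so that single
  blocks do not saturate, and counts a tie as success, since fusing cannot
  be expected to improve on a perfect single block;
* null calibration uses `delta = 0` panels. The accuracy band is binomial
  at the sample size aggregated over the 20 panels because LOOCV
  predictions within one panel are dependent — a single noise direction can
  mislead every fold — so the per-panel i.i.d. band would be
  anti-conservative. These checks run PCA-DA with **uniform priors**:
  with class-proportional priors the held-out sample's class always has the
  smallest training prior, which on signal-free data pushes LOOCV accuracy
  far below chance. That artifact belongs to the validation scheme, not to
  the generator, and uniform priors remove it.

## Known limitations

* The default (non-nested) evaluation reports selection-biased accuracy by
  design, to match the emulated workflow; use `nested = TRUE` for honest
  generalization estimates.
* PLS-DA's argmax rule has no "unclassified" outcome and no reject option.
* The pooled-covariance discriminant assumes equal class covariances;
  no regularized or quadratic variants are provided.
* CARS assumes the indicator-regression RMSECV is a meaningful proxy for
  classification quality; with many classes and few samples per fold this
  can be noisy, which is why the fold assignment is held fixed.
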