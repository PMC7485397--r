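---
title: "Deep-learning radiomics for breast ultrasound and shear-wave elastography: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learning radiomics for breast ultrasound and shear-wave elastography: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

B-mode ultrasound is sensitive but not specific for distinguishing benign
from malignant breast masses; shear-wave elastography (SWE) adds a
quantitative stiffness map (Young's modulus in kPa per pixel) because
malignant tissue is typically much stiffer than benign tissue, with the
stiffest tissue often in the peritumoral rim rather than the mass itself.
`swerad` implements a complete deep-learning radiomics pipeline on paired
B-mode/SWE images: lesion patches feed a small convolutional network, the
activations of its penultimate fully connected layers become quantitative
image descriptors ("deep radiomic features"), a reproducibility screen and
a sparse regression turn them into a per-patient *rad-score*, and a
diagnostic-statistics battery compares that score against quantitative SWE
parameters and an ordinal reader category.

Because no public image set accompanies this kind of study, the package
ships a first-class synthetic phantom generator so that every stage is
exercisable and testable end to end without downloads.

## The synthetic phantom generator

`cohort_spec()` / `generate_cohort()` emulate the statistical structure the
analysis relies on, not ultrasound physics:

* **Geometry.** Lesions are smooth star-convex blobs built from random
  radial harmonics (four harmonics, amplitudes shrinking with frequency)
  rather than ellipses, so ROI and bounding-box code faces realistically
  irregular boundaries. Default diameters are 3–6 mm at 0.1 mm/px spacing.
* **Elasticity.** The background sits at a fatty-tissue baseline
  (9 kPa) with smooth spatial variation. Lesion pixels are drawn around a
  class mean (defaults 20 kPa benign, 120 kPa malignant, additive noise
  SD 5 kPa) with multiplicative log-normal speckle whose log-SD is the
  per-class `texture_heterogeneity` (0.05 benign, 0.35 malignant).
  Malignant lesions additionally carry a ~1 mm peritumoral rim annulus
  (dilation minus mask) boosted by `rim_stiffness_boost` (60 kPa),
  implementing the observation that peritumoral tissue is stiffest. Maps
  are clamped at zero.
* **Contouring convention.** Masses with a stiff rim (non-homogeneous, in
  practice the malignant ones) get SWE masks dilated to cover adjacent
  tissue; homogeneous masses are contoured at the border. The convention
  lives in the generator because contouring is a human act; the pipeline
  itself consumes whatever masks it is given. In a null cohort (no rim)
  both classes are therefore contoured identically — this matters for the
  anti-leakage check below.
* **B-mode.** Bright gland background with speckle; lesions are
  hypoechoic with per-class interior brightness
  (`bmode_lesion_brightness`, defaults 0.42 benign / 0.28 malignant) and
  the class's own speckle heterogeneity. Intensities are quantized to
  8 bits so PNG round trips are exact.
* **Raters.** `perturb_mask()` emulates a second rater or repeat session
  by adding a smooth random field to the signed distance transform of a
  mask; because the signed distance has unit gradient along the boundary,
  the field amplitude directly bounds the boundary displacement in
  pixels. `magnitude = 0` is the identity and every draw is seeded.
* **Ordinal reader category.** A noisy ordinal function of the label
  (configurable error rate) on the conventional 3/4a/4b/4c/5 scale. It
  exists solely to exercise the comparison statistics and makes no claim
  of modelling radiologists.

What the phantoms deliberately do **not** model: acoustic speckle
statistics, attenuation and shadowing, operator pressure artefacts,
vendor-specific stiffness estimation, or histologic subtype diversity.
Passing end-to-end tests on phantoms therefore demonstrates that the
pipeline's statistical machinery is correct and leak-free — not that the
trained networks would transfer to clinical images.

## Patch extraction and segmentation agreement

`extract_patch()` crops the axis-aligned bounding box of the lesion mask
(optionally expanded by a margin, clipped to the frame), min–max scales
intensities to [0, 1] per patch (a constant crop maps to zeros) and
bilinearly resamples to the network input, 302 × 430 (height × width) at
full resolution. Masks are never resampled. Whether intensities should be
normalized per patch before the network is an open choice; min–max per
patch is this package's convention and is recorded here. Grayscale input
is replicated to three channels so a single architecture serves both
modalities.

Segmentation agreement uses the Dice coefficient
\(2|A\cap B| / (|A|+|B|)\) with the conventional bands (0.75–1.00
excellent, 0.50–0.74 good, 0.25–0.49 moderate, < 0.25 poor). Band edges
are closed on their printed two-decimal endpoints; a value in an unprinted
gap (e.g. 0.745) falls to the lower band.

## Quantitative SWE parameters

Four parameters per case, with the clinical ROI conventions:

* `place_max_stiffness_roi()` searches every circle center lying within
  the lesion mask dilated by one ROI radius — the smallest neighbourhood
  consistent with "within or adjacent to the mass" — keeping the circle
  inside the acquisition box, and maximizes mean elasticity. The 2 mm²
  round ROI becomes a radius of \(\sqrt{2/\pi}/s\) px at spacing
  \(s\) mm/px. Ties break to the smallest row then column, so placement
  is deterministic; a brute-force search over all centers reproduces it
  exactly on small maps.
* `place_fat_roi()` places the reference ROI fully inside the fatty
  tissue and the acquisition box, at the fat pixel farthest from the
  lesion.
* `compute_quant_params()`: E_max and E_mean are the max/mean over the
  lesion ROI; E_ratio is the lesion-ROI mean over the fat-ROI mean (the
  assumption that the numerator comes from the same 2 mm² lesion ROI is
  implied by the measurement workflow and adopted here); E_SD is the
  standard deviation over a round ROI "adjusted to the mass contour",
  realized as the maximum inscribed circle of the lesion mask via the
  distance transform. The SD uses the population (n) denominator by
  default because the device convention is unknown; the sample convention
  is a switch.
* `aggregate_repeats()` applies the clinical triplicate rule: maximum of
  E_max, median of the others. On phantoms, repeats are simulated by
  re-running placement after seeded kPa jitter.

## The network and the 768 deep radiomic features

The extractor is a small CNN: two blocks of 3 × 3 same-padded convolution
(depths 32 and 64, ReLU) each followed by 2 × 2 max pooling, then fully
connected layers of 512 (dropout 0.5), 256 and 2 nodes trained with
categorical cross-entropy under plain SGD (learning rate 0.01, 80 epochs
at full scale) on an 8:2 stratified internal split, with on-the-fly
horizontal/vertical flips and rescaling of the training stream; the
checkpoint with the best internal-validation accuracy is kept. The deep
radiomic features are the concatenated activations of the 512- and
256-node layers in inference mode — 768 values regardless of input size.

No deep-learning framework is involved: convolution is im2col plus BLAS
matrix products, with hand-derived backpropagation verified against
finite differences. Choices a framework would normally hide are fixed and
recorded on the trained model rather than guessed: He initialization,
batch size 8, no momentum, rescaling augmentation as a random zoom in
[0.9, 1.1], features taken **post**-ReLU, accuracy as the
model-selection metric, and "second and third to the last" fully
connected layers read as the 256- and 512-node layers (the last being the
2-node output), which is exactly what makes the dimension 768.

One practical note on geometry: at the full 302 × 430 input the first
fully connected layer holds over 2.6 × 10⁸ weights, which R can describe
(`build_network()`) but should not train on a laptop. The package
therefore runs its own studies at reduced inputs (the desk default is
48 × 64; tests also exercise 96 × 128), which preserve the layer
structure and the 768-dimensional embedding while shrinking only the
flattened convolutional map. The vignette's problem sizes below are the
package's chosen desk-scale study conditions.

## Feature reproducibility screening

The first selection step recomputes features under a repeat session of
rater 1 and under rater 2 (on phantoms: `perturb_mask()` stand-ins), then
keeps features whose intra-rater **and** inter-rater ICC exceed 0.6
(strict inequality, matching the conventional "satisfactory agreement"
cutoff). The ICC form is not standardized in this setting; the package
defaults to ICC(2,1) — two-way random effects, absolute agreement, single
measures — because raters are interchangeable measurement devices here,
with ICC(3,1) available as an option. Zero-variance features (dead ReLU
units are common) have undefined ICC; they get `NA` and are dropped
rather than raising an error mid-screen. The per-feature significance
comparison between readers' selected feature sets reported in some
studies has no defined test statistic and is deliberately not
implemented.

## LASSO rad-score and thresholds

The second and third steps fit an L1-penalized logistic regression
(glmnet) on the ICC-retained features, with the penalty chosen by
stratified cross-validation on the binomial deviance at `lambda.min`.
Features are standardized first (mean 0, SD 1) and the standardization is
stored in the model, so coefficients are on the standardized scale — the
serialized JSON flags this. Non-zero-coefficient features form the
signature; the rad-score is the linear predictor
\(\beta_0 + \sum_j \beta_j x_j\). Score orientation (whether higher means
malignant) is set automatically so the training AUC is at least 0.5 and
recorded in the model. The classification threshold maximizes the Youden
index over midpoints of adjacent sorted unique scores, with ties broken
toward higher specificity and then the lower threshold.

Two frozen reference signatures (7 B-mode features, intercept 3.6044336;
4 SWE features, intercept 2.496014) ship as JSON fixtures under
`inst/extdata/`. They validate the rad-score arithmetic; synthetic runs
select their own, different indices, and no attempt is made to reproduce
published coefficients, which would require the original images.

## Diagnostic statistics

The reporting layer mirrors the standard diagnostic-performance table:
sensitivity and specificity as count fractions with exact
Clopper–Pearson 95% CIs; positive/negative likelihood ratios
(`sens/(1−spec)`, `(1−sens)/spec`) with Simel log-method CIs on the
counts, infinite PLR rendered as ∞ and CIs omitted at infinite or zero
point estimates; Jaeschke interpretation bands (> 10 or < 0.1 large,
5–10 or 0.1–0.2 moderate, otherwise small); AUC as the Mann–Whitney
statistic with DeLong structural-component variance, CIs and paired
z-tests; McNemar tests (exact binomial below 25 discordant pairs,
continuity-corrected chi-square above); Bonferroni correction; and
Table-1-style cohort comparisons (Student's t when both groups pass
Shapiro–Wilk, otherwise Mann–Whitney U; chi-square for categoricals).
The CI methods are this package's documented standards — proportion and
LR interval methods are rarely stated in clinical reports, so published
intervals are not chased. Rendered percentages round half up to
integers, likelihood ratios print to two decimals except values ≥ 100,
which print as integers.

A classifier that calls no case positive (possible on null phantoms) has
undefined likelihood ratios; its report row carries `NA` rather than
aborting the run.

## The pipeline and its guarantees

`run_pipeline()` executes simulate → perturb → patch → train → extract →
ICC-filter → LASSO → SWE quantification → evaluate → report for both
modalities, writing every artifact (signature JSONs, feature and ICC
CSVs, per-cohort tables, rad-score scatter data, a seeded run log) under
one run directory stamped with a config hash. Case ids of the three
cohorts must be disjoint; an overlap aborts the run before any training.
The "combined quantitative SWE parameters" row is an unpenalized logistic
combination of the four parameters fitted on the training cohort only —
how such a combination is built is never stated in clinical reports, so
this choice is documented rather than claimed equivalent. All stage seeds
derive from one master seed; two runs from the same configuration are
byte-identical.

The desk-scale study conditions (`desk_config()`): training 20/20,
independent validation 8/8, external validation 4/4 benign/malignant
cases at 128 × 128 px, network input 48 × 64, 12 epochs. Under strong
separation (100 kPa stiffness gap, distinct texture and echogenicity)
both modality signatures reach validation AUC ≥ 0.95. The complementary
null configuration (`null_cohort = TRUE`) draws both classes from one
distribution — equal stiffness, equal heterogeneity, equal echogenicity,
no rim, hence identical contouring — and the validation AUC must stay
near 0.5; this is the anti-leakage guard. Early versions of the
generator failed it by encoding the label in echogenicity and mask
dilation even at zero separation, which is exactly the class of bug the
check exists to catch.

## Numerical choices and degenerate inputs

* Band classifications are closed on printed endpoints; gaps fall to the
  lower band. ICC above 1 and Dice outside [0, 1] are rejected.
* ROI placement tie-breaks are scan-order (smallest row, then column)
  everywhere, making placement reproducible.
* Empty masks, single-class label vectors, zero denominators, zero fat
  means, non-triplet repeat sets and mismatched shapes raise typed
  errors early.
* The elasticity TIFF is 32-bit float, stored as kPa/1000 (float TIFFs
  carry [0, 1]); round trips are exact to float32 precision.
* Max pooling on odd dimensions floors (drops the last row/column), so
  the full 302 × 430 geometry is valid.

## Known limitations

* Phantom realism is intentionally minimal (see above); absolute
  performance numbers on phantoms say nothing about clinical images.
* Training the full 302 × 430 geometry is out of desk reach in pure R;
  the architecture is still constructible and the geometry reported.
* ICC forms other than (2,1)/(3,1), decision-curve analysis, calibration
  and sample-size planning are out of scope.
* The CNN trains per modality from scratch; no transfer learning or
  released clinical weights are involved.
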