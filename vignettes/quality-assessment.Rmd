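---
title: "Radiomics-based image quality assessment for breast DCE-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics-based image quality assessment for breast DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dynamic contrast-enhanced breast MRI is acquired under tight temporal
constraints, which makes it prone to noise, blurring, incomplete fat
suppression, ghosting from cardiac flow, and stripe ("zebra") artifacts.
Large imaging repositories need an automatic, *no-reference* way to flag
series whose quality is too low for analysis. `dceqc` implements such a
pipeline: from a single post-contrast 3D volume it samples 2D slices,
extracts an interpretable radiomic description of the image and of an
automatically located air-background region, classifies the patient as
high (0) or low (1) quality with patient-level cross-validation, and
explains the decision with Shapley attributions. Because expert-annotated
quality labels are not redistributable, the package carries a synthetic
phantom generator so every stage is testable end to end.

## Slice sampling

Two scenarios are supported and tagged on every slice:

* **twelve_slice** — the through-plane range is split into thirds and 3, 6
  and 3 evenly spaced slices are drawn from the bottom, middle and top
  third. Even spacing uses linearly spaced positions inclusive of the third
  boundaries, rounded to the nearest integer; rounding collisions shift to
  the nearest unused in-range index (lower index on ties). Whenever the
  middle third holds at least 6 slices this yields an exact 3/6/3 split;
  for very short stacks (12–16 slices) the shifts necessarily spill across
  a third boundary while still returning 12 unique indices. Sampling many
  slices makes the decision robust to local degradations (coil sensitivity,
  clips, partial coverage).
* **middle_slice** — the single slice at `floor(Z/2)` (floor chosen as the
  deterministic convention for even `Z`), which is dominated by anatomy and
  is strongly representative of the protocol's global quality.

The through-plane axis is inferred as the axis with the largest voxel
spacing (DCE acquisitions are anisotropic), with an explicit override for
unusual headers.

## Regions of interest

Each slice contributes two ROIs:

* the **whole image**, and
* a **background** region built from two corner squares, each
  `floor(H/8) x floor(W/8)` pixels anchored flush to the image corners.

Corners are scored by SNR = mean / (population SD + 1e-6). Among the four
*non-diagonal* corner pairs, the pair with the smallest total SNR is taken:
low-SNR corners are the most anatomy-free and therefore isolate noise and
artifacts best. The non-diagonal constraint keeps the two squares on one
image edge, which holds for both axial and sagittal orientations (anatomy
enters from one side). Ties are broken in the fixed order
(TL,TR) < (BL,BR) < (TL,BL) < (TR,BR) so runs are reproducible. The two
squares are pooled into one union mask for feature extraction; extracting
them separately and averaging was the alternative and is noted as such.

## Normalization and discretization

Each slice is z-scored with whole-slice statistics (population SD), so both
ROIs live on one scale. Statistics are per-slice rather than per-volume
because both ROIs are 2D objects of the slice being analyzed; a
whole-volume variant can be obtained by normalizing the volume upstream.

Texture matrices require discretized gray levels. We use IBSI fixed bin
size (FBS), `level(x) = floor((x - min)/w) + 1`, with default width 54 —
the width a mean ROI intensity range near 3456 yields at a fixed bin number
of 64 (`derive_bin_width()`), with `w = 1` as the "no discretization"
regime for integer-valued data. A width of 54 is only meaningful on the
*native* intensity scale, while the filter bank runs on the z-scored slice.
Because FBS is min-referenced and scale-equivariant, discretizing the
z-scored filtered image with an effective width `w / sd(raw slice)` is
algebraically identical to discretizing the raw-scale filtered image with
width `w`; this is the default (`discretize_on = "raw"`). The literal
interpretation (`"normalized"`) is exposed for comparison, since the
ordering of normalization and discretization is a genuinely open choice.

First-order Entropy and Uniformity are histogram features and use the same
FBS levels as the texture matrices; the other 16 first-order features use
the z-scored intensities directly.

## The feature bank

Nine filtered images are produced per slice: the original, four one-level
coif1 wavelet subbands (LL/LH/HL/HH, symmetric extension, subbands restored
to slice size by pixel replication so a single ROI mask fits all filtered
images), and four Laplacian-of-Gaussian responses at sigma 2, 3, 4, 5
pixels (Gaussian truncated at three sigma, then the 5-point Laplacian,
symmetric boundaries). Per filtered image and ROI we compute 91 features:

| class       | count | matrix |
|-------------|------:|--------|
| first-order |    18 | intensity histogram |
| GLCM        |    22 | symmetric co-occurrence, distance 1, 4 in-plane directions averaged |
| GLDM        |    14 | dependence, 8-neighbourhood, tolerance 0 |
| GLRLM       |    16 | run lengths, 4 directions averaged |
| GLSZM       |    16 | 8-connected size zones |
| NGTDM       |     5 | neighbourhood gray-tone differences |

for 91 x 9 = 819 radiomic features per ROI, split 162 first-order + 657
textural (198/126/144/144/45 per class). Two no-reference metrics
(BRISQUE-style score and total variation) complete the 821-dimensional
vector. In combined mode the background vector is appended with a `_bg`
suffix (1642 values). These count identities are asserted when the
extraction config is built.

The GLCM set is the standard 22-feature list (the redundant dissimilarity
and sum-average measures are excluded). The GLDM dependence index counts
the centre pixel plus its dependent neighbours, so the `1/j^2`
small-dependence weights are always defined. Degenerate inputs take fixed
analytic conventions: on a constant region GLCM correlation is 1, the
information measures are 0, all contrasts and entropies are 0,
uniformity-type measures are 1, and NGTDM coarseness (1/0) is capped at
1e6. Masked-out pixels never pair with masked-in pixels, break runs, and do
not count as neighbours.

## No-reference metrics

**Total variation** is the anisotropic sum of absolute horizontal and
vertical neighbour differences, normalized by pixel count. Noise raises it;
blur lowers it.

**BRISQUE-style score.** The full 36-feature natural-scene-statistics front
end is implemented: MSCN coefficients (7x7 Gaussian local mean/SD, C =
1/255), a GGD moment fit to the MSCN field and AGGD fits to the four
pairwise-product orientations, at the native and a 2x downsampled scale.
The published mapping from these features to an opinion score is a trained
regression on human ratings of natural photographs; no such model is
shipped here. Instead the scalar score is the Mahalanobis distance between
a slice's 36 features and pristine-image statistics fitted on clean
synthetic phantom slices (`inst/extdata/brisque_pristine_stats_synthetic.csv`,
a synthetic asset by construction) — the same construction NIQE uses.
Higher means worse; the score is finite on constant images thanks to the
stabilizers. Background-ROI metrics are computed on the bounding band of
the two selected corner squares; the standalone minimum image side of 32 is
relaxed to 4 in the extraction path because corner bands of small matrices
are narrow.

## Feature selection

A three-step cascade, fitted on training folds only:

1. variance threshold 0.05 on the raw feature variance (this subsumes plain
   zero-variance removal, reconciling the two readings of that rule);
2. per-feature one-way ANOVA between the label groups, keeping `p < 0.05`
   (a top-k variant is exposed, since the retention rule is a free choice);
3. L1-penalized logistic regression on standardized features at inverse
   regularization C = 0.5 (lasso penalty `lambda = 1/(n C)`), keeping
   features with non-zero coefficients.

The fitted selector stores the surviving names and the training
mean/SD, and applying it to test data only standardizes and subsets — a
mutation test corrupting test folds verifies nothing fitted changes.

## Classification, cross-validation and voting

Six classifiers are supported: logistic regression, SVM with RBF kernel
(probabilities via internal Platt calibration on the training fold), KNN
(k = 5), random forest (500 trees), AdaBoost (SAMME over depth-1 stumps,
50 rounds, probability from the logistic of the normalized margin), and
Gaussian naive Bayes. Hyperparameters beyond those the pipeline fixes are
library defaults, frozen in the configuration.

Folds are stratified *by patient*: patients are shuffled within class
(seeded) and dealt round-robin, so per-fold class counts are within one
patient of balance and all slices of a patient share a fold. Per-slice
class-1 probabilities are soft-voted into one patient probability (mean),
thresholded at 0.5; an exact tie votes high quality (0), a documented
convention since the threshold rule does not state a tie direction. Class 1
(low quality) is the positive class for sensitivity. Fold metrics are
aggregated as mean +/- population SD across folds, and the best fold is the
one with the highest accuracy, ties broken by AUC then by the lowest fold
id.

## Explanation

`kernel_shap()` implements Kernel SHAP: coalition values are expectations
over a training-fold background set (subsampled to at most 100 rows,
seeded), and the kernel-weighted least squares problem is solved with the
sum constraint eliminated analytically, so local accuracy
(`base + sum(phi) = output`) holds exactly on every explained sample. All
`2^m` coalitions are enumerated for m <= 11 selected features; above that,
coalitions are sampled by kernel weight. The best CV fold is explained on
its held-out test rows (the training rows serve as background), and
`summary_ranking()` orders features by mean absolute attribution, as in the
usual SHAP summary plot (`plot_shap_summary()`).

## The phantom generator

`phantom_spec()` describes an MRI-like volume: an ellipsoidal anatomy
region with a radial intensity gradient and smooth internal texture on a
dark air background with mild Gaussian noise, plus a bright chest-wall band
at the bottom of each slice; intensities sit on a DCE-like native scale
(anatomy around 3000–3900) so the default bin width of 54 yields about 64
whole-image gray levels. `degradation_spec()` applies, in order: Gaussian
blur, multiplicative sinusoidal zebra stripes, a shifted attenuated ghost
copy, and additive Gaussian (optionally Rician magnitude) noise. A severity
score `s = noise/60 + blur/1.5 + zebra/0.2 + ghost/0.25` labels a volume
low quality at `s >= 1`; cohort draws leave a guard band around the
threshold (class 0 stays below s = 0.5, class 1 above s = 1.1) so synthetic
classes are cleanly separable — the point of the cohort is to test pipeline
correctness, not to probe a classifier frontier. Consequently, perfect
synthetic scores demonstrate that the plumbing (sampling, ROIs, features,
selection, voting) preserves a strong quality signal; they say nothing
about performance on real data, where degradations are subtle, correlated
with anatomy, and labelled with expert disagreement. The generator also
does not model k-space physics, coil sensitivity profiles, susceptibility
or motion.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on 96x96x20
phantoms: 110 + 110 patients for the middle-slice scenario and 30 + 30
patients (12 slices each) for the soft-voting scenario — sizes chosen so
the whole synthetic study re-runs in a few minutes on one CPU while keeping
the published cohort structure for the middle-slice arm. All randomness
descends from explicit integer seeds: phantom voxels, severity draws, fold
assignment, classifier fitting and SHAP sampling are each seeded, and two
runs with the same configuration produce identical feature tables.

## Known limitations

* 2D extraction only; no 3D texture, and no shape features (there is no
  anatomy mask).
* The BRISQUE-style scalar is a pristine-distance score, not the published
  opinion-score regression; its 36 underlying features are standard.
* The wavelet family is fixed to coif1 at one level.
* Whether background squares should be pooled or averaged, whether
  normalization is per-slice or per-volume, and the ANOVA retention rule
  are open choices; the defaults above are exposed as configuration.
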