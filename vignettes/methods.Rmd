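---
title: "Detecting ischemic stroke in CTA source images with a dual-pathway 3D CNN: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acute ischemic stroke appears on CT-angiography source images (CTA-SI) as
*hypoattenuation*: tissue with reduced contrast enhancement because blood
flow to it is delayed or absent. Segmenting these regions voxel by voxel,
and then reading the segmentation at the level of the ten ASPECTS regions
per hemisphere (the six middle-cerebral-artery cortical segments M1–M6,
insular ribbon I, lentiform nucleus L, caudate C, internal capsule IC),
gives both a lesion volume estimate and a clinically interpretable score:
ASPECTS points are 10 minus the number of stroke-positive regions, taking
the worse hemisphere.

The central difficulty is that normal aging produces *symmetric*
hypoattenuation — periventricular white-matter change (leukoaraiosis) and
widened cortical sulci — that locally mimics ischemia. A detector that
only looks at local intensity therefore produces false positives in
exactly these places. The remedy exploited here is that ischemic stroke of
the middle cerebral artery territory is (in the cohorts of interest)
unilateral, while aging changes are bilaterally symmetric: each voxel's
approximate contralateral homolog is supplied to the classifier as an
extra image channel, the *hemispheric comparison volume*, built by
flipping the CTA left–right and rigidly registering the flipped volume
back onto the original.

This package implements the full analysis desk-scale: a synthetic phantom
cohort generator, the preprocessing chain, a patch-based dual-pathway 3D
convolutional network with its training recipe, and the two-level
evaluation, behind one pipeline.

## The network

The segmentation model is a two-pathway, multi-scale, patch-based 3D CNN
of the DeepMedic family. The normal-resolution pathway sees a small cube
at full resolution; the context pathway sees the same location in a
mean-pooled (factor 3) version of the volume, so its receptive field
covers roughly three times the physical extent. Both pathways are stacks
of unpadded 3×3×3 convolutions with ReLU; the context pathway's output is
upsampled by voxel repetition, concatenated with the normal pathway's
output, and passed through 1×1×1 hidden and classification layers with a
per-voxel two-class softmax. Because convolutions are unpadded, an output
segment of edge *o* requires a normal-pathway input patch of edge
*o + 2L* for *L* convolution layers, and a context patch of edge
*o/3 + 2L*.

The default desk-scale configuration is depth 6 (four convolution layers
of 8, 8, 12, 16 hidden filters; patch 17³, context 11³, output 9³),
trainable in about a minute on one CPU. The published full-scale depth of
11 (eight convolution layers, two hidden layers) is reachable through
`networkConfig()`.

Training follows the published recipe, all exposed in
`trainingConfig()`: voxel-wise two-class cross-entropy (the loss itself is
unpublished; cross-entropy is the standard choice for this family) with
L1 = 1e-6 and L2 = 1e-4 penalties, RMSprop (ρ = 0.9, ε = 1e-4) with
Nesterov momentum 0.6, batches of 10 segments, 35 epochs × 15 sub-epochs,
initial learning rate 0.001 halved at eight predefined epochs. The update
rule is

    r <- rho * r + (1 - rho) * g^2
    step <- -lr * g / sqrt(r + eps)
    v <- mu * v + step
    w <- w + mu * v + step

i.e. the Nesterov reformulation in which the lookahead is folded into the
parameter update. The exact halving epochs are unpublished; the default
(17, 19, 21, 23, 25, 27, 29, 31) follows the late-phase halving
convention of this network family. Half of the training patches are
centred on lesion voxels (`fgFraction = 0.5`, unpublished, needed against
the severe class imbalance); the rest are drawn uniformly from the brain
mask.

### Reflection augmentation and the comparison channel

Left–right directional dependence is removed by sagittal-reflection
augmentation: all channels and the label patch of a training segment are
mirrored in unison. One design point deserves care. For a well-registered
head, the mirror of the comparison channel approximately *is* the CTA
(and vice versa): mirroring both channels and additionally swapping their
roles therefore nearly reproduces the unreflected input while the labels
are mirrored — which trains the network to mark the healthy contralateral
homolog of every lesion. We observed exactly this failure (contralateral
false-positive regions) when the swap was enabled. Plain unison
reflection without a role swap correctly emulates mirroring the whole
head, so that is the default (`reflectionSwapRoles = FALSE`); the swap
remains available as an option in `augmentReflection()`.

Whole-volume inference tiles the brain bounding box with disjoint output
segments; because output tiles are disjoint on the output grid, stitching
is seam-free and identical to single-pass inference where a volume fits
one tile. Probabilities outside the intracranial mask are zero.

## Preprocessing

The input-conditioning chain (`preprocessCase()`):

1. **Brain mask estimation** from the raw CTA: the largest connected
   sub-threshold component fully enclosed by the bright skull shell
   (6-connectivity, hole-filled). The threshold sits between the volume
   median and its 99.9th percentile.
2. **Cropping** to the brain bounding box plus margin, with the origin
   updated so physical coordinates are preserved.
3. **Isotropic resampling**: trilinear for images, nearest-neighbour for
   masks and the atlas so delineations keep their value sets. The desk
   default target is 1.0 mm (phantom experiments use 1.5 mm); the
   clinical-scale 0.5 mm is one config entry away.
4. **Intensity standardization** to zero mean, unit variance over in-mask
   voxels (population SD; the same affine map is applied outside the
   mask).
5. **Hemispheric comparison**: sagittal flip, then rigid registration of
   the flipped volume back onto the original, minimizing mean squared
   intensity difference over the brain mask with a 3-level Gaussian
   pyramid and a derivative-free simplex optimizer under fixed iteration
   caps; if optimization cannot beat the identity transform the identity
   is kept. Whether normalization precedes the comparison construction is
   unpublished; the default normalizes first (`normalizeBeforeComparison
   = TRUE`), and the alternative order is implemented.

All outputs of a case are grid-congruent, and the chain is deterministic.

## Evaluation

Two levels, as in the study design:

- **Voxel-wise**, over in-mask voxels only: sensitivity TP/(TP+FN),
  specificity TN/(TN+FP), Dice 2TP/(2TP+FP+FN) at a conservative
  probability threshold of 0.5, plus ROC curves swept over all distinct
  probability values with trapezoidal AUC. A voxel at exactly the
  threshold is positive (the tie rule is unpublished and must be fixed
  for exactness). The trapezoidal AUC equals the pairwise concordance
  estimator with ties counted half, which the tests verify to 1e-9.
- **Region-level**: a region is stroke-positive as soon as a single
  predicted-positive voxel carries its atlas label. Positivity vectors
  are tallied into TN/TP/FN/FP counts over cases; sensitivity,
  specificity and a region-count Dice 2TP/(2TP+FP+FN) follow. The
  combined Dice over both groups adds the lesion-free group's false
  positives to the denominator: 2TP/(2TP+FP_A+FP_B+FN). This formula
  reproduces all six published Dice values from the published counts,
  which is how it was confirmed. Lesion-free subjects are assumed to
  contribute 20 negative-truth regions each (implied by the published
  count arithmetic: each group's counts sum to 15 × 20). Metrics are
  compared to printed values after half-up rounding to 2 decimals.

Lesion volumetry uses the largest connected component of the thresholded
map, 26-connectivity (unpublished; the standard choice for 3D lesion
volumetry), times the voxel volume.

## The phantom generator

No imaging data from the study are shared, so every stage is exercised on
synthetic head phantoms (`generatePhantom()`, `generateCohort()`)
designed to carry the statistical structure the method depends on:

- nested-ellipsoid anatomy in pseudo-HU arbitrary units: parenchyma 35,
  CSF 5, skull shell 100 — only relative contrast matters because
  preprocessing standardizes intensities;
- exact bilateral mirror symmetry by construction (the grid midplane is a
  voxel-to-voxel mirror) before the pose perturbation;
- symmetric aging confounders: a periventricular rim whose intensity
  drops toward the lesion range as severity rises, and radial cortical
  sulcal grooves that deepen and widen with severity — the two structures
  reported as the main false-positive sources;
- a unilateral lesion ellipsoid (semi-axes r·(1, 1.2, 0.85)) wholly
  inside one hemisphere, modelled as a uniform intensity drop
  parenchyma·(1−contrast) plus noise (no quantitative lesion texture
  description exists to emulate);
- an NCCT-like channel: the same anatomy with compressed contrast and a
  strong through-plane blur, mimicking thick-slice acquisition;
- additive Gaussian noise (default SD 2, i.e. roughly a quarter of the
  lesion contrast at default settings) and a small random rigid head-pose
  perturbation (default within 2° and 2 mm) applied to all channels in
  unison;
- a procedural ASPECTS-analog atlas: per hemisphere, four deep regions
  (I, L, C, IC) by nearest-prototype assignment and six cortical regions
  (M1–M6) by band and sector, partitioning the brain mask into 20
  labels.

Cohorts randomize lesion side (p = 0.5), radius (by default 0.20–0.38 of
the inner skull semi-axis, so the largest lesion still fits one
hemisphere; relative to phantom brain volume this spans roughly the
published lesion-volume range, whose upper end is capped by the
unilateral-fit constraint), contrast (0.25–0.45) and confounder
severities (0.2–0.8). Per-case seeds derive deterministically from the
cohort seed, so any case can be regenerated in isolation and identical
spec + seed is bit-identical.

What the phantoms do *not* emulate: calibrated Hounsfield units, beam
hardening and bolus physics, vessel trees, gyral anatomy, bilateral or
multifocal lesions, heterogeneous lesion texture, scanner-to-scanner
variation. Passing tests on phantoms therefore demonstrate that the
pipeline's machinery is correct and that the hemispheric-comparison
mechanism behaves as designed under controlled asymmetry — not clinical
performance.

## Desk-scale problem sizes

The package's reference experiment (`deskExperimentConfig()`) uses
64 × 64 × 44 phantoms at 1.5 × 1.5 × 2.0 mm resampled to 1.5 mm
isotropic, cohorts of 4+4 training and 4+4 test cases, the depth-6
network above, and a compressed schedule of 10 epochs × 5 sub-epochs × 8
batches with halving at epochs 6–10. These sizes were chosen so that a
full end-to-end experiment trains in roughly a minute and the
three-feature-set ablation over several seeds completes in minutes on a
single CPU, while every mechanism of the full-scale method (multi-scale
pathways, masked sampling, augmentation, tiled inference) is exercised
unchanged. The full-scale design — 96 × 96 × 64 phantoms (the
`PhantomSpec()` default), 0.5 mm resampling, 15+15/15+15 cohorts, the
11-layer network and the 35 × 15 schedule — is reachable purely through
configuration.

## Numerical choices and degenerate inputs

- Threshold ties are positive (≥).
- Standardization uses the population SD; constant in-mask intensities
  raise a degenerate-variance error, an empty mask is an error.
- ROC requires at least one positive and one negative in-mask voxel.
- Empty-truth conventions: sensitivity is NaN with an explanatory
  attribute; Dice is 1 when prediction and truth are both empty, 0 when
  only the truth is empty.
- Registration falls back to the identity transform when optimization
  does not improve on it, and warns when an iteration cap is hit.
- Resampling places output voxel centres so the first voxel edges of the
  input and output grids coincide; physical extent is preserved within
  one voxel.
- Region labels absent from an atlas volume produce a warning and
  evaluate as negative.
- All randomness flows through per-stage seeds derived from one
  experiment seed by a fixed integer mix, making cohort generation,
  training and reports reproducible bit for bit.

## Known limitations

The phantom world is much easier than clinical CTA-SI: real lesions are
textured, irregular, and sometimes bilateral; real heads are not
ellipsoids; real registration contends with gantry tilt and motion. The
desk-scale network is far smaller than the published one and its
absolute metrics on phantoms should not be compared with the published
clinical numbers — only the exact contingency-table arithmetic and the
directional behaviour of the input-feature ablation carry over. Training
uses a single worker and is deliberately deterministic; no GPU path is
provided.
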