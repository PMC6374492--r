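# ctastroke

Desk-scale R implementation of an end-to-end analysis for detecting acute
ischemic stroke lesions in CT-angiography source images (CTA-SI) with a
patch-based, dual-pathway 3D convolutional network.

## Who this is for

Researchers in medical image analysis who want a fully reproducible,
CPU-sized re-implementation of the hemispheric-comparison approach to
CTA-SI stroke segmentation: every stage — phantom cohort generation,
preprocessing, network training, inference and two-level evaluation — is
exercised on synthetic head phantoms, so the whole pipeline runs and is
testable without any clinical data.

## The method

Ischemic tissue appears on CTA-SI as *hypoattenuation*. A voxel-wise
classifier confuses it with symmetric aging changes (periventricular
white-matter hypoattenuation, widened cortical sulci). The key input
feature is therefore the **hemispheric comparison volume**: the CTA
flipped left–right and rigidly registered back onto itself, giving each
voxel its approximate contralateral homolog as a second channel — a
unilateral lesion is dark in one channel and bright in the other, while
symmetric aging changes are dark in both.

The segmentation model is a two-pathway multi-scale 3D CNN (DeepMedic
family): a normal-resolution pathway and a mean-pooled context pathway of
unpadded 3×3×3 convolutions, concatenated and classified per voxel with a
two-class softmax. Training uses voxel-wise cross-entropy with L1 = 1e-6
and L2 = 1e-4, RMSprop (ρ = 0.9, ε = 1e-4) with Nesterov momentum 0.6,
batch size 10, 35 epochs × 15 sub-epochs, initial learning rate 0.001
halved at predefined epochs, and sagittal-reflection augmentation.

Evaluation is two-level:

- **voxel-wise**: sensitivity, specificity, Dice DSC = 2TP/(2TP+FP+FN)
  at threshold 0.5, ROC/AUC by threshold sweep;
- **ASPECTS regions**: ten regions per hemisphere (M1–M6, insular ribbon
  I, lentiform nucleus L, caudate C, internal capsule IC); a region is
  stroke-positive as soon as one predicted voxel carries its label;
  region counts give sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
  DSC = 2TP/(2TP+FP+FN), and ASPECTS points = 10 − positive regions,
  worst hemisphere. Largest-connected-component volumetry
  (26-connectivity) reports lesion volume in cm³.

See `vignettes/methods.Rmd` for the model, the phantom generator, and
every numerical design decision.

## Worked example

Region-level metrics from a contingency table of ASPECTS-region calls
(here: the published counts for the CTA + hemispheric-comparison
experiment, 15 lesioned test subjects × 20 regions):

```r
library(ctastroke)
ct <- new("RegionContingency", tn = 158, tp = 98, fn = 7, fp = 37)
metricsFromContingency(ct)$rounded
#> sensitivity specificity         dsc
#>        0.93        0.81        0.82
combinedDsc(ct, fpGroupB = 46)$rounded   # pooled with 15 lesion-free subjects
#> [1] 0.69
table2Check()                             # verify the whole packaged table
#>   features        check expected computed pass
#> 1      cta  sensitivity     0.94     0.94 TRUE
#> 2      cta  specificity     0.40     0.40 TRUE
#> 3      cta          dsc     0.62     0.62 TRUE
#> 4      cta dsc_combined     0.48     0.48 TRUE
#> ...
```

Generating and inspecting a phantom subject:

```r
cs <- generatePhantom(PhantomSpec(seed = 7L))
cs
#> PhantomCase phantom (group A): 96x96x64 grid, lesion 3210 voxels
largestComponentVolume(cs@lesionMask)
#> [1] 7.398086          # cm^3
```

An end-to-end desk-scale experiment (cohort generation, preprocessing,
training, inference, evaluation; ~3 minutes on one CPU):

```r
bundle <- runExperiment(deskExperimentConfig(seed = 1L, outputDir = "exp"))
bundle$voxel        # pooled test-set sensitivity/specificity/DSC/AUC
bundle$contingencyA # ASPECTS-region contingency over lesioned test cases
```

and the input-feature comparison on a shared test cohort:

```r
runAblation(deskExperimentConfig(seed = 1L),
            featureSets = c("cta", "cta+flip"), seeds = 1:3)$median
```

A thin CLI over the same functions is in `inst/cli/ctastroke.R`
(`generate`, `run`, `ablate`, `table2-check` subcommands).

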