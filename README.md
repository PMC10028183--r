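# cambnet

Classify luminal versus non-luminal breast-cancer molecular subtype from
contoured DCE-MRI tumor patches with **CAMBNET**, a compact cross-attention
multi-branch convolutional network — together with the full workflow around
it: phantom cohort simulation, contour-driven ROI preprocessing,
patient-wise training with best-on-validation checkpointing, confusion
matrix / ROC evaluation with covariate-stratified subgroups, and Grad-CAM
explainability.

## Who this is for

Researchers in quantitative breast MRI who want a fully reproducible,
dependency-light reference implementation of a multi-branch attention CNN
pipeline: the network's forward and backward passes, RMSprop training, and
Grad-CAM are implemented in this package (R + RcppArmadillo kernels), so
every component is inspectable and testable without a deep-learning
framework. Because the clinical cohort behind the method is private, the
package ships a lesion-phantom generator that emulates its structure
(spiculated luminal-like lesions versus round, ring-enhanced
non-luminal-like lesions, with per-patient metadata), making the whole
pipeline exercisable end to end.

## The model in brief

A 3×3 stem (16 channels) feeds three branches over 64×64×3 patches:

* **SFEpath** — 1×1 expand to 128 → 3×3 depthwise → squeeze-and-excitation
  → 1×1 reduce to 16, plus a residual connection from the stem;
* **LTTpath1** — 1×1 bottleneck to 8 → 3×3 depthwise → 1×1 to 16;
* **LTTpath2** — 1×1 to 4, then alternating asymmetric 1×3 / 3×1
  convolutions through 8, 8, 8, 16 channels.

A **cross-attention** module gates the LTT paths against each other
(channel attention from one path, spatial attention from the other; both
single-path, sigmoid-gated). The gated paths are summed, concatenated with
SFEpath (64×64×32), and a deep feature-extraction module (maxpool → 1×1 to
128 → stride-2 depthwise → SE → 1×1 to 64 → maxpool → global average pool
→ dropout 0.5 → linear 64×2) produces the two-class logits. Training uses
cross-entropy, RMSprop at learning rate 0.002 decayed ×0.95 every 10
epochs, batch sizes 8/1, L2 regularization and a per-kernel max-norm
clamp, with the best-on-validation checkpoint kept. Metrics are accuracy,
precision, recall, F1 (per-class and macro) and midrank ROC AUC; subgroup
evaluation stratifies at age at menarche 14 years and tumor size 20 mm.

## Worked example

```r
library(cambnet)

co   <- generateCohort(40, spec = phantomSpec(), seed = 11)
ps   <- preprocessCohort(co)                  # 64 x 64 x 3 patches
plan <- patientSplit(patchMetadata(ps), seed = 11)
fit  <- trainCambnet(buildCambnet(seed = 11), ps, plan,
                     trainConfig(maxEpochs = 8, seed = 11))
head(fit$history, 3)
#>   epoch    lr train_loss val_acc
#> 1     0 0.002 0.75951925     0.8
#> 2     1 0.002 0.09418971     1.0
#> 3     2 0.002 0.05585893     1.0

testIdx <- which(patchMetadata(ps)$patient_id %in% plan@testIds)
evaluateModel(fit$model, subsetPatchSet(ps, testIdx),
              classLevels = fit$classLevels)
#> MetricsReport (macro, n = 8)
#>   Acc 100.00%  Pre 100.00%  Rec 100.00%  F1 100.00%  AUC 100.00%
```

The history rows show the step-decay schedule (`lr`), the mean training
cross-entropy per epoch and validation accuracy; the report prints the
macro-averaged test metrics — on this small separable phantom cohort the
model reaches perfect held-out classification within a few epochs. A
Grad-CAM map for one test case, with the fraction of saliency inside the
tumor contour:

```r
i    <- testIdx[1]
sal  <- gradCam(fit$model, patchArray(ps)[, , , i])
mask <- maskToPatch(caseMask(cohortCases(co)[[i]]),
                    extractBoundingBox(caseMask(cohortCases(co)[[i]])))
localizationScore(sal, mask)   # saliency mass on the lesion
mean(mask > 0)                 # uniform-saliency chance baseline
```

`runPipeline(validateConfig())` drives the whole chain
(simulate → preprocess → split → train → evaluate → explain) from one YAML
config and writes metrics CSVs, history logs, a ROC plot, Grad-CAM scores
and a checkpoint; `inst/scripts/cambnet` exposes the same steps as shell
subcommands (`simulate`, `preprocess`, `train`, `evaluate`, `explain`,
`run-all`, `summary`).

## Package layout

* `R/` — S4 classes (`PhantomSpec`, `ContouredCase`, `RoiPatchSet`,
  `CambnetConfig`, `CambnetModel`, `SplitPlan`, `MetricsReport`,
  `SaliencyMap`) and the pipeline functions; `src/` — convolution,
  batch-norm, pooling and resize kernels (RcppArmadillo).
* `vignettes/cambnet-methods.Rmd` — the model, its assumptions, parameter
  defaults, numerical choices and limitations.
* `tests/testthat/` — unit, property and end-to-end conformance suites.
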