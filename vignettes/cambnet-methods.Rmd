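---
title: "CAMBNET: model, pipeline and design notes"
author: "cambnet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CAMBNET: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cambnet)
```

## The problem

Breast-cancer molecular subtype (luminal A/B versus HER2-overexpressing and
triple-negative) drives treatment choice, but is established by invasive
immunohistochemistry. DCE-MRI morphology correlates with subtype — luminal
masses tend to be irregular with burr-like (spiculated) margins, while
triple-negative lesions are more often well-defined round masses with
annular (ring) enhancement — which makes image-based prediction attractive.
The difficulty is low lesion/background contrast and high between-subtype
shape similarity.

`cambnet` implements CAMBNET, a compact cross-attention multi-branch
convolutional network for classifying luminal versus non-luminal subtype
from physician-contoured tumor patches, together with everything the
workflow needs: ROI preprocessing, patient-wise data splitting, the
training recipe, confusion-matrix/ROC evaluation with covariate-stratified
subgroups, and Grad-CAM explainability. Because the clinical cohort the
method was developed on is private, the package ships a phantom generator
that emulates the two morphologies, so the entire pipeline is exercisable
and testable end to end.

## The architecture

The input is a normalized $64 \times 64 \times 3$ patch. A $3\times3$ stem
produces 16 channels shared by three branches:

* **SFEpath** (shallow features): $1\times1$ expansion to 128 channels,
  $3\times3$ depthwise convolution, a squeeze-and-excitation (SE) block,
  $1\times1$ reduction back to 16, plus a residual connection from the stem
  output. The residual protects shallow texture/shape information.
* **LTTpath1** (lesion localisation): a $1\times1$ bottleneck to 8
  channels, $3\times3$ depthwise convolution, $1\times1$ expansion to 16.
* **LTTpath2**: $1\times1$ to 4 channels, then alternating $1\times3$ and
  $3\times1$ asymmetric convolutions through 8, 8, 8, 16 channels —
  Inception-style factorization that is cheaper than $3\times3$ kernels at
  the same depth (a test asserts the parameter saving).

Every convolution is followed by batch normalization and ReLU.

**Cross-attention.** Both attention sub-modules are single-path
(average-pooling descriptors only, unlike CBAM's avg+max dual paths):
channel attention is an SE-style gate (global average pool, bottleneck MLP,
sigmoid), spatial attention is a sigmoid-gated $k \times k$ convolution
(default $k = 7$) over the channel-mean map. The "cross" wiring computes
channel weights from LTTpath1 to gate LTTpath2, and spatial weights from
LTTpath2 to gate LTTpath1. The published description does not pin the
direction, so the mirrored wiring is available behind
`cambnetConfig(attentionWiring = "ch2_sp1")`; the default is the simplest
reading with exactly one attention type per direction.

**Fusion and deep feature extraction.** The two gated LTT outputs are
added; the sum is concatenated with the SFEpath output (LTT sum first) to a
$64\times64\times32$ map. The deep module then max-pools to $32\times32$,
expands to 128 channels, halves resolution with a stride-2 depthwise
convolution (no residual in this block), applies SE, reduces to 64
channels, max-pools to $8\times8$, global-average-pools to a 64-vector,
applies dropout (0.5) and a $64 \to 2$ linear classifier. The printed
per-stage dimension plan shows the classifier input as $8\times8\times64$
with a $64\times2$ weight; global average pooling is the only
shape-consistent bridge, and that is what the package implements.

`stageShapes()` / `summary()` expose every stage's realized dimensions;
the test suite sweeps all of them.

### Numerical choices

* Batch-norm: batch statistics during training (momentum 0.1 running
  updates, $\epsilon = 10^{-5}$), running statistics at inference.
* Convolutions that feed batch normalization carry no bias: the BN shift
  subsumes a conv bias exactly, and under batch-statistics training the
  bias gradient is identically zero — keeping such parameters would leave
  permanently dead tensors. Bias terms remain where no BN follows (the
  spatial-attention convolution, SE bottlenecks, the classifier).
* Initialization: Kaiming-style normal ($\mathrm{sd} = \sqrt{2/\text{fan-in}}$)
  for all convolution and linear weights, zero biases, unit BN scale,
  fully seeded.
* SE reduction ratio 16 where it divides the channel count (128-channel
  blocks use a bottleneck of 8); at 16 channels the bottleneck is clamped
  to a floor of 4 units so the gate keeps expressive capacity.
* The whole forward/backward engine is implemented in the package (R
  orchestration over RcppArmadillo convolution kernels, with analytic
  backward passes for every block); gradients are verified against central
  finite differences in development and the gradient-flow test asserts
  every tensor receives signal.

## Preprocessing

The contour mask drives everything: the extreme positive pixels in the
four directions define the minimum covering matrix, each side is extended
by a 10-pixel margin (clipped at the frame — the only well-defined
behaviour without a padding policy), the rectangular crop is resized
directly to $64\times64$ by bilinear interpolation (aspect ratio is *not*
preserved), and intensities already scaled to $[0,1]$ are normalized per
channel with $(x - 0.5)/0.5$. Both constants are configurable; the
defaults are label-free and dataset-independent. Box indices are 0-based
and inclusive. Bilinear sampling uses the half-pixel-center convention
(`src = (dst + 0.5) * scale - 0.5`, clamped); golden tests pin this
convention, and Grad-CAM upsampling reuses the same kernel so saliency maps
align with patches exactly.

## Training recipe

Defaults in `trainConfig()`: batch sizes 8 (train) and 1 (eval), up to 200
epochs, RMSprop (alpha 0.99, epsilon 1e-8, momentum 0) with initial
learning rate 0.002 multiplied by 0.95 every 10 epochs
(`lrAt()` is the closed form), cross-entropy loss, L2 penalty (1e-4, on
convolution/linear kernels), and a per-kernel max-norm clamp (bound 2.0)
applied after every step. The L2 coefficient and norm bound realize the
named regularizers whose values the source description omits; both are
configurable. Optional augmentation draws from the dihedral family: random
right-angle rotations and transposition about the main diagonal.

**Splitting.** `patientSplit()` holds out 20% of patients as the test set,
stratified by class, with all images of a patient travelling together.
Checkpoint selection needs a validation set the source protocol never
defines; selecting on the test set would leak, so 15% of the training
patients are carved out (stratified) for that purpose. `kfoldPlan()`
provides patient-level, class-stratified 5-fold assignments; because the
published protocol is ambiguous about whether cross-validation ran over
the full cohort or the held-out split, both the fixed 80/20 split and fold
plans over any id set are available. The training entry point re-asserts
train/test disjointness (leakage guard) independently of the splitter.

The best-on-validation checkpoint is returned together with a per-epoch
history (learning rate, training loss, validation accuracy).

## Evaluation

Accuracy, precision, recall and F1 come from the confusion counts;
precision/recall/F1 are reported per class and macro-averaged (the
headline numbers use the macro average — with near-balanced classes this
is the convention under which recall can exceed accuracy, matching how the
original results are ordered). Zero denominators yield 0 with a warning.
AUC uses the midrank/Mann–Whitney convention, so ties contribute 1/2 and
the value is invariant under monotone score transforms; tests check it
against a brute-force pairwise oracle and against pROC. The positive class
is non-luminal by default; the macro AUC is also reported (for a binary
task it equals the positive-class value).

`subgroupEval()` stratifies the evaluation set at age at menarche 14 years
or tumor size 20 mm (the two strata partition the cohort) and relabels
ground truth under the binary schemes of the subgroup analyses:
luminal-vs-non-luminal, triple-negative-vs-rest, luminalA-vs-rest. The
binary model's non-luminal probability serves as the ranking score under
every scheme; empty strata are reported as missing rather than dropped.

## Explainability

`gradCam()` computes the gradient of a target-class logit with respect to
a convolutional stage (default `Conv4_5`, the last convolutional stage of
the deep module), global-average-pools the gradient into channel weights,
forms the rectified weighted activation sum, bilinearly upsamples to the
input size and min–max normalizes; an identically zero map is returned as
zeros rather than divided by zero. Saliency arrays are colormap-free; any
display colouring happens in the plotting layer. `featureGrid()` returns
channel-mean (or per-channel) activation images for the six stage groups
(stem, SFEpath, LTTpath1, LTTpath2, fused, deep). `localizationScore()`
quantifies the qualitative "focus on the tumor" claim as the fraction of
saliency mass inside the (patch-projected) contour mask; a uniform map
scores the mask-area fraction, the natural per-case chance baseline.

## The phantom generator

`generatePhantom()` renders one case: a smoothed random background field
(coarse Gaussian noise bilinearly upsampled, plus fine pixel noise — the
knob for the low-contrast property), and a lesion whose boundary is an
ellipse perturbed by radial sinusoidal spiculation for the luminal-like
class (amplitude 0.35 of the radius, 8–14 lobes) or a smooth near-circular
disc with a brighter annulus (ring contrast 0.35) for the non-luminal-like
class. Three channels re-render the same lesion at different contrast
(0.5 / 0.75 / 1.0), emulating T1WI, T2WI and the third-phase DCE series.
The mask is the lesion's 4-connected support; tumor size is its maximum
caliper diameter at a fixed 0.5 mm/pixel spacing (radii 12–36 px place
diameters on both sides of the 20 mm threshold); age at menarche is
uniform on the integers 11–17, populating both sides of the 14-year
threshold roughly evenly. Four-way sublabels are drawn within each binary
class at the approximate clinical composition, and the default cohort is
160 cases at an 84:76 luminal:non-luminal balance.

What the phantoms do *not* emulate: MR physics and DCE pharmacokinetics,
3-D volumes, registration error between series, intensity
non-uniformities, or the shape overlap between real subtypes. Passing the
learnability checks therefore shows the pipeline trains, checkpoints and
evaluates correctly on a cohort whose classes are separable by the same
kind of morphology the clinical problem involves — it does not certify
clinical accuracy, and the published clinical performance numbers are not
reproduction targets here (the dataset is private).

A cohort invariant keeps the downstream checks meaningful: a linear
classifier on two hand-crafted mask features (isoperimetric roughness,
ring-intensity contrast) must separate the default classes with > 0.9
accuracy; if the generator drifted to unlearnable settings, training tests
would become vacuous.

## Problem sizes used by the checks

The heavier suites run at a documented scale chosen to be decisive yet
desk-sized: a 200-case default-spec cohort, 30 training epochs with a
fixed seed (reaching $\ge 0.95$ training and $\ge 0.85$ held-out accuracy
in the reference run), Grad-CAM localization on 50 held-out cases against
per-case uniform baselines, 1,000 random confusion tables and 100 tied
score vectors for the metric oracles, and 200 random cohorts for the
split-integrity properties. `scripts/acceptance.R` re-runs this
computation from scratch and writes the resulting quantities as JSON.

## Known limitations

* Single 2-D slice per case; no 3-D context or multi-slice aggregation.
* The four-way subtype labels are only exercised through the relabeling
  schemes; the default classifier head is binary (a 4-way head is one
  config switch away but untrained by default).
* The engine is CPU-only and double-precision; it is sized for this
  model (26,440 trainable parameters under the default configuration),
  not for general deep learning.
* Checkpoints are R serializations (`.rds`); no interchange format.
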