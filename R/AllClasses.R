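#' @include utils.R
NULL

SUBTYPES2 <- c("luminal", "non_luminal")
SUBTYPES4 <- c("luminalA", "luminalB", "HER2", "TN")

#' Phantom cohort generation parameters
#'
#' Describes the synthetic DCE-MRI-like phantoms: frame size, number of
#' acquisition-like channels, lesion radius range (pixels), the class-specific
#' morphology knobs (spiculation amplitude for luminal-like lesions, annular
#' ring contrast for non-luminal-like lesions), background texture scale, and
#' the pixel spacing used to convert lesion diameters to millimetres.
#'
#' @slot imageSide frame side length in pixels.
#' @slot nChannels number of image channels per case (3 emulates T1WI, T2WI
#'   and the third-phase DCE series).
#' @slot lesionRadiusRange numeric length-2, min/max lesion radius in pixels.
#' @slot spiculationAmplitude radial boundary perturbation for luminal-like
#'   lesions, as a fraction of the radius; in `[0, 1)`.
#' @slot ringContrast intensity increment of the enhancing annulus of
#'   non-luminal-like lesions; non-negative.
#' @slot backgroundNoiseScale intensity scale of the textured background.
#' @slot pixelSpacing millimetres per pixel for tumor-size synthesis.
#' @slot seed integer seed attached to the spec (used when no explicit seed
#'   is passed at generation time).
#' @seealso [phantomSpec()], [generatePhantom()], [generateCohort()]
#' @export
setClass("PhantomSpec", representation(
  imageSide = "integer",
  nChannels = "integer",
  lesionRadiusRange = "numeric",
  spiculationAmplitude = "numeric",
  ringContrast = "numeric",
  backgroundNoiseScale = "numeric",
  pixelSpacing = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@imageSide < 16) msg <- c(msg, "imageSide must be >= 16")
  if (length(object@lesionRadiusRange) != 2) {
    msg <- c(msg, "lesionRadiusRange must have length 2")
  } else {
    if (object@lesionRadiusRange[1] < 4)
      msg <- c(msg, "lesionRadiusRange min must be >= 4 px")
    if (object@lesionRadiusRange[2] >= object@imageSide / 2)
      msg <- c(msg, "lesionRadiusRange max must be < imageSide/2")
    if (diff(object@lesionRadiusRange) < 0)
      msg <- c(msg, "lesionRadiusRange must be increasing")
  }
  if (object@spiculationAmplitude < 0 || object@spiculationAmplitude >= 1)
    msg <- c(msg, "spiculationAmplitude must lie in [0, 1)")
  if (object@ringContrast < 0) msg <- c(msg, "ringContrast must be >= 0")
  if (object@pixelSpacing <= 0) msg <- c(msg, "pixelSpacing must be > 0")
  if (object@nChannels < 1) msg <- c(msg, "nChannels must be >= 1")
  if (length(msg)) msg else TRUE
})

#' One contoured case: images, tumor mask and patient metadata
#'
#' The unit record the pipeline consumes: one grayscale image per channel,
#' a binary physician-style tumor contour mask aligned with the images, the
#' molecular subtype label (binary and four-way), and the grouping covariates
#' (age at menarche in years, tumor size in millimetres).
#'
#' @slot patientId unique case identifier.
#' @slot images list of H x W numeric matrices, one per channel.
#' @slot mask H x W integer matrix, 1 inside the tumor contour.
#' @slot subtypeLabel `"luminal"` or `"non_luminal"`.
#' @slot subtypeLabel4 one of `"luminalA"`, `"luminalB"`, `"HER2"`, `"TN"`.
#' @slot menarcheAge age at menarche, years (> 0).
#' @slot tumorSizeMm maximum lesion diameter, millimetres (> 0).
#' @slot lesionInfo list of generator-internal lesion geometry (empty for
#'   cases read from disk).
#' @export
setClass("ContouredCase", representation(
  patientId = "character",
  images = "list",
  mask = "matrix",
  subtypeLabel = "character",
  subtypeLabel4 = "character",
  menarcheAge = "numeric",
  tumorSizeMm = "numeric",
  lesionInfo = "list"
))

setValidity("ContouredCase", function(object) {
  msg <- character()
  if (!length(object@images)) msg <- c(msg, "at least one image channel required")
  d <- dim(object@images[[1]])
  for (im in object@images)
    if (!identical(dim(im), d)) msg <- c(msg, "all channels must share dimensions")
  if (!identical(dim(object@mask), d))
    msg <- c(msg, "mask dimensions must equal image dimensions")
  if (sum(object@mask) < 1) msg <- c(msg, "mask must contain >= 1 positive pixel")
  if (!object@subtypeLabel %in% SUBTYPES2)
    msg <- c(msg, "subtypeLabel must be 'luminal' or 'non_luminal'")
  if (!object@subtypeLabel4 %in% SUBTYPES4)
    msg <- c(msg, "subtypeLabel4 must be one of luminalA/luminalB/HER2/TN")
  if (object@menarcheAge <= 0) msg <- c(msg, "menarcheAge must be > 0")
  if (object@tumorSizeMm <= 0) msg <- c(msg, "tumorSizeMm must be > 0")
  if (length(msg)) msg else TRUE
})

#' A cohort of contoured cases with a metadata table
#'
#' @slot cases list of [ContouredCase-class] objects.
#' @slot metadata data.frame with one row per case: `patient_id`, `label`,
#'   `label4`, `menarche_age`, `tumor_size_mm`.
#' @slot spec the [PhantomSpec-class] the cohort was generated from (may be
#'   a default spec for cohorts read from disk).
#' @export
setClass("PhantomCohort", representation(
  cases = "list",
  metadata = "data.frame",
  spec = "PhantomSpec"
))

setValidity("PhantomCohort", function(object) {
  msg <- character()
  if (nrow(object@metadata) != length(object@cases))
    msg <- c(msg, "metadata rows must match number of cases")
  ids <- object@metadata$patient_id
  if (anyDuplicated(ids)) msg <- c(msg, "patient ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Tumor bounding box (0-based, inclusive pixel indices)
#'
#' The minimum matrix covering the contour, expanded by a margin in each of
#' the four directions and clipped to the image frame. Indices are 0-based
#' and inclusive.
#'
#' @slot rowMin,rowMax,colMin,colMax integer pixel indices.
#' @export
setClass("BoundingBox", representation(
  rowMin = "integer", rowMax = "integer",
  colMin = "integer", colMax = "integer"
))

setValidity("BoundingBox", function(object) {
  msg <- character()
  if (object@rowMin > object@rowMax) msg <- c(msg, "rowMin must be <= rowMax")
  if (object@colMin > object@colMax) msg <- c(msg, "colMin must be <= colMax")
  if (min(object@rowMin, object@colMin) < 0) msg <- c(msg, "indices must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A set of normalized 64 x 64 tumor patches
#'
#' @slot data numeric array `side x side x C x N` of normalized intensities.
#' @slot metadata data.frame with one row per patch (`patient_id`, `label`,
#'   `label4`, `menarche_age`, `tumor_size_mm`).
#' @slot normMean,normSd the per-channel normalization constants applied.
#' @export
setClass("RoiPatchSet", representation(
  data = "array",
  metadata = "data.frame",
  normMean = "numeric",
  normSd = "numeric"
))

setValidity("RoiPatchSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4) msg <- c(msg, "data must be a 4-d array (H, W, C, N)")
  else {
    if (d[1] != d[2]) msg <- c(msg, "patches must be square")
    if (d[4] != nrow(object@metadata))
      msg <- c(msg, "metadata rows must match number of patches")
  }
  if (!all(is.finite(object@data))) msg <- c(msg, "all patch values must be finite")
  if (length(msg)) msg else TRUE
})

#' CAMBNET architecture hyperparameters
#'
#' Realizes the published per-stage dimension plan: a 3 x 3 stem to 16
#' channels shared by three branches; SFEpath (1 x 1 expand to 128, 3 x 3
#' depthwise, squeeze-and-excitation, 1 x 1 reduce to 16, residual); LTTpath1
#' (1 x 1 to 8, 3 x 3 depthwise, 1 x 1 to 16); LTTpath2 (1 x 1 to 4 then
#' alternating 1 x 3 / 3 x 1 convolutions through 8, 8, 8, 16); cross
#' attention between the LTT paths; and the depth feature extraction module
#' (maxpool, expand to 128, stride-2 depthwise, SE, reduce to 64, maxpool,
#' global average pool, dropout, linear classifier).
#'
#' @slot inputSide input patch side (64).
#' @slot inChannels input channels (3).
#' @slot stemChannels stem output channels (16).
#' @slot sfeExpansionChannels SFEpath expansion width (128).
#' @slot ltt1BottleneckChannels LTTpath1 bottleneck width (8).
#' @slot ltt2ChannelPlan LTTpath2 channel plan (4, 8, 8, 8, 16).
#' @slot branchOutChannels common branch output width (16).
#' @slot dfemExpansionChannels DFEM expansion width (128).
#' @slot dfemOutChannels pre-classifier feature length (64).
#' @slot nClasses number of output classes (2).
#' @slot seReductionRatio squeeze-and-excitation reduction ratio (16); the
#'   bottleneck is clamped to at least 4 units.
#' @slot dropoutRate dropout probability before the classifier (0.5).
#' @slot attentionKernelSize spatial-attention convolution kernel size (7).
#' @slot attentionWiring `"ch1_sp2"` (channel attention from LTTpath1 gates
#'   LTTpath2, spatial attention from LTTpath2 gates LTTpath1) or the
#'   mirrored `"ch2_sp1"`.
#' @export
setClass("CambnetConfig", representation(
  inputSide = "integer",
  inChannels = "integer",
  stemChannels = "integer",
  sfeExpansionChannels = "integer",
  ltt1BottleneckChannels = "integer",
  ltt2ChannelPlan = "integer",
  branchOutChannels = "integer",
  dfemExpansionChannels = "integer",
  dfemOutChannels = "integer",
  nClasses = "integer",
  seReductionRatio = "integer",
  dropoutRate = "numeric",
  attentionKernelSize = "integer",
  attentionWiring = "character"
))

setValidity("CambnetConfig", function(object) {
  msg <- character()
  if (length(object@ltt2ChannelPlan) != 5)
    msg <- c(msg, "ltt2ChannelPlan must have 5 entries")
  else if (object@ltt2ChannelPlan[5] != object@branchOutChannels)
    msg <- c(msg, "ltt2ChannelPlan must end at branchOutChannels (additive fusion)")
  if (object@stemChannels != object@branchOutChannels)
    msg <- c(msg, "stemChannels must equal branchOutChannels (SFE residual add)")
  if (object@sfeExpansionChannels %% object@seReductionRatio != 0)
    msg <- c(msg, "seReductionRatio must divide sfeExpansionChannels")
  if (object@dfemExpansionChannels %% object@seReductionRatio != 0)
    msg <- c(msg, "seReductionRatio must divide dfemExpansionChannels")
  if (object@inputSide %% 8 != 0)
    msg <- c(msg, "inputSide must be divisible by 8 (three halvings)")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  if (object@attentionKernelSize %% 2 != 1)
    msg <- c(msg, "attentionKernelSize must be odd")
  if (!object@attentionWiring %in% c("ch1_sp2", "ch2_sp1"))
    msg <- c(msg, "attentionWiring must be 'ch1_sp2' or 'ch2_sp1'")
  if (object@nClasses < 2) msg <- c(msg, "nClasses must be >= 2")
  if (length(msg)) msg else TRUE
})

#' A built CAMBNET model
#'
#' Holds the architecture config, all trainable parameters (nested list of
#' numeric arrays) and the batch-normalization running statistics. Obtain one
#' with [buildCambnet()]; never manipulate the slots directly.
#'
#' @slot config a [CambnetConfig-class].
#' @slot params nested list of trainable arrays.
#' @slot state nested list of batch-norm running means/variances.
#' @export
setClass("CambnetModel", representation(
  config = "CambnetConfig",
  params = "list",
  state = "list"
))

#' Training hyperparameters
#'
#' Defaults follow the published recipe: train/eval batch sizes 8 and 1,
#' 200 epochs maximum, RMSprop with initial learning rate 0.002 multiplied
#' by 0.95 every 10 epochs, cross-entropy loss, L2 regularization and a
#' per-kernel max-norm constraint, best-on-validation checkpointing.
#'
#' @slot batchSizeTrain,batchSizeEval batch sizes (8, 1).
#' @slot maxEpochs maximum number of epochs (200).
#' @slot baseLr initial learning rate (0.002).
#' @slot lrDecayFactor multiplicative decay (0.95).
#' @slot lrDecayIntervalEpochs decay interval in epochs (10).
#' @slot optimizerName `"rmsprop"`.
#' @slot l2Weight L2 penalty coefficient.
#' @slot kernelMaxnorm per-kernel weight-norm bound.
#' @slot rmspropAlpha,rmspropEps,rmspropMomentum RMSprop internals.
#' @slot seed training seed.
#' @slot nFolds folds for cross-validation planning (5).
#' @slot testFraction held-out patient fraction (0.2).
#' @slot valFraction fraction of training patients carved out for
#'   checkpoint selection (0.15).
#' @slot augment logical; random right-angle rotation / diagonal-flip
#'   augmentation during training.
#' @export
setClass("TrainConfig", representation(
  batchSizeTrain = "integer", batchSizeEval = "integer",
  maxEpochs = "integer",
  baseLr = "numeric", lrDecayFactor = "numeric",
  lrDecayIntervalEpochs = "integer",
  optimizerName = "character",
  l2Weight = "numeric", kernelMaxnorm = "numeric",
  rmspropAlpha = "numeric", rmspropEps = "numeric",
  rmspropMomentum = "numeric",
  seed = "integer", nFolds = "integer",
  testFraction = "numeric", valFraction = "numeric",
  augment = "logical"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@testFraction <= 0 || object@testFraction >= 1)
    msg <- c(msg, "testFraction must lie in (0, 1)")
  if (object@valFraction < 0 || object@valFraction >= 1)
    msg <- c(msg, "valFraction must lie in [0, 1)")
  if (object@lrDecayFactor <= 0 || object@lrDecayFactor > 1)
    msg <- c(msg, "lrDecayFactor must lie in (0, 1]")
  if (object@batchSizeTrain < 1 || object@batchSizeEval < 1)
    msg <- c(msg, "batch sizes must be >= 1")
  if (object@maxEpochs < 1) msg <- c(msg, "maxEpochs must be >= 1")
  if (!identical(object@optimizerName, "rmsprop"))
    msg <- c(msg, "only the 'rmsprop' optimizer is provided")
  if (length(msg)) msg else TRUE
})

#' Patient-wise split plan
#'
#' Disjoint train / validation / test patient-id sets plus optional fold
#' assignments partitioning the non-test patients.
#'
#' @slot trainIds,valIds,testIds character vectors of patient ids.
#' @slot foldAssignments named integer vector, patient id to fold index.
#' @export
setClass("SplitPlan", representation(
  trainIds = "character", valIds = "character", testIds = "character",
  foldAssignments = "integer"
))

setValidity("SplitPlan", function(object) {
  msg <- character()
  all3 <- c(object@trainIds, object@valIds, object@testIds)
  if (anyDuplicated(all3))
    msg <- c(msg, "train/val/test patient sets must be disjoint")
  fa <- object@foldAssignments
  if (length(fa)) {
    nonTest <- c(object@trainIds, object@valIds)
    if (!setequal(names(fa), nonTest))
      msg <- c(msg, "foldAssignments must partition the non-test patients")
  }
  if (length(msg)) msg else TRUE
})

#' Confusion-matrix counts
#'
#' @slot tp,fp,tn,fn non-negative integer counts.
#' @export
setClass("ConfusionCounts", representation(
  tp = "integer", fp = "integer", tn = "integer", fn = "integer"
))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(v < 0)) "counts must be non-negative" else TRUE
})

#' Classification metrics report
#'
#' Accuracy, precision, recall and F1 from the confusion counts, plus ROC
#' AUC from the positive-class score. `averagingMode` selects whether the
#' headline precision/recall/F1 are positive-class values or macro averages
#' over classes; the per-class table always carries both classes.
#'
#' @slot accuracy,precision,recall,f1,auc fractions in `[0, 1]`.
#' @slot aucMacro macro-averaged AUC (for a binary task this equals the
#'   positive-class AUC).
#' @slot averagingMode `"macro"` or `"per-class"`.
#' @slot perClass data.frame of per-class precision/recall/F1.
#' @slot counts the positive-class [ConfusionCounts-class].
#' @slot n number of evaluated samples.
#' @export
setClass("MetricsReport", representation(
  accuracy = "numeric", precision = "numeric", recall = "numeric",
  f1 = "numeric", auc = "numeric", aucMacro = "numeric",
  averagingMode = "character", perClass = "data.frame",
  counts = "ConfusionCounts", n = "integer"
))

#' Grad-CAM saliency map
#'
#' @slot data matrix in `[0, 1]`, aligned with the input patch.
#' @slot targetClass class index the map explains (1-based).
#' @slot sourceLayer stage tag of the convolutional layer used.
#' @export
setClass("SaliencyMap", representation(
  data = "matrix", targetClass = "integer", sourceLayer = "character"
))

setValidity("SaliencyMap", function(object) {
  v <- object@data
  if (any(v < 0 | v > 1)) "saliency values must lie in [0, 1]" else TRUE
})
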