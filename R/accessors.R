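#' @include AllClasses.R
NULL

#' Construct a PhantomSpec
#'
#' Defaults emulate the clinical imaging setting the pipeline targets:
#' 256 x 256 frames, three channels standing for T1WI / T2WI / third-phase
#' DCE, lesion radii 12-36 px which at 0.5 mm/px place maximum diameters on
#' both sides of the 20 mm size threshold.
#'
#' @param imageSide frame side, pixels.
#' @param nChannels channels per case.
#' @param lesionRadiusRange length-2 numeric, lesion radius range in pixels.
#' @param spiculationAmplitude boundary spiculation amplitude for
#'   luminal-like lesions, fraction of radius in `[0, 1)`.
#' @param ringContrast intensity delta of the enhancing annulus of
#'   non-luminal-like lesions.
#' @param backgroundNoiseScale background texture intensity scale.
#' @param pixelSpacing millimetres per pixel.
#' @param seed integer seed stored with the spec.
#' @return a [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(seed = 1)
#' spec
#' @export
phantomSpec <- function(imageSide = 256L, nChannels = 3L,
                        lesionRadiusRange = c(12, 36),
                        spiculationAmplitude = 0.35,
                        ringContrast = 0.35,
                        backgroundNoiseScale = 0.12,
                        pixelSpacing = 0.5,
                        seed = 1L) {
  new("PhantomSpec",
      imageSide = as.integer(imageSide), nChannels = as.integer(nChannels),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      spiculationAmplitude = as.numeric(spiculationAmplitude),
      ringContrast = as.numeric(ringContrast),
      backgroundNoiseScale = as.numeric(backgroundNoiseScale),
      pixelSpacing = as.numeric(pixelSpacing),
      seed = as.integer(seed))
}

#' @describeIn phantomSpec display method
#' @param object a `PhantomSpec`
#' @export
setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@imageSide, "x", object@imageSide,
      "px,", object@nChannels, "channel(s)\n")
  cat("  lesion radius", object@lesionRadiusRange[1], "-",
      object@lesionRadiusRange[2], "px @", object@pixelSpacing, "mm/px\n")
  cat("  spiculation", object@spiculationAmplitude,
      "| ring contrast", object@ringContrast,
      "| background noise", object@backgroundNoiseScale, "\n")
})

setMethod("show", "ContouredCase", function(object) {
  d <- dim(object@mask)
  cat("ContouredCase", object@patientId, ":",
      object@subtypeLabel, sprintf("(%s),", object@subtypeLabel4),
      d[1], "x", d[2], "px,", length(object@images), "channel(s)\n")
  cat("  tumor", round(object@tumorSizeMm, 1), "mm | menarche",
      object@menarcheAge, "y | mask area", sum(object@mask), "px\n")
})

setMethod("show", "PhantomCohort", function(object) {
  tab <- table(object@metadata$label)
  cat("PhantomCohort:", length(object@cases), "cases (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
})

setMethod("show", "RoiPatchSet", function(object) {
  d <- dim(object@data)
  cat("RoiPatchSet:", d[4], "patches of", d[1], "x", d[2], "x", d[3], "\n")
  tab <- table(object@metadata$label)
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "CambnetModel", function(object) {
  cfg <- object@config
  cat("CambnetModel:", cfg@inputSide, "x", cfg@inputSide, "x",
      cfg@inChannels, "->", cfg@nClasses, "classes,",
      countParams(object), "trainable parameters\n")
  cat("  attention wiring:", cfg@attentionWiring, "\n")
})

setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan: train", length(object@trainIds),
      "| val", length(object@valIds),
      "| test", length(object@testIds), "patients\n")
  if (length(object@foldAssignments))
    cat("  folds:", paste(table(object@foldAssignments), collapse = "/"),
        "patients\n")
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: TP", object@tp, "FP", object@fp,
      "TN", object@tn, "FN", object@fn, "\n")
})

setMethod("show", "MetricsReport", function(object) {
  pct <- function(x) sprintf("%.2f%%", 100 * x)
  cat("MetricsReport (", object@averagingMode, ", n = ", object@n, ")\n",
      sep = "")
  cat("  Acc ", pct(object@accuracy), "  Pre ", pct(object@precision),
      "  Rec ", pct(object@recall), "  F1 ", pct(object@f1),
      "  AUC ", pct(object@auc), "\n", sep = "")
})

setMethod("show", "SaliencyMap", function(object) {
  cat("SaliencyMap from", object@sourceLayer, "for class",
      object@targetClass, ":", nrow(object@data), "x", ncol(object@data),
      "in [0,1]\n")
})

#' Cohort accessors
#'
#' @param x a [PhantomCohort-class].
#' @return `cohortMetadata` returns the per-case metadata data.frame;
#'   `cohortCases` the list of [ContouredCase-class] objects.
#' @export
cohortMetadata <- function(x) x@metadata

#' @rdname cohortMetadata
#' @export
cohortCases <- function(x) x@cases

#' Case accessors
#'
#' @param x a [ContouredCase-class].
#' @return `caseMask` returns the binary mask matrix; `caseImages` the list
#'   of channel matrices.
#' @export
caseMask <- function(x) x@mask

#' @rdname caseMask
#' @export
caseImages <- function(x) x@images

#' Patch-set accessors
#'
#' @param x a [RoiPatchSet-class].
#' @return `patchArray` returns the `side x side x C x N` array;
#'   `patchMetadata` the per-patch metadata data.frame.
#' @export
patchArray <- function(x) x@data

#' @rdname patchArray
#' @export
patchMetadata <- function(x) x@metadata

#' Model accessor
#'
#' @param x a [CambnetModel-class].
#' @return the model's [CambnetConfig-class].
#' @export
modelConfig <- function(x) x@config

#' Saliency accessor
#'
#' @param x a [SaliencyMap-class].
#' @return the saliency matrix.
#' @export
saliencyData <- function(x) x@data
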