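#' @include model.R
NULL

gradcamTags <- c("Pre_layer", "SFEpath", "Conv2_3", "Conv3_5", "Fuse",
                 "Dwconv4_3", "Conv4_5", "Maxpool4_6")

#' Grad-CAM class-activation map
#'
#' Computes the gradient of the target-class logit with respect to the
#' activations of a convolutional stage, global-average-pools the gradient
#' into per-channel importance weights, forms the weighted activation sum,
#' rectifies it, bilinearly upsamples to the input patch size and min-max
#' normalizes to `[0, 1]`. A map whose pre-normalization values are
#' identically zero is returned as all zeros.
#'
#' @param model a [CambnetModel-class] (run in inference mode).
#' @param patch numeric array `side x side x C` (a single input patch).
#' @param targetClass 1-based class index to explain (default: the
#'   predicted class).
#' @param layerTag stage tag of the convolutional layer; default
#'   `"Conv4_5"`, the last convolutional stage of the deep feature
#'   extraction module.
#' @return a [SaliencyMap-class].
#' @export
gradCam <- function(model, patch, targetClass = NULL,
                    layerTag = "Conv4_5") {
  if (!layerTag %in% gradcamTags)
    stopNamed("cambnet_layer_error", paste0(
      "unknown layer tag '", layerTag, "'; valid tags: ",
      paste(gradcamTags, collapse = ", ")))
  if (length(dim(patch)) == 3L) dim(patch) <- c(dim(patch), 1L)
  fw <- cambnetForward(model, patch, training = FALSE, keepCache = TRUE,
                       keepStages = TRUE)
  K <- model@config@nClasses
  if (is.null(targetClass))
    targetClass <- which.max(fw$logits[, 1])
  targetClass <- as.integer(targetClass)
  if (targetClass < 1 || targetClass > K)
    stopNamed("cambnet_layer_error", "targetClass out of range")
  gLogits <- matrix(0, K, 1)
  gLogits[targetClass, 1] <- 1
  bw <- cambnetBackward(model, fw$cache, gLogits, stageGrads = layerTag)
  A <- fw$stages[[layerTag]]
  G <- bw$stageGrads[[layerTag]]
  d <- dim(A)
  wts <- colMeans(matrix(G, d[1] * d[2], d[3]))          # GAP of gradients
  cam <- matrix(matrix(A, d[1] * d[2], d[3]) %*% wts, d[1], d[2])
  cam[cam < 0] <- 0
  side <- model@config@inputSide
  up <- cpp_bilinear_resize(array(cam, dim = c(d[1], d[2], 1L)),
                            c(d[1], d[2], 1L), side, side)
  up <- matrix(up, side, side)
  mx <- max(up)
  if (mx > 0) up <- (up - min(up)) / (mx - min(up))
  new("SaliencyMap", data = up, targetClass = targetClass,
      sourceLayer = layerTag)
}

#' Per-stage feature images
#'
#' Channel-mean (or per-channel) activation images for the six stage
#' groups of the network — stem, SFEpath, LTTpath1, LTTpath2, the fused
#' map and the deep feature extraction module — each min-max scaled for
#' display.
#'
#' @param model a [CambnetModel-class].
#' @param patch numeric array `side x side x C`.
#' @param mode `"mean"` for one channel-mean image per stage, or
#'   `"channels"` for a list of per-channel images per stage.
#' @return named list over stages; matrices (`mode = "mean"`) or lists of
#'   matrices (`mode = "channels"`), all scaled to `[0, 1]`.
#' @export
featureGrid <- function(model, patch, mode = c("mean", "channels")) {
  mode <- match.arg(mode)
  if (length(dim(patch)) == 3L) dim(patch) <- c(dim(patch), 1L)
  fw <- cambnetForward(model, patch, keepStages = TRUE)
  groups <- c(stem = "Pre_layer", SFEpath = "SFEpath", LTTpath1 = "Conv2_3",
              LTTpath2 = "Conv3_5", fused = "Fuse", DFEM = "Conv4_5")
  rescale <- function(m) {
    rg <- range(m)
    if (diff(rg) == 0) return(m * 0)
    (m - rg[1]) / diff(rg)
  }
  out <- lapply(groups, function(tag) {
    A <- fw$stages[[tag]]
    d <- dim(A)
    if (mode == "mean") {
      rescale(matrix(rowMeans(matrix(A, d[1] * d[2], d[3])), d[1], d[2]))
    } else {
      lapply(seq_len(d[3]), function(c) rescale(A[, , c, 1]))
    }
  })
  names(out) <- names(groups)
  out
}

#' Crop and resize a contour mask into patch coordinates
#'
#' Applies the same bounding box and bilinear resize as the image
#' preprocessing, then re-binarizes at 0.5, so the mask aligns with the
#' 64 x 64 patch a saliency map explains.
#'
#' @param mask binary matrix in original image coordinates.
#' @param box the [BoundingBox-class] used for the patch.
#' @param size patch side (default 64).
#' @return binary matrix `size x size`.
#' @export
maskToPatch <- function(mask, box, size = 64L) {
  m <- mask
  storage.mode(m) <- "double"
  (cropResize(m, box, size)[, , 1] > 0.5) * 1L
}

#' Saliency localization score
#'
#' Fraction of total saliency mass that falls inside the tumor mask:
#' `sum(saliency[mask]) / sum(saliency)`. A uniform saliency map scores the
#' mask-area fraction, which serves as the per-case chance baseline.
#'
#' @param saliency a [SaliencyMap-class] or numeric matrix.
#' @param mask binary matrix of the same dimensions (tumor support in
#'   patch coordinates, see [maskToPatch()]).
#' @return fraction in `[0, 1]` (0 when the map is identically zero).
#' @export
localizationScore <- function(saliency, mask) {
  s <- if (is(saliency, "SaliencyMap")) saliency@data else saliency
  if (!identical(dim(s), dim(mask)))
    stopNamed("cambnet_shape_error", "saliency/mask dimension mismatch")
  if (sum(mask > 0) == 0)
    stopNamed("cambnet_empty_mask", "mask has no positive pixels")
  tot <- sum(s)
  if (tot == 0) return(0)
  sum(s[mask > 0]) / tot
}
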