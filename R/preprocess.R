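#' @include accessors.R
NULL

#' Bounding box of a tumor contour with margin
#'
#' Finds the extreme positive pixels of the mask in the four directions
#' (the minimum matrix covering the tumor), extends each side by `margin`
#' pixels, and clips to the image frame. Indices in the returned
#' [BoundingBox-class] are 0-based and inclusive.
#'
#' @param mask binary matrix (1 = tumor).
#' @param margin pixels added in each direction (default 10).
#' @return a [BoundingBox-class].
#' @examples
#' m <- matrix(0L, 64, 64); m[13:21, 31:41] <- 1L
#' extractBoundingBox(m)   # rows 2..30, cols 20..50 (0-based)
#' @export
extractBoundingBox <- function(mask, margin = 10L) {
  if (sum(mask > 0) == 0)
    stopNamed("cambnet_empty_mask",
              "mask has no visible region of interest")
  pos <- which(mask > 0, arr.ind = TRUE)
  H <- nrow(mask); W <- ncol(mask)
  new("BoundingBox",
      rowMin = as.integer(max(min(pos[, 1]) - 1L - margin, 0L)),
      rowMax = as.integer(min(max(pos[, 1]) - 1L + margin, H - 1L)),
      colMin = as.integer(max(min(pos[, 2]) - 1L - margin, 0L)),
      colMax = as.integer(min(max(pos[, 2]) - 1L + margin, W - 1L)))
}

#' Crop to a bounding box and bilinearly resize
#'
#' Crops every channel to the box and resizes the rectangular crop directly
#' to a `size x size` square (aspect ratio is not preserved) by bilinear
#' interpolation with half-pixel-center sampling.
#'
#' @param images list of channel matrices (or a single matrix).
#' @param box a [BoundingBox-class] (0-based inclusive indices).
#' @param size output side length (default 64).
#' @return numeric array `size x size x C`.
#' @export
cropResize <- function(images, box, size = 64L) {
  if (is.matrix(images)) images <- list(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  if (box@rowMax >= H || box@colMax >= W)
    stopNamed("cambnet_box_error", "bounding box exceeds image frame")
  rows <- (box@rowMin + 1L):(box@rowMax + 1L)
  cols <- (box@colMin + 1L):(box@colMax + 1L)
  if (length(rows) < 1 || length(cols) < 1)
    stopNamed("cambnet_box_error", "bounding box has zero area")
  C <- length(images)
  crop <- array(0, dim = c(length(rows), length(cols), C))
  for (ch in seq_len(C)) crop[, , ch] <- images[[ch]][rows, cols]
  out <- cpp_bilinear_resize(crop, as.integer(dim(crop)),
                             as.integer(size), as.integer(size))
  array(out, dim = c(size, size, C))
}

#' Normalize / denormalize a patch
#'
#' Per-channel affine normalization `(x - mean) / sd`. The defaults
#' (mean 0.5, sd 0.5 on every channel) map intensities already scaled to
#' `[0, 1]` onto `[-1, 1]`; the transform is label-free and invertible
#' given the constants.
#'
#' @param patch numeric array `H x W x C`.
#' @param mean,sd per-channel constants (recycled across channels).
#' @return the transformed array.
#' @export
normalizePatch <- function(patch, mean = 0.5, sd = 0.5) {
  C <- dim(patch)[3]
  mean <- rep_len(mean, C)
  sd <- rep_len(sd, C)
  if (any(sd == 0))
    stopNamed("cambnet_norm_error", "normalization sd must be non-zero")
  if (any(!is.finite(patch)))
    stopNamed("cambnet_norm_error", "patch contains non-finite values")
  out <- patch
  for (ch in seq_len(C)) out[, , ch] <- (patch[, , ch] - mean[ch]) / sd[ch]
  out
}

#' @rdname normalizePatch
#' @export
denormalizePatch <- function(patch, mean = 0.5, sd = 0.5) {
  C <- dim(patch)[3]
  mean <- rep_len(mean, C)
  sd <- rep_len(sd, C)
  out <- patch
  for (ch in seq_len(C)) out[, , ch] <- patch[, , ch] * sd[ch] + mean[ch]
  out
}

#' Preprocess one contoured case into a normalized ROI patch
#'
#' Contour -> extreme points -> bounding box with margin -> crop ->
#' bilinear resize to `size x size` -> per-channel normalization.
#'
#' @param case a [ContouredCase-class].
#' @param margin bounding-box margin in pixels (default 10).
#' @param size patch side (default 64).
#' @param mean,sd normalization constants.
#' @return numeric array `size x size x C`.
#' @export
preprocessCase <- function(case, margin = 10L, size = 64L,
                           mean = 0.5, sd = 0.5) {
  box <- extractBoundingBox(case@mask, margin)
  normalizePatch(cropResize(case@images, box, size), mean, sd)
}

#' Preprocess a cohort into a patch set
#'
#' Applies [preprocessCase()] to every case and assembles a
#' [RoiPatchSet-class] carrying the per-patch metadata needed downstream
#' (labels and the subgroup covariates).
#'
#' @param cohort a [PhantomCohort-class] (or list of cases plus a metadata
#'   data.frame via `metadata`).
#' @param margin,size,mean,sd see [preprocessCase()].
#' @param metadata optional metadata data.frame when `cohort` is a plain
#'   list of cases.
#' @return a [RoiPatchSet-class].
#' @examples
#' co <- generateCohort(4, spec = phantomSpec(imageSide = 96), seed = 5)
#' ps <- preprocessCohort(co)
#' dim(patchArray(ps))
#' @export
preprocessCohort <- function(cohort, margin = 10L, size = 64L,
                             mean = 0.5, sd = 0.5, metadata = NULL) {
  if (is(cohort, "PhantomCohort")) {
    cases <- cohort@cases
    metadata <- cohort@metadata
  } else {
    cases <- cohort
    if (is.null(metadata))
      metadata <- data.frame(
        patient_id = vapply(cases, function(x) x@patientId, character(1)),
        label = vapply(cases, function(x) x@subtypeLabel, character(1)),
        label4 = vapply(cases, function(x) x@subtypeLabel4, character(1)),
        menarche_age = vapply(cases, function(x) x@menarcheAge, numeric(1)),
        tumor_size_mm = vapply(cases, function(x) x@tumorSizeMm, numeric(1)),
        stringsAsFactors = FALSE)
  }
  n <- length(cases)
  C <- length(cases[[1]]@images)
  data <- array(0, dim = c(size, size, C, n))
  for (i in seq_len(n))
    data[, , , i] <- preprocessCase(cases[[i]], margin, size, mean, sd)
  new("RoiPatchSet", data = data, metadata = metadata,
      normMean = rep_len(mean, C), normSd = rep_len(sd, C))
}
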