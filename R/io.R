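#' @include synthetic.R
NULL

#' Write a cohort to disk
#'
#' One PNG per channel per case (`<id>_ch<k>.png`), one PNG mask
#' (`<id>_mask.png`), and a `metadata.csv` with columns `patient_id`,
#' `label`, `label4`, `menarche_age`, `tumor_size_mm`.
#'
#' @param cohort a [PhantomCohort-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the metadata file path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (case in cohort@cases) {
    for (ch in seq_along(case@images)) {
      png::writePNG(pmin(pmax(case@images[[ch]], 0), 1),
                    file.path(dir, sprintf("%s_ch%d.png",
                                           case@patientId, ch)))
    }
    png::writePNG(case@mask + 0,
                  file.path(dir, sprintf("%s_mask.png", case@patientId)))
  }
  path <- file.path(dir, "metadata.csv")
  write.csv(cohort@metadata, path, row.names = FALSE)
  invisible(path)
}

readImageFile <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopNamed("cambnet_io_error", "the tiff package is required for TIFF input")
    tiff::readTIFF(path)
  } else {
    stopNamed("cambnet_io_error", paste0("unsupported image format: ", path))
  }
  if (length(dim(img)) == 3L) img <- img[, , 1] # grayscale from first plane
  img
}

#' Read a cohort from disk
#'
#' Reads the layout written by [writeCohort()]: `metadata.csv` plus
#' per-case channel and mask PNGs (TIFF channels are also accepted).
#'
#' @param dir cohort directory.
#' @param nChannels channels per case (default: all `<id>_ch*.png` found).
#' @return a [PhantomCohort-class] (with empty `lesionInfo` per case).
#' @export
readCohort <- function(dir, nChannels = NULL) {
  metaPath <- file.path(dir, "metadata.csv")
  if (!file.exists(metaPath))
    stopNamed("cambnet_io_error", paste0("metadata.csv not found in ", dir))
  metadata <- read.csv(metaPath, stringsAsFactors = FALSE)
  cases <- vector("list", nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    id <- metadata$patient_id[i]
    chFiles <- sort(Sys.glob(file.path(dir, paste0(id, "_ch*.png"))))
    if (!is.null(nChannels)) chFiles <- chFiles[seq_len(nChannels)]
    if (!length(chFiles))
      stopNamed("cambnet_io_error", paste0("no channel images for ", id))
    images <- lapply(chFiles, readImageFile)
    maskPath <- file.path(dir, paste0(id, "_mask.png"))
    if (!file.exists(maskPath))
      stopNamed("cambnet_io_error", paste0("mask file missing for ", id))
    maskImg <- readImageFile(maskPath)
    mask <- matrix(as.integer(maskImg > 0.5), nrow(maskImg), ncol(maskImg))
    if (sum(mask) < 1)
      stopNamed("cambnet_empty_mask",
                paste0("mask ", maskPath, " has no visible region of interest"))
    cases[[i]] <- new("ContouredCase",
                      patientId = id, images = images, mask = mask,
                      subtypeLabel = metadata$label[i],
                      subtypeLabel4 = metadata$label4[i],
                      menarcheAge = metadata$menarche_age[i],
                      tumorSizeMm = metadata$tumor_size_mm[i],
                      lesionInfo = list())
  }
  new("PhantomCohort", cases = cases, metadata = metadata,
      spec = phantomSpec())
}
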