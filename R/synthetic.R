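#' @include accessors.R
NULL

# Per-channel contrast multipliers emulating T1WI / T2WI / third-phase DCE:
# the lesion is faintest on T1 and most conspicuous on the enhanced series.
channelContrast <- function(nChannels) {
  mult <- c(0.5, 0.75, 1.0)
  if (nChannels <= 3) mult[seq_len(nChannels)]
  else c(mult, rep(1.0, nChannels - 3))
}

# Four-way sublabel mix within each binary class, following the near-even
# clinical composition of the cohort the generator emulates.
drawLabel4 <- function(classLabel) {
  if (classLabel == "luminal") {
    if (runif(1) < 38 / 85) "luminalA" else "luminalB"
  } else {
    if (runif(1) < 47 / 75) "HER2" else "TN"
  }
}

# Smooth textured background: coarse random field bilinearly upsampled to
# the frame, plus fine pixel noise. Gives the low lesion/background
# contrast its tunable knob.
renderBackground <- function(side, noiseScale) {
  coarse <- array(rnorm(16 * 16), dim = c(16L, 16L, 1L))
  up <- cpp_bilinear_resize(coarse, c(16L, 16L, 1L), side, side)
  fine <- rnorm(side * side, sd = noiseScale / 3)
  matrix(0.35 + noiseScale * up + fine, side, side)
}

#' Isoperimetric boundary-roughness statistic of a binary mask
#'
#' `perimeter^2 / (4 * pi * area)`: 1 for a perfect disc, larger for
#' irregular, spiculated outlines. The perimeter is the total length of
#' 4-neighbour boundary edges (frame edges count as boundary).
#'
#' @param mask binary matrix.
#' @return the roughness statistic (>= 1 up to rasterization effects).
#' @export
maskRoughness <- function(mask) {
  m <- (mask > 0) * 1L
  area <- sum(m)
  if (area == 0) stopNamed("cambnet_empty_mask", "mask has no positive pixels")
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[2:(H + 1), 2:(W + 1)]
  nbr <- pad[1:H, 2:(W + 1)] + pad[3:(H + 2), 2:(W + 1)] +
    pad[2:(H + 1), 1:W] + pad[2:(H + 1), 3:(W + 2)]
  perim <- sum((4L - nbr)[inner == 1L])
  perim^2 / (4 * pi * area)
}

# Maximum caliper diameter of the mask in pixels (via convex hull).
maskMaxDiameter <- function(mask) {
  pts <- which(mask > 0, arr.ind = TRUE)
  if (nrow(pts) == 1) return(1)
  hull <- pts[grDevices::chull(pts[, 2], pts[, 1]), , drop = FALSE]
  d2 <- outer(hull[, 1], hull[, 1], "-")^2 + outer(hull[, 2], hull[, 2], "-")^2
  sqrt(max(d2))
}

#' Generate one phantom case
#'
#' Renders a two-class lesion phantom on a textured background.
#' Luminal-like lesions are ellipses whose boundary is perturbed by radial
#' sinusoidal spiculation (irregular, burr-like margins); non-luminal-like
#' lesions are smooth, nearly round discs with a brighter enhancing annulus.
#' The mask is the rendered lesion support (its 4-connected component
#' containing the lesion centre); tumor size is the mask's maximum caliper
#' diameter converted to millimetres by the spec's pixel spacing; age at
#' menarche is drawn uniformly from the integers 11-17, spanning both sides
#' of the 14-year threshold.
#'
#' @param classLabel `"luminal"` or `"non_luminal"`.
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed (defaults to the spec's seed); the case is a
#'   pure function of `(classLabel, spec, seed)`.
#' @param patientId identifier for the case.
#' @return a [ContouredCase-class].
#' @examples
#' case <- generatePhantom("non_luminal", phantomSpec(imageSide = 96), seed = 7)
#' case
#' @export
generatePhantom <- function(classLabel, spec = phantomSpec(),
                            seed = spec@seed, patientId = "case") {
  if (!is.character(classLabel) || length(classLabel) != 1 ||
      !classLabel %in% SUBTYPES2)
    stopNamed("cambnet_label_error", paste0(
      "classLabel must be one of: ", paste(SUBTYPES2, collapse = ", ")))
  validObject(spec)
  withSeed(seed, {
    S <- spec@imageSide
    cx <- S / 2 + runif(1, -0.06, 0.06) * S
    cy <- S / 2 + runif(1, -0.06, 0.06) * S
    a <- runif(1, spec@lesionRadiusRange[1], spec@lesionRadiusRange[2])
    luminal <- classLabel == "luminal"
    b <- a * if (luminal) runif(1, 0.6, 0.9) else runif(1, 0.9, 1.0)
    theta <- runif(1, 0, pi)
    amp <- if (luminal) spec@spiculationAmplitude else 0
    nLobes <- sample(8:14, 1)
    phase <- runif(1, 0, 2 * pi)

    row <- matrix(seq_len(S), S, S)
    col <- matrix(seq_len(S), S, S, byrow = TRUE)
    dx <- col - cx
    dy <- row - cy
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    rho <- sqrt((u / a)^2 + (v / b)^2)
    phi <- atan2(v / b, u / a)
    boundary <- 1 + amp * sin(nLobes * phi + phase)
    lesion <- (rho <= boundary) * 1L

    mask <- cpp_seed_component(matrix(as.integer(lesion), S, S),
                               as.integer(round(cy)) - 1L,
                               as.integer(round(cx)) - 1L)
    if (sum(mask) < 1)
      stopNamed("cambnet_empty_mask", "rendered lesion has no support")

    mult <- channelContrast(spec@nChannels)
    ring <- (mask == 1L) & rho >= 0.7 & rho <= 1.05
    images <- vector("list", spec@nChannels)
    for (ch in seq_len(spec@nChannels)) {
      img <- renderBackground(S, spec@backgroundNoiseScale)
      img[mask == 1L] <- img[mask == 1L] + 0.3 * mult[ch]
      if (!luminal && spec@ringContrast > 0)
        img[ring] <- img[ring] + spec@ringContrast * mult[ch]
      images[[ch]] <- pmin(pmax(img, 0), 1)
    }

    tumorSize <- maskMaxDiameter(mask) * spec@pixelSpacing
    menarche <- sample(11:17, 1)
    label4 <- drawLabel4(classLabel)

    new("ContouredCase",
        patientId = patientId, images = images, mask = mask,
        subtypeLabel = classLabel, subtypeLabel4 = label4,
        menarcheAge = menarche, tumorSizeMm = tumorSize,
        lesionInfo = list(center = c(cx, cy), axes = c(a, b), theta = theta,
                          spiculationAmplitude = amp, nLobes = nLobes,
                          phase = phase))
  })
}

#' Generate a phantom cohort with metadata table
#'
#' Generates `nCases` phantoms with unique patient ids, split between the
#' luminal-like and non-luminal-like classes by `classBalance`. The defaults
#' (160 cases, balance 84:76) mirror the clinical cohort composition the
#' generator emulates. The cohort is a pure function of `(spec, seed)`.
#'
#' @param nCases number of cases (>= 2; each class gets at least one case).
#' @param classBalance fraction of luminal-like cases.
#' @param spec a [PhantomSpec-class].
#' @param seed integer master seed; per-case seeds are derived from it.
#' @return a [PhantomCohort-class] whose metadata has columns `patient_id`,
#'   `label`, `label4`, `menarche_age`, `tumor_size_mm`.
#' @examples
#' co <- generateCohort(6, spec = phantomSpec(imageSide = 96), seed = 3)
#' cohortMetadata(co)
#' @export
generateCohort <- function(nCases = 160L, classBalance = 84 / 160,
                           spec = phantomSpec(), seed = spec@seed) {
  nCases <- as.integer(nCases)
  if (nCases < 2) stopNamed("cambnet_cohort_error", "nCases must be >= 2")
  nLum <- round(nCases * classBalance)
  nLum <- min(max(nLum, 1L), nCases - 1L)
  labels <- c(rep("luminal", nLum), rep("non_luminal", nCases - nLum))
  ids <- sprintf("P%03d", seq_len(nCases))
  caseSeeds <- withSeed(seed, sample.int(.Machine$integer.max, nCases))
  cases <- vector("list", nCases)
  for (i in seq_len(nCases)) {
    cases[[i]] <- generatePhantom(labels[i], spec, seed = caseSeeds[i],
                                  patientId = ids[i])
  }
  metadata <- data.frame(
    patient_id = ids,
    label = labels,
    label4 = vapply(cases, function(x) x@subtypeLabel4, character(1)),
    menarche_age = vapply(cases, function(x) x@menarcheAge, numeric(1)),
    tumor_size_mm = vapply(cases, function(x) x@tumorSizeMm, numeric(1)),
    stringsAsFactors = FALSE
  )
  new("PhantomCohort", cases = cases, metadata = metadata, spec = spec)
}
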