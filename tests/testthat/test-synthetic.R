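test_that("phantom generation is deterministic and rejects bad labels", {
  spec <- phantomSpec(imageSide = 128)
  a <- generatePhantom("luminal", spec, seed = 7)
  b <- generatePhantom("luminal", spec, seed = 7)
  expect_identical(a@images, b@images)
  expect_identical(a@mask, b@mask)
  expect_identical(a@tumorSizeMm, b@tumorSizeMm)
  expect_identical(a@menarcheAge, b@menarcheAge)
  c <- generatePhantom("luminal", spec, seed = 8)
  expect_false(identical(a@mask, c@mask))
  expect_error(generatePhantom("ductal", spec), class = "cambnet_label_error")
})

test_that("zero spiculation collapses the luminal boundary to a pure ellipse", {
  spec <- phantomSpec(imageSide = 128, spiculationAmplitude = 0)
  case <- generatePhantom("luminal", spec, seed = 5)
  g <- case@lesionInfo
  S <- spec@imageSide
  row <- matrix(seq_len(S), S, S)
  col <- matrix(seq_len(S), S, S, byrow = TRUE)
  dx <- col - g$center[1]; dy <- row - g$center[2]
  u <- dx * cos(g$theta) + dy * sin(g$theta)
  v <- -dx * sin(g$theta) + dy * cos(g$theta)
  ellipse <- ((u / g$axes[1])^2 + (v / g$axes[2])^2 <= 1) * 1L
  expect_identical(unname(as.vector(case@mask)), as.vector(ellipse))
  expect_equal(maskRoughness(case@mask), maskRoughness(ellipse))
})

test_that("luminal-like masks are rougher than non-luminal-like masks", {
  spec <- phantomSpec()
  rough <- function(cl, seeds) vapply(seeds, function(s)
    maskRoughness(caseMask(generatePhantom(cl, spec, seed = s))), numeric(1))
  seeds <- 1:100
  expect_gt(mean(rough("luminal", seeds)),
            mean(rough("non_luminal", seeds + 1000)))
})

test_that("masks stay inside the frame and are 4-connected", {
  co <- smallCohort()
  for (case in cohortCases(co)) {
    m <- caseMask(case)
    expect_true(sum(m) >= 1)
    # no positive pixel on the frame border (fully contained)
    expect_true(all(m[1, ] == 0) && all(m[nrow(m), ] == 0) &&
                  all(m[, 1] == 0) && all(m[, ncol(m)] == 0))
    expect_true(isFourConnected(m))
  }
})

test_that("default cohort mirrors the 84:76 class composition", {
  co <- generateCohort(160, spec = phantomSpec(imageSide = 96), seed = 31)
  md <- cohortMetadata(co)
  expect_equal(sum(md$label == "luminal"), 84)
  expect_equal(sum(md$label == "non_luminal"), 76)
  expect_false(anyDuplicated(md$patient_id) > 0)
  # both covariate strata populated on either side of the thresholds
  expect_true(all(table(md$menarche_age <= 14) > 0))
  expect_true(all(table(md$tumor_size_mm <= 20) > 0))
  expect_true(all(sort(unique(md$label4)) %in%
                    c("HER2", "TN", "luminalA", "luminalB")))
})

test_that("cohort generation handles edge sizes and is a pure function of seed", {
  expect_error(generateCohort(1, spec = phantomSpec(imageSide = 96)),
               class = "cambnet_cohort_error")
  co2 <- generateCohort(2, spec = phantomSpec(imageSide = 96), seed = 3)
  expect_setequal(cohortMetadata(co2)$label, c("luminal", "non_luminal"))
  a <- generateCohort(8, spec = phantomSpec(imageSide = 96), seed = 12)
  b <- generateCohort(8, spec = phantomSpec(imageSide = 96), seed = 12)
  expect_identical(cohortMetadata(a), cohortMetadata(b))
  expect_identical(caseImages(cohortCases(a)[[5]]),
                   caseImages(cohortCases(b)[[5]]))
})

test_that("two hand-crafted mask features separate the classes", {
  co <- studyCohort()
  feats <- t(vapply(cohortCases(co), function(case) {
    m <- caseMask(case)
    dce <- caseImages(case)[[length(caseImages(case))]]
    # ring feature: boundary band vs eroded core intensity
    er <- m
    for (k in 1:3) {
      H <- nrow(er); W <- ncol(er)
      pad <- matrix(0L, H + 2, W + 2)
      pad[2:(H + 1), 2:(W + 1)] <- er
      er <- er * (pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
                    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)])
    }
    band <- m == 1 & er == 0
    ring <- if (any(er == 1)) mean(dce[band]) - mean(dce[er == 1]) else 0
    c(maskRoughness(m), ring)
  }, numeric(2)))
  y <- as.integer(cohortMetadata(co)$label == "luminal")
  fit <- suppressWarnings(glm(y ~ feats[, 1] + feats[, 2],
                              family = binomial))
  acc <- mean((fitted(fit) > 0.5) == (y == 1))
  expect_gt(acc, 0.9)
})

test_that("cohorts round-trip through the PNG + CSV layout", {
  dir <- withr::local_tempdir()
  co <- generateCohort(4, spec = phantomSpec(imageSide = 96), seed = 9)
  writeCohort(co, dir)
  back <- readCohort(dir)
  md <- cohortMetadata(back)
  expect_identical(md$patient_id, cohortMetadata(co)$patient_id)
  expect_identical(md$label, cohortMetadata(co)$label)
  # masks survive exactly; images up to 8-bit quantization
  expect_identical(caseMask(cohortCases(back)[[1]]),
                   caseMask(cohortCases(co)[[1]]))
  expect_lt(max(abs(caseImages(cohortCases(back)[[2]])[[1]] -
                      caseImages(cohortCases(co)[[2]])[[1]])), 1 / 255)
})
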