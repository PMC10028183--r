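test_that("Grad-CAM maps are normalized, aligned and deterministic", {
  m <- buildCambnet(seed = 41)
  set.seed(41)
  x <- array(rnorm(64 * 64 * 3), dim = c(64, 64, 3))
  sal <- gradCam(m, x, targetClass = 1)
  expect_s4_class(sal, "SaliencyMap")
  expect_equal(dim(saliencyData(sal)), c(64, 64))
  expect_true(all(saliencyData(sal) >= 0 & saliencyData(sal) <= 1))
  expect_equal(max(saliencyData(sal)), 1)
  expect_identical(saliencyData(gradCam(m, x, targetClass = 1)),
                   saliencyData(sal))
  expect_error(gradCam(m, x, layerTag = "nonsense"),
               class = "cambnet_layer_error")
  expect_match(tryCatch(gradCam(m, x, layerTag = "zzz"),
                        error = conditionMessage), "Conv4_5")
})

test_that("a constant logit yields the all-zero map", {
  m <- buildCambnet(seed = 42)
  m@params$fc$w[] <- 0 # logits no longer depend on the input
  x <- array(rnorm(64 * 64 * 3), dim = c(64, 64, 3))
  sal <- gradCam(m, x, targetClass = 2)
  expect_true(all(saliencyData(sal) == 0))
})

test_that("the pooled-stage map matches the analytic classifier gradient", {
  # At the Maxpool4_6 stage the target logit is w . GAP(A) + b, so the
  # Grad-CAM channel weights are exactly fc$w[, k] / (8*8); the map is
  # reproducible in closed form from the stage activations alone.
  m <- buildCambnet(cambnetConfig(dropoutRate = 0), seed = 43)
  set.seed(43)
  x <- array(rnorm(64 * 64 * 3), dim = c(64, 64, 3))
  fw <- cambnetForward(m, array(x, dim = c(64, 64, 3, 1)),
                       keepStages = TRUE)
  A <- fw$stages$Maxpool4_6[, , , 1]
  checked <- 0
  for (k in 1:2) {
    sal <- gradCam(m, x, targetClass = k, layerTag = "Maxpool4_6")
    wts <- m@params$fc$w[, k] / (8 * 8)
    cam <- matrix(0, 8, 8)
    for (ch in seq_len(64)) cam <- cam + wts[ch] * A[, , ch]
    cam[cam < 0] <- 0
    up <- bilinearOracle(cam, 64, 64)
    if (max(up) > 0) {
      up <- (up - min(up)) / (max(up) - min(up))
      checked <- checked + 1
    }
    expect_equal(saliencyData(sal), up, tolerance = 1e-10)
  }
  expect_gt(checked, 0) # at least one class produced a non-trivial map
})

test_that("logits are invariant to batch padding with other samples", {
  m <- buildCambnet(seed = 44)
  set.seed(44)
  x <- array(rnorm(64 * 64 * 3 * 3), dim = c(64, 64, 3, 3))
  alone <- cambnetForward(m, x[, , , 1, drop = FALSE])$logits
  padded <- cambnetForward(m, x)$logits[, 1, drop = FALSE]
  expect_equal(alone, padded, tolerance = 1e-12)
})

test_that("feature grids cover the six stage groups and rescale to [0,1]", {
  m <- buildCambnet(seed = 45)
  set.seed(45)
  x <- array(rnorm(64 * 64 * 3), dim = c(64, 64, 3))
  g <- featureGrid(m, x)
  expect_named(g, c("stem", "SFEpath", "LTTpath1", "LTTpath2", "fused",
                    "DFEM"))
  for (img in g) {
    expect_true(all(img >= 0 & img <= 1))
  }
  expect_equal(dim(g$stem), c(64, 64))
  expect_equal(dim(g$DFEM), c(16, 16))
  # constant input: the stem map is constant away from the padded border
  gc <- featureGrid(m, array(0.3, dim = c(64, 64, 3)))
  interior <- gc$stem[3:62, 3:62]
  expect_lt(diff(range(interior)), 1e-12)
  # per-channel mode returns one image per channel
  gch <- featureGrid(m, x, mode = "channels")
  expect_length(gch$LTTpath1, 16)
  expect_identical(featureGrid(m, x), g)
})

test_that("localization score is the in-mask saliency fraction", {
  s <- matrix(0, 64, 64)
  mask <- matrix(0L, 64, 64)
  mask[20:40, 20:40] <- 1L
  s[25:30, 25:30] <- 1
  expect_equal(localizationScore(s, mask), 1)
  uniform <- matrix(1, 64, 64)
  expect_equal(localizationScore(uniform, mask), mean(mask > 0))
  expect_error(localizationScore(s, matrix(0L, 64, 64)),
               class = "cambnet_empty_mask")
  expect_error(localizationScore(s, mask[1:32, 1:32]),
               class = "cambnet_shape_error")
  expect_equal(localizationScore(matrix(0, 64, 64), mask), 0)
})

test_that("mask projection follows the preprocessing geometry", {
  co <- smallCohort()
  case <- cohortCases(co)[[1]]
  box <- extractBoundingBox(caseMask(case))
  pm <- maskToPatch(caseMask(case), box)
  expect_equal(dim(pm), c(64, 64))
  expect_true(all(pm %in% c(0L, 1L)))
  expect_gt(sum(pm), 0)
})
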