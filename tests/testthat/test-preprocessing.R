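test_that("bounding box matches the min/max +- margin arithmetic oracle", {
  m <- matrix(0L, 64, 64)
  m[13:21, 31:41] <- 1L  # 0-based rows 12-20, cols 30-40
  box <- extractBoundingBox(m, margin = 10)
  expect_equal(c(box@rowMin, box@rowMax, box@colMin, box@colMax),
               c(2L, 30L, 20L, 50L))
  tight <- extractBoundingBox(m, margin = 0)
  expect_equal(c(tight@rowMin, tight@rowMax, tight@colMin, tight@colMax),
               c(12L, 20L, 30L, 40L))
})

test_that("bounding box clips at the frame and rejects empty masks", {
  m <- matrix(0L, 32, 32)
  m[1:4, 30:32] <- 1L
  box <- extractBoundingBox(m, margin = 10)
  expect_equal(box@rowMin, 0L)
  expect_equal(box@colMax, 31L)
  expect_error(extractBoundingBox(matrix(0L, 8, 8)),
               class = "cambnet_empty_mask")
})

test_that("the box always covers the mask and shrinking margin never grows it", {
  set.seed(20)
  for (rep in 1:25) {
    m <- matrix(0L, 48, 48)
    r <- sort(sample(48, 2)); cc <- sort(sample(48, 2))
    m[r[1]:r[2], cc[1]:cc[2]] <- 1L
    prev <- NULL
    for (margin in c(12, 8, 4, 0)) {
      box <- extractBoundingBox(m, margin)
      pos <- which(m > 0, arr.ind = TRUE) - 1L
      expect_true(all(pos[, 1] >= box@rowMin & pos[, 1] <= box@rowMax &
                        pos[, 2] >= box@colMin & pos[, 2] <= box@colMax))
      if (!is.null(prev)) {
        expect_gte(box@rowMin, prev@rowMin)
        expect_lte(box@rowMax, prev@rowMax)
        expect_gte(box@colMin, prev@colMin)
        expect_lte(box@colMax, prev@colMax)
      }
      prev <- box
    }
  }
})

test_that("bilinear resize preserves constants and the identity", {
  box <- new("BoundingBox", rowMin = 0L, rowMax = 31L,
             colMin = 0L, colMax = 31L)
  const <- matrix(0.42, 32, 32)
  out <- cropResize(const, box, size = 64)
  expect_equal(dim(out), c(64, 64, 1))
  expect_true(all(abs(out - 0.42) < 1e-12))

  img <- matrix(rnorm(64 * 64), 64, 64)
  idBox <- new("BoundingBox", rowMin = 0L, rowMax = 63L,
               colMin = 0L, colMax = 63L)
  expect_equal(cropResize(img, idBox, size = 64)[, , 1], img)
})

test_that("upsampling matches the half-pixel-center closed form", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  box <- new("BoundingBox", rowMin = 0L, rowMax = 1L, colMin = 0L,
             colMax = 1L)
  up <- cropResize(m, box, size = 4)[, , 1]
  expect_equal(up, bilinearOracle(m, 4, 4))
  # the patch centre interpolates all four corners equally
  expect_equal(mean(up[2:3, 2:3]), 0.5)

  m2 <- matrix(rnorm(35), 5, 7)
  box2 <- new("BoundingBox", rowMin = 0L, rowMax = 4L, colMin = 0L,
              colMax = 6L)
  expect_equal(cropResize(m2, box2, size = 16)[, , 1],
               bilinearOracle(m2, 16, 16))
})

test_that("normalization is the configured affine map and inverts exactly", {
  p <- array(0.5, dim = c(4, 4, 3))
  expect_true(all(normalizePatch(p) == 0))
  set.seed(4)
  q <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  n <- normalizePatch(q, mean = c(0.2, 0.5, 0.7), sd = c(0.1, 0.5, 2))
  oracle <- q
  for (ch in 1:3) oracle[, , ch] <-
      (q[, , ch] - c(0.2, 0.5, 0.7)[ch]) / c(0.1, 0.5, 2)[ch]
  expect_equal(n, oracle)
  expect_equal(denormalizePatch(n, mean = c(0.2, 0.5, 0.7),
                                sd = c(0.1, 0.5, 2)), q,
               tolerance = 1e-12)
  expect_error(normalizePatch(q, sd = 0), class = "cambnet_norm_error")
})

test_that("the case pipeline yields 64 x 64 x C patches deterministically", {
  co <- smallCohort()
  for (case in cohortCases(co)[1:4]) {
    p <- preprocessCase(case)
    expect_equal(dim(p), c(64, 64, 3))
    expect_true(all(is.finite(p)))
    expect_identical(p, preprocessCase(case))
  }
  ps <- preprocessCohort(co)
  expect_equal(dim(patchArray(ps)), c(64, 64, 3, 16))
  expect_identical(patchMetadata(ps)$patient_id,
                   cohortMetadata(co)$patient_id)
})
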