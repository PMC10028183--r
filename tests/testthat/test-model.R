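test_that("forward pass produces logits of the configured arity", {
  m <- buildCambnet(seed = 1)
  x <- array(rnorm(64 * 64 * 3), dim = c(64, 64, 3, 1))
  fw <- cambnetForward(m, x)
  expect_equal(dim(fw$logits), c(2, 1))
  m4 <- buildCambnet(cambnetConfig(nClasses = 4), seed = 1)
  expect_equal(dim(cambnetForward(m4, x)$logits), c(4, 1))
  expect_error(cambnetForward(m, array(0, dim = c(32, 32, 3, 1))),
               class = "cambnet_shape_error")
})

test_that("trainable parameter count matches the layer-by-layer hand count", {
  m <- buildCambnet(seed = 1)
  conv <- function(kh, kw, cin, cout) kh * kw * cin * cout
  bn <- function(c) 2 * c
  se <- function(c, cb) c * cb + cb + cb * c + c
  expected <-
    conv(3, 3, 3, 16) + bn(16) +                          # stem
    conv(1, 1, 16, 128) + bn(128) +                       # SFE expand
    conv(3, 3, 1, 128) + bn(128) +                        # SFE depthwise
    se(128, 8) +                                          # SFE SE (ratio 16)
    conv(1, 1, 128, 16) + bn(16) +                        # SFE reduce
    conv(1, 1, 16, 8) + bn(8) +                           # LTT1 bottleneck
    conv(3, 3, 1, 8) + bn(8) +                            # LTT1 depthwise
    conv(1, 1, 8, 16) + bn(16) +                          # LTT1 expand
    conv(1, 1, 16, 4) + bn(4) +                           # LTT2 plan
    conv(1, 3, 4, 8) + bn(8) +
    conv(3, 1, 8, 8) + bn(8) +
    conv(1, 3, 8, 8) + bn(8) +
    conv(3, 1, 8, 16) + bn(16) +
    se(16, 4) +                                           # channel attention
    conv(7, 7, 1, 1) + 1 +                                # spatial attention
    conv(1, 1, 32, 128) + bn(128) +                       # DFEM expand
    conv(3, 3, 1, 128) + bn(128) +                        # DFEM depthwise
    se(128, 8) +                                          # DFEM SE
    conv(1, 1, 128, 64) + bn(64) +                        # DFEM reduce
    64 * 2 + 2                                            # classifier
  expect_equal(countParams(m), expected)
})

test_that("asymmetric LTTpath2 kernels are cheaper than square equivalents", {
  m <- buildCambnet(seed = 1)
  dims <- lapply(m@params$ltt2[-1], function(p) dim(p$w))
  asym <- sum(vapply(dims, prod, numeric(1)))
  square <- sum(vapply(dims, function(d) 3 * 3 * d[3] * d[4], numeric(1)))
  expect_lt(asym, square)
  # kernels alternate 1x3 / 3x1
  expect_equal(dims[[1]][1:2], c(1L, 3L))
  expect_equal(dims[[2]][1:2], c(3L, 1L))
  expect_equal(dims[[3]][1:2], c(1L, 3L))
  expect_equal(dims[[4]][1:2], c(3L, 1L))
})

test_that("zeroing the SFE conv path reduces the branch to the residual", {
  m <- buildCambnet(seed = 2)
  m@params$sfe$conv2$w[] <- 0
  m@params$sfe$conv2$gamma[] <- 0
  m@params$sfe$conv2$beta[] <- 0
  x <- array(rnorm(64 * 64 * 3 * 2), dim = c(64, 64, 3, 2))
  fw <- cambnetForward(m, x, keepStages = TRUE)
  expect_equal(fw$stages$SFEpath, fw$stages$Pre_layer)
})

test_that("SE and attention gates lie strictly in (0, 1) and rescale exactly", {
  m <- buildCambnet(seed = 3)
  x <- array(rnorm(64 * 64 * 3 * 2), dim = c(64, 64, 3, 2))
  fw <- cambnetForward(m, x, keepStages = TRUE)
  att <- fw$attention
  expect_true(all(att$channelWeights > 0 & att$channelWeights < 1))
  expect_true(all(att$spatialWeights > 0 & att$spatialWeights < 1))
  expect_true(all(att$sfeSeWeights > 0 & att$sfeSeWeights < 1))
  expect_true(all(att$dfemSeWeights > 0 & att$dfemSeWeights < 1))
  # SE output equals input rescaled channelwise (direct recomputation)
  p <- m@params$sfe$se
  a <- fw$stages$Dwconv1_2
  seOut <- fw$stages$SEB1_3
  d <- dim(a)
  for (n in 1:2) for (ch in c(1, 64, 128)) {
    z <- colMeans(matrix(a[, , , n], d[1] * d[2], d[3]))
    h <- pmax(t(p$w1) %*% z + p$b1, 0)
    s <- 1 / (1 + exp(-(t(p$w2) %*% h + p$b2)))
    expect_equal(seOut[, , ch, n], a[, , ch, n] * s[ch], tolerance = 1e-12)
  }
})

test_that("cross-attention gates the branches in the configured direction", {
  x <- array(rnorm(64 * 64 * 3), dim = c(64, 64, 3, 1))
  m <- buildCambnet(seed = 4)
  fw <- cambnetForward(m, x, keepStages = TRUE)
  # default wiring: LTT1 gated spatially, LTT2 gated channelwise
  sw <- matrix(fw$attention$spatialWeights, 64 * 64, 1)
  expect_equal(matrix(fw$stages$Cross_Attention_LTT1[, , 5, 1], ncol = 1),
               matrix(fw$stages$Conv2_3[, , 5, 1] * matrix(sw, 64, 64),
                      ncol = 1))
  cw <- fw$attention$channelWeights
  expect_equal(fw$stages$Cross_Attention_LTT2[, , 7, 1],
               fw$stages$Conv3_5[, , 7, 1] * cw[7, 1])
  # mirrored wiring swaps the roles
  m2 <- buildCambnet(cambnetConfig(attentionWiring = "ch2_sp1"), seed = 4)
  fw2 <- cambnetForward(m2, x, keepStages = TRUE)
  cw2 <- fw2$attention$channelWeights
  expect_equal(fw2$stages$Cross_Attention_LTT1[, , 3, 1],
               fw2$stages$Conv2_3[, , 3, 1] * cw2[3, 1])
})

test_that("branch fusion adds the LTT paths and concatenates SFE", {
  m <- buildCambnet(seed = 5)
  x <- array(rnorm(64 * 64 * 3), dim = c(64, 64, 3, 1))
  fw <- cambnetForward(m, x, keepStages = TRUE)
  fused <- fw$stages$Fuse
  expect_equal(dim(fused)[3], 32)
  expect_equal(fused[, , 1:16, , drop = FALSE],
               fw$stages$Cross_Attention_LTT1 +
                 fw$stages$Cross_Attention_LTT2)
  expect_equal(fused[, , 17:32, , drop = FALSE], fw$stages$SFEpath)
})

test_that("forward is deterministic and batch-equivariant", {
  m <- buildCambnet(seed = 6)
  x <- array(rnorm(64 * 64 * 3 * 4), dim = c(64, 64, 3, 4))
  l1 <- cambnetForward(m, x)$logits
  l2 <- cambnetForward(m, x)$logits
  expect_identical(l1, l2)
  perm <- c(3, 1, 4, 2)
  lp <- cambnetForward(m, x[, , , perm])$logits
  expect_equal(lp, l1[, perm], tolerance = 1e-10)
})

test_that("every parameter tensor receives gradient signal", {
  m <- buildCambnet(cambnetConfig(dropoutRate = 0), seed = 7)
  x <- array(rnorm(64 * 64 * 3 * 4), dim = c(64, 64, 3, 4))
  y <- c(1L, 2L, 1L, 2L)
  fw <- cambnetForward(m, x, training = TRUE, keepCache = TRUE)
  sm <- cambnet:::softmaxXent(fw$logits, y)
  bw <- cambnet:::cambnetBackward(m, fw$cache, sm$gLogits)
  walk <- function(g, path) {
    if (is.list(g)) {
      for (nm in names(g)) walk(g[[nm]], c(path, nm))
    } else {
      expect_gt(sqrt(sum(g^2)), 0,
                label = paste0("gradient norm of ",
                               paste(path, collapse = "$")))
    }
  }
  walk(bw$grads, character())
})

test_that("stage summary prints the realized shape table", {
  m <- buildCambnet(seed = 8)
  out <- capture.output(shapes <- summary(m))
  expect_true(any(grepl("Dwconv1_2", out)))
  expect_equal(shapes$Fc4_7, c(2L, 1L))
})
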