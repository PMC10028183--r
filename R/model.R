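#' @include AllClasses.R nn-ops.R
NULL

#' Construct a CAMBNET architecture configuration
#'
#' Defaults realize the published per-stage dimension plan exactly; see
#' [CambnetConfig-class] for the meaning of each knob and [stageShapes()]
#' for a programmatic dump of the realized shapes.
#'
#' @param inputSide,inChannels input patch geometry.
#' @param stemChannels,sfeExpansionChannels,ltt1BottleneckChannels
#'   stem / SFEpath / LTTpath1 widths.
#' @param ltt2ChannelPlan LTTpath2 channel plan (five stages).
#' @param branchOutChannels common branch output width.
#' @param dfemExpansionChannels,dfemOutChannels DFEM widths.
#' @param nClasses number of classes.
#' @param seReductionRatio squeeze-and-excitation reduction ratio.
#' @param dropoutRate classifier dropout probability.
#' @param attentionKernelSize spatial-attention kernel size (odd).
#' @param attentionWiring `"ch1_sp2"` (default) or `"ch2_sp1"`; see
#'   [CambnetConfig-class].
#' @return a validated [CambnetConfig-class].
#' @examples
#' cfg <- cambnetConfig()
#' cfg@sfeExpansionChannels
#' @export
cambnetConfig <- function(inputSide = 64L, inChannels = 3L,
                          stemChannels = 16L,
                          sfeExpansionChannels = 128L,
                          ltt1BottleneckChannels = 8L,
                          ltt2ChannelPlan = c(4L, 8L, 8L, 8L, 16L),
                          branchOutChannels = 16L,
                          dfemExpansionChannels = 128L,
                          dfemOutChannels = 64L,
                          nClasses = 2L,
                          seReductionRatio = 16L,
                          dropoutRate = 0.5,
                          attentionKernelSize = 7L,
                          attentionWiring = "ch1_sp2") {
  new("CambnetConfig",
      inputSide = as.integer(inputSide), inChannels = as.integer(inChannels),
      stemChannels = as.integer(stemChannels),
      sfeExpansionChannels = as.integer(sfeExpansionChannels),
      ltt1BottleneckChannels = as.integer(ltt1BottleneckChannels),
      ltt2ChannelPlan = as.integer(ltt2ChannelPlan),
      branchOutChannels = as.integer(branchOutChannels),
      dfemExpansionChannels = as.integer(dfemExpansionChannels),
      dfemOutChannels = as.integer(dfemOutChannels),
      nClasses = as.integer(nClasses),
      seReductionRatio = as.integer(seReductionRatio),
      dropoutRate = as.numeric(dropoutRate),
      attentionKernelSize = as.integer(attentionKernelSize),
      attentionWiring = attentionWiring)
}

seBottleneck <- function(channels, ratio) max(channels %/% ratio, 4L)

initConv <- function(kh, kw, cg, cout) {
  fanIn <- kh * kw * cg
  array(rnorm(kh * kw * cg * cout, sd = sqrt(2 / fanIn)),
        dim = c(kh, kw, cg, cout))
}

# Convolutions feeding batch norm carry no bias: the BN shift makes a
# conv bias redundant (its gradient is annihilated by the mean-centering).
initCbr <- function(kh, kw, cg, cout) {
  list(w = initConv(kh, kw, cg, cout),
       gamma = rep(1, cout), beta = numeric(cout))
}

initSe <- function(channels, ratio) {
  cb <- seBottleneck(channels, ratio)
  list(w1 = matrix(rnorm(channels * cb, sd = sqrt(2 / channels)), channels, cb),
       b1 = numeric(cb),
       w2 = matrix(rnorm(cb * channels, sd = sqrt(2 / cb)), cb, channels),
       b2 = numeric(channels))
}

bnState <- function(cout) list(mean = numeric(cout), var = rep(1, cout))

#' Build a CAMBNET model
#'
#' Allocates and initializes all trainable parameters (Kaiming-style normal
#' initialization for convolution and linear weights, zero biases, unit
#' batch-norm scale) under a fixed seed.
#'
#' @param config a [CambnetConfig-class]; default configuration if omitted.
#' @param seed integer seed for weight initialization.
#' @return a [CambnetModel-class].
#' @examples
#' model <- buildCambnet(seed = 1)
#' model
#' @export
buildCambnet <- function(config = cambnetConfig(), seed = 1L) {
  validObject(config)
  cb <- config@branchOutChannels
  plan <- config@ltt2ChannelPlan
  if (config@ltt2ChannelPlan[5] != cb)
    stopNamed("cambnet_config_error",
              "stage Conv3_5: LTTpath2 must end at branchOutChannels")
  withSeed(seed, {
    params <- list(
      pre = initCbr(3L, 3L, config@inChannels, config@stemChannels),
      sfe = list(
        conv1 = initCbr(1L, 1L, cb, config@sfeExpansionChannels),
        dw = initCbr(3L, 3L, 1L, config@sfeExpansionChannels),
        se = initSe(config@sfeExpansionChannels, config@seReductionRatio),
        conv2 = initCbr(1L, 1L, config@sfeExpansionChannels, cb)
      ),
      ltt1 = list(
        conv1 = initCbr(1L, 1L, cb, config@ltt1BottleneckChannels),
        dw = initCbr(3L, 3L, 1L, config@ltt1BottleneckChannels),
        conv2 = initCbr(1L, 1L, config@ltt1BottleneckChannels, cb)
      ),
      ltt2 = list(
        conv1 = initCbr(1L, 1L, cb, plan[1]),
        conv2 = initCbr(1L, 3L, plan[1], plan[2]),
        conv3 = initCbr(3L, 1L, plan[2], plan[3]),
        conv4 = initCbr(1L, 3L, plan[3], plan[4]),
        conv5 = initCbr(3L, 1L, plan[4], plan[5])
      ),
      ca = list(
        ch = initSe(cb, config@seReductionRatio),
        sp = list(w = initConv(config@attentionKernelSize,
                               config@attentionKernelSize, 1L, 1L),
                  b = numeric(1))
      ),
      dfem = list(
        conv1 = initCbr(1L, 1L, 2L * cb, config@dfemExpansionChannels),
        dw = initCbr(3L, 3L, 1L, config@dfemExpansionChannels),
        se = initSe(config@dfemExpansionChannels, config@seReductionRatio),
        conv2 = initCbr(1L, 1L, config@dfemExpansionChannels,
                        config@dfemOutChannels)
      ),
      fc = list(
        w = matrix(rnorm(config@dfemOutChannels * config@nClasses,
                         sd = sqrt(2 / config@dfemOutChannels)),
                   config@dfemOutChannels, config@nClasses),
        b = numeric(config@nClasses)
      )
    )
    state <- list(
      pre = bnState(config@stemChannels),
      sfe = list(conv1 = bnState(config@sfeExpansionChannels),
                 dw = bnState(config@sfeExpansionChannels),
                 conv2 = bnState(cb)),
      ltt1 = list(conv1 = bnState(config@ltt1BottleneckChannels),
                  dw = bnState(config@ltt1BottleneckChannels),
                  conv2 = bnState(cb)),
      ltt2 = list(conv1 = bnState(plan[1]), conv2 = bnState(plan[2]),
                  conv3 = bnState(plan[3]), conv4 = bnState(plan[4]),
                  conv5 = bnState(plan[5])),
      dfem = list(conv1 = bnState(config@dfemExpansionChannels),
                  dw = bnState(config@dfemExpansionChannels),
                  conv2 = bnState(config@dfemOutChannels))
    )
    new("CambnetModel", config = config, params = params, state = state)
  })
}

#' Total number of trainable parameters
#'
#' Counts every convolution kernel, bias, batch-norm scale/shift,
#' squeeze-and-excitation bottleneck and classifier weight.
#'
#' @param model a [CambnetModel-class].
#' @return integer parameter count.
#' @export
countParams <- function(model) {
  sumLeaves(model@params, length)
}

checkInput <- function(x, config) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(d) != 4L || d[1] != config@inputSide || d[2] != config@inputSide ||
      d[3] != config@inChannels)
    stopNamed("cambnet_shape_error", sprintf(
      "input must be %d x %d x %d (x N), got %s",
      config@inputSide, config@inputSide, config@inChannels,
      paste(d, collapse = " x ")))
  x
}

#' Forward pass through CAMBNET
#'
#' Runs a batch through the network, optionally keeping per-stage
#' activations (named after the per-stage dimension plan) and the caches
#' required for a backward pass.
#'
#' @param model a [CambnetModel-class].
#' @param x numeric array `side x side x C` or `side x side x C x N`.
#' @param training logical; use batch statistics and dropout (also updates
#'   and returns batch-norm running statistics).
#' @param keepCache keep backward-pass caches.
#' @param keepStages keep per-stage activations and attention maps.
#' @return list with `logits` (`nClasses x N`), and when requested `stages`
#'   (named list of activations), `attention` (channel and spatial attention
#'   weights, all strictly in (0, 1)), `cache`, and `state` (updated
#'   batch-norm running statistics when `training = TRUE`).
#' @export
cambnetForward <- function(model, x, training = FALSE, keepCache = FALSE,
                           keepStages = FALSE) {
  cfg <- model@config
  p <- model@params
  st <- model@state
  x <- checkInput(x, cfg)
  cb <- cfg@branchOutChannels

  pre <- cbrFwd(x, p$pre, st$pre, training, ph = 1L, pw = 1L)
  stem <- pre$y

  # SFEpath: expand -> depthwise -> SE -> reduce -> residual add
  s1 <- cbrFwd(stem, p$sfe$conv1, st$sfe$conv1, training)
  s2 <- cbrFwd(s1$y, p$sfe$dw, st$sfe$dw, training, ph = 1L, pw = 1L,
               groups = cfg@sfeExpansionChannels)
  sse <- seGateFwd(s2$y, s2$y, p$sfe$se)
  s3 <- cbrFwd(sse$y, p$sfe$conv2, st$sfe$conv2, training)
  sfeOut <- s3$y + stem

  # LTTpath1: bottleneck -> depthwise -> expand
  l1a <- cbrFwd(stem, p$ltt1$conv1, st$ltt1$conv1, training)
  l1b <- cbrFwd(l1a$y, p$ltt1$dw, st$ltt1$dw, training, ph = 1L, pw = 1L,
                groups = cfg@ltt1BottleneckChannels)
  l1c <- cbrFwd(l1b$y, p$ltt1$conv2, st$ltt1$conv2, training)
  ltt1Out <- l1c$y

  # LTTpath2: 1x1 then alternating asymmetric 1x3 / 3x1 convolutions
  l2a <- cbrFwd(stem, p$ltt2$conv1, st$ltt2$conv1, training)
  l2b <- cbrFwd(l2a$y, p$ltt2$conv2, st$ltt2$conv2, training, ph = 0L, pw = 1L)
  l2c <- cbrFwd(l2b$y, p$ltt2$conv3, st$ltt2$conv3, training, ph = 1L, pw = 0L)
  l2d <- cbrFwd(l2c$y, p$ltt2$conv4, st$ltt2$conv4, training, ph = 0L, pw = 1L)
  l2e <- cbrFwd(l2d$y, p$ltt2$conv5, st$ltt2$conv5, training, ph = 1L, pw = 0L)
  ltt2Out <- l2e$y

  # Cross-attention: channel attention from one path gates the other;
  # spatial attention crosses in the opposite direction.
  if (cfg@attentionWiring == "ch1_sp2") {
    chGate <- seGateFwd(ltt1Out, ltt2Out, p$ca$ch)  # -> gated LTT2
    spGate <- spatGateFwd(ltt2Out, ltt1Out, p$ca$sp) # -> gated LTT1
    attA <- spGate$y
    attB <- chGate$y
  } else {
    chGate <- seGateFwd(ltt2Out, ltt1Out, p$ca$ch)  # -> gated LTT1
    spGate <- spatGateFwd(ltt1Out, ltt2Out, p$ca$sp) # -> gated LTT2
    attA <- chGate$y
    attB <- spGate$y
  }

  # Fusion: LTT paths add; SFEpath concatenates (LTT sum first)
  lttSum <- attA + attB
  dF <- dim(lttSum)
  fused <- array(0, dim = c(dF[1], dF[2], 2L * cb, dF[4]))
  fused[, , seq_len(cb), ] <- lttSum
  fused[, , cb + seq_len(cb), ] <- sfeOut

  # DFEM
  mp1 <- maxpool2Fwd(fused)
  d1 <- cbrFwd(mp1$y, p$dfem$conv1, st$dfem$conv1, training)
  d2 <- cbrFwd(d1$y, p$dfem$dw, st$dfem$dw, training, stride = 2L,
               ph = 1L, pw = 1L, groups = cfg@dfemExpansionChannels)
  dse <- seGateFwd(d2$y, d2$y, p$dfem$se)
  d3 <- cbrFwd(dse$y, p$dfem$conv2, st$dfem$conv2, training)
  mp2 <- maxpool2Fwd(d3$y)
  gvec <- gapFwd(mp2$y)
  dr <- dropoutFwd(gvec, cfg@dropoutRate, training)
  logits <- fcFwd(dr$y, p$fc$w, p$fc$b)

  out <- list(logits = logits)

  if (training) {
    out$state <- list(
      pre = pre$state,
      sfe = list(conv1 = s1$state, dw = s2$state, conv2 = s3$state),
      ltt1 = list(conv1 = l1a$state, dw = l1b$state, conv2 = l1c$state),
      ltt2 = list(conv1 = l2a$state, conv2 = l2b$state, conv3 = l2c$state,
                  conv4 = l2d$state, conv5 = l2e$state),
      dfem = list(conv1 = d1$state, dw = d2$state, conv2 = d3$state)
    )
  }

  if (keepStages) {
    out$stages <- list(
      Pre_layer = stem,
      Conv1_1 = s1$y, Dwconv1_2 = s2$y, SEB1_3 = sse$y, Conv1_4 = s3$y,
      SFEpath = sfeOut,
      Conv2_1 = l1a$y, Dwconv2_2 = l1b$y, Conv2_3 = ltt1Out,
      Conv3_1 = l2a$y, Conv3_2 = l2b$y, Conv3_3 = l2c$y, Conv3_4 = l2d$y,
      Conv3_5 = ltt2Out,
      Cross_Attention_LTT1 = attA, Cross_Attention_LTT2 = attB,
      Fuse = fused,
      Maxpool4_1 = mp1$y, Conv4_2 = d1$y, Dwconv4_3 = d2$y, SEB4_4 = dse$y,
      Conv4_5 = d3$y, Maxpool4_6 = mp2$y, GAP = gvec, Fc4_7 = logits
    )
    out$attention <- list(
      channelWeights = chGate$weights,
      spatialWeights = spGate$weights,
      sfeSeWeights = sse$weights,
      dfemSeWeights = dse$weights
    )
  }

  if (keepCache) {
    out$cache <- list(
      x = x, pre = pre$cache,
      s1 = s1$cache, s2 = s2$cache, sse = sse$cache, s3 = s3$cache,
      l1a = l1a$cache, l1b = l1b$cache, l1c = l1c$cache,
      l2a = l2a$cache, l2b = l2b$cache, l2c = l2c$cache, l2d = l2d$cache,
      l2e = l2e$cache,
      chGate = chGate$cache, spGate = spGate$cache,
      mp1 = mp1$cache, d1 = d1$cache, d2 = d2$cache, dse = dse$cache,
      d3 = d3$cache, mp2 = mp2$cache,
      mp2dim = dim(mp2$y), dropMask = dr$mask, fcIn = dr$y
    )
  }
  out
}

# Backward pass from a logits gradient. Returns parameter gradients
# (mirroring model@params) and, when `stageGrads` names stages, the
# gradients flowing into those stage outputs (used by Grad-CAM).
cambnetBackward <- function(model, cache, gLogits, stageGrads = character()) {
  cfg <- model@config
  p <- model@params
  cb <- cfg@branchOutChannels
  sg <- list()

  fc <- fcBwd(gLogits, cache$fcIn, p$fc$w)
  gG <- fc$gx
  if (!is.null(cache$dropMask)) gG <- gG * cache$dropMask
  gMp2 <- gapBwd(gG, cache$mp2dim)
  if ("Maxpool4_6" %in% stageGrads) sg$Maxpool4_6 <- gMp2
  gD3y <- maxpool2Bwd(gMp2, cache$mp2)
  if ("Conv4_5" %in% stageGrads) sg$Conv4_5 <- gD3y
  d3 <- cbrBwd(gD3y, cache$d3, p$dfem$conv2)
  dse <- seGateBwd(d3$gx, cache$dse, p$dfem$se)
  gD2y <- dse$gsrc + dse$gtgt
  if ("Dwconv4_3" %in% stageGrads) sg$Dwconv4_3 <- gD2y
  d2 <- cbrBwd(gD2y, cache$d2, p$dfem$dw)
  d1 <- cbrBwd(d2$gx, cache$d1, p$dfem$conv1)
  gFused <- maxpool2Bwd(d1$gx, cache$mp1)
  if ("Fuse" %in% stageGrads) sg$Fuse <- gFused

  gLttSum <- gFused[, , seq_len(cb), , drop = FALSE]
  gSfeOut <- gFused[, , cb + seq_len(cb), , drop = FALSE]
  gAttA <- gLttSum
  gAttB <- gLttSum

  if (cfg@attentionWiring == "ch1_sp2") {
    ch <- seGateBwd(gAttB, cache$chGate, p$ca$ch)   # src ltt1, tgt ltt2
    sp <- spatGateBwd(gAttA, cache$spGate, p$ca$sp) # src ltt2, tgt ltt1
    gLtt1 <- ch$gsrc + sp$gtgt
    gLtt2 <- ch$gtgt + sp$gsrc
  } else {
    ch <- seGateBwd(gAttA, cache$chGate, p$ca$ch)   # src ltt2, tgt ltt1
    sp <- spatGateBwd(gAttB, cache$spGate, p$ca$sp) # src ltt1, tgt ltt2
    gLtt1 <- ch$gtgt + sp$gsrc
    gLtt2 <- ch$gsrc + sp$gtgt
  }
  if ("Conv2_3" %in% stageGrads) sg$Conv2_3 <- gLtt1
  if ("Conv3_5" %in% stageGrads) sg$Conv3_5 <- gLtt2

  # LTTpath2
  l2e <- cbrBwd(gLtt2, cache$l2e, p$ltt2$conv5)
  l2d <- cbrBwd(l2e$gx, cache$l2d, p$ltt2$conv4)
  l2c <- cbrBwd(l2d$gx, cache$l2c, p$ltt2$conv3)
  l2b <- cbrBwd(l2c$gx, cache$l2b, p$ltt2$conv2)
  l2a <- cbrBwd(l2b$gx, cache$l2a, p$ltt2$conv1)

  # LTTpath1
  l1c <- cbrBwd(gLtt1, cache$l1c, p$ltt1$conv2)
  l1b <- cbrBwd(l1c$gx, cache$l1b, p$ltt1$dw)
  l1a <- cbrBwd(l1b$gx, cache$l1a, p$ltt1$conv1)

  # SFEpath (residual: gSfeOut reaches both the conv path and the stem)
  if ("SFEpath" %in% stageGrads) sg$SFEpath <- gSfeOut
  s3 <- cbrBwd(gSfeOut, cache$s3, p$sfe$conv2)
  sse <- seGateBwd(s3$gx, cache$sse, p$sfe$se)
  gS2y <- sse$gsrc + sse$gtgt
  s2 <- cbrBwd(gS2y, cache$s2, p$sfe$dw)
  s1 <- cbrBwd(s2$gx, cache$s1, p$sfe$conv1)

  gStem <- s1$gx + gSfeOut + l1a$gx + l2a$gx
  if ("Pre_layer" %in% stageGrads) sg$Pre_layer <- gStem
  pre <- cbrBwd(gStem, cache$pre, p$pre)

  cbrG <- function(b) list(w = b$grads$w,
                           gamma = b$grads$gamma, beta = b$grads$gbeta)
  grads <- list(
    pre = cbrG(pre),
    sfe = list(conv1 = cbrG(s1), dw = cbrG(s2), se = sse$grads,
               conv2 = cbrG(s3)),
    ltt1 = list(conv1 = cbrG(l1a), dw = cbrG(l1b), conv2 = cbrG(l1c)),
    ltt2 = list(conv1 = cbrG(l2a), conv2 = cbrG(l2b), conv3 = cbrG(l2c),
                conv4 = cbrG(l2d), conv5 = cbrG(l2e)),
    ca = list(ch = ch$grads, sp = sp$grads),
    dfem = list(conv1 = cbrG(d1), dw = cbrG(d2), se = dse$grads,
                conv2 = cbrG(d3)),
    fc = list(w = fc$gw, b = fc$gb)
  )
  list(grads = grads, stageGrads = sg, gInput = NULL)
}

#' Realized per-stage output shapes
#'
#' Runs one forward pass with stage hooks and returns the dimension vector
#' of every named stage, for eyeball or automated comparison against the
#' published per-stage dimension table.
#'
#' @param model a [CambnetModel-class].
#' @param batchSize batch size of the probe input.
#' @return named list of integer dimension vectors (`H, W, C, N`; the
#'   classifier stages are `features x N`).
#' @examples
#' m <- buildCambnet(seed = 1)
#' stageShapes(m)$Conv1_1   # 64 64 128 1
#' @export
stageShapes <- function(model, batchSize = 1L) {
  cfg <- model@config
  x <- array(0, dim = c(cfg@inputSide, cfg@inputSide, cfg@inChannels,
                        batchSize))
  fw <- cambnetForward(model, x, training = FALSE, keepStages = TRUE)
  lapply(fw$stages, function(s) if (is.null(dim(s))) length(s) else dim(s))
}

#' Print the realized shape table
#'
#' Console summary of each stage's output dimensions, in network order —
#' the `summary` surface for diffing against the published dimension table.
#'
#' @param object a [CambnetModel-class].
#' @param ... unused.
#' @return invisibly, the [stageShapes()] list.
#' @export
setMethod("summary", "CambnetModel", function(object, ...) {
  shapes <- stageShapes(object)
  cat(sprintf("%-22s %s\n", "Stage", "Output dims"))
  for (nm in names(shapes))
    cat(sprintf("%-22s %s\n", nm, paste(shapes[[nm]], collapse = " x ")))
  cat("Trainable parameters:", countParams(object), "\n")
  invisible(shapes)
})

#' Predict class probabilities and labels
#'
#' Runs the network in inference mode (running batch-norm statistics, no
#' dropout) over a patch array or [RoiPatchSet-class].
#'
#' @param object a [CambnetModel-class].
#' @param patches a `RoiPatchSet` or a `side x side x C x N` array.
#' @param batchSize evaluation batch size (default 1, the published eval
#'   batch size).
#' @param ... unused.
#' @return list with `probs` (N x nClasses matrix), `pred` (1-based class
#'   indices) and `logits` (N x nClasses).
#' @export
setMethod("predict", "CambnetModel", function(object, patches,
                                              batchSize = 1L, ...) {
  x <- if (is(patches, "RoiPatchSet")) patches@data else patches
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  K <- object@config@nClasses
  probs <- matrix(0, n, K)
  logits <- matrix(0, n, K)
  i <- 1L
  while (i <= n) {
    j <- min(i + batchSize - 1L, n)
    fw <- cambnetForward(object, x[, , , i:j, drop = FALSE])
    logits[i:j, ] <- t(fw$logits)
    probs[i:j, ] <- t(softmaxProbs(fw$logits))
    i <- j + 1L
  }
  list(probs = probs, pred = max.col(probs, ties.method = "first"),
       logits = logits)
})
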