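# Internal neural-network primitives. Every forward returns what its
# backward needs in a `cache` list; backwards return the input gradient plus
# parameter gradients. Feature maps are (H, W, C, N) arrays; the heavy
# lifting (convolutions, batch-norm, attention broadcasts) lives in the
# compiled kernels.

convOutDims <- function(xdim, wdim, stride, ph, pw) {
  c((xdim[1] + 2 * ph - wdim[1]) %/% stride + 1,
    (xdim[2] + 2 * pw - wdim[2]) %/% stride + 1,
    wdim[4], xdim[4])
}

isDepthwise <- function(xdim, wdim, groups) {
  groups == xdim[3] && wdim[3] == 1L && wdim[4] == xdim[3]
}

convFwd <- function(x, w, b, stride = 1L, ph = 0L, pw = 0L, groups = 1L) {
  xd <- dim(x); wd <- dim(w)
  if (isDepthwise(xd, wd, groups)) {
    cpp_dwconv_fwd(x, as.integer(xd), w, as.integer(wd), b,
                   as.integer(stride), as.integer(ph), as.integer(pw))
  } else {
    cpp_conv2d_fwd(x, as.integer(xd), w, as.integer(wd), b,
                   as.integer(stride), as.integer(ph), as.integer(pw),
                   as.integer(groups))
  }
}

convBwd <- function(x, w, gy, stride = 1L, ph = 0L, pw = 0L, groups = 1L) {
  xd <- dim(x); wd <- dim(w)
  out <- if (isDepthwise(xd, wd, groups)) {
    cpp_dwconv_bwd(x, as.integer(xd), w, as.integer(wd), gy,
                   as.integer(stride), as.integer(ph), as.integer(pw))
  } else {
    cpp_conv2d_bwd(x, as.integer(xd), w, as.integer(wd), gy,
                   as.integer(stride), as.integer(ph), as.integer(pw),
                   as.integer(groups))
  }
  out
}

# Conv -> BN -> ReLU composite used by every convolutional stage. Batch
# normalization uses batch statistics in training (updating the running
# values with momentum 0.1) and the running statistics in eval.
cbrFwd <- function(x, p, s, training, stride = 1L, ph = 0L, pw = 0L,
                   groups = 1L) {
  y1 <- convFwd(x, p$w, numeric(dim(p$w)[4]), stride, ph, pw, groups)
  d <- dim(y1)
  bn <- cpp_bn_relu_fwd(y1, as.integer(d), p$gamma, p$beta, s$mean, s$var,
                        1e-5, 0.1, training, TRUE)
  y <- bn$y
  list(y = y,
       cache = list(x = x, xhat = bn$xhat, invstd = bn$invstd,
                    training = training, y = y,
                    stride = stride, ph = ph, pw = pw, groups = groups),
       state = list(mean = bn$rmean, var = bn$rvar))
}

cbrBwd <- function(gy, cache, p) {
  d <- dim(cache$y)
  bn <- cpp_bn_relu_bwd(gy, cache$y, cache$xhat, as.integer(d), p$gamma,
                        cache$invstd, cache$training, TRUE)
  gc <- convBwd(cache$x, p$w, bn$gx, cache$stride, cache$ph, cache$pw,
                cache$groups)
  list(gx = gc$gx,
       grads = list(w = gc$gw, gamma = bn$ggamma, gbeta = bn$gbeta))
}

# Squeeze-and-excitation: global average pool -> bottleneck MLP -> sigmoid
# channel weights -> rescale. Gate source and gated tensor may differ
# (channel attention); classic SE passes the same tensor for both.
seGateFwd <- function(src, tgt, p) {
  d <- dim(tgt)
  z <- cpp_chan_mean_cn(src, as.integer(dim(src)))   # C x N
  h <- pmax(crossprod(p$w1, z) + p$b1, 0)            # Cb x N
  s <- sigmoid(crossprod(p$w2, h) + p$b2)            # C x N
  y <- cpp_scale_cn(tgt, as.integer(d), s)
  list(y = y, weights = s,
       cache = list(src = src, tgt = tgt, z = z, h = h, s = s))
}

seGateBwd <- function(gy, cache, p) {
  d <- dim(cache$tgt)
  s <- cache$s
  gtgt <- cpp_scale_cn(gy, as.integer(d), s)
  gs <- cpp_dot_cn(gy, cache$tgt, as.integer(d))     # C x N
  gpre2 <- gs * s * (1 - s)
  gw2 <- cache$h %*% t(gpre2)
  gb2 <- rowSums(gpre2)
  gh <- p$w2 %*% gpre2
  gpre1 <- gh * (cache$h > 0)
  gw1 <- cache$z %*% t(gpre1)
  gb1 <- rowSums(gpre1)
  gz <- p$w1 %*% gpre1
  ds <- dim(cache$src)
  gsrc <- cpp_bcast_cn(gz, as.integer(ds), ds[1] * ds[2])
  list(gsrc = gsrc, gtgt = gtgt,
       grads = list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2))
}

# Spatial attention: channel-mean map of `src` -> k x k conv (1 channel) ->
# sigmoid -> gate `tgt` at every spatial location.
spatGateFwd <- function(src, tgt, p) {
  d <- dim(src)
  k <- dim(p$w)[1]
  pad <- (k - 1L) %/% 2L
  m <- cpp_chan_collapse_mean(src, as.integer(d))    # HW x N
  marr <- array(m, dim = c(d[1], d[2], 1L, d[4]))
  a <- convFwd(marr, p$w, p$b, 1L, pad, pad, 1L)
  sArr <- sigmoid(a)                                 # H x W x 1 x N
  sMat <- matrix(sArr, d[1] * d[2], d[4])
  y <- cpp_scale_sp(tgt, as.integer(dim(tgt)), sMat)
  list(y = y, weights = sArr,
       cache = list(src = src, tgt = tgt, marr = marr, sArr = sArr,
                    sMat = sMat, pad = pad))
}

spatGateBwd <- function(gy, cache, p) {
  dt <- dim(cache$tgt)
  gtgt <- cpp_scale_sp(gy, as.integer(dt), cache$sMat)
  gsMat <- cpp_dot_sp(gy, cache$tgt, as.integer(dt)) # HW x N
  sArr <- cache$sArr
  ga <- array(gsMat, dim = dim(sArr)) * sArr * (1 - sArr)
  gc <- convBwd(cache$marr, p$w, ga, 1L, cache$pad, cache$pad, 1L)
  ds <- dim(cache$src)
  gm <- matrix(gc$gx, ds[1] * ds[2], ds[4])
  gsrc <- cpp_bcast_sp(gm, as.integer(ds), ds[3])
  list(gsrc = gsrc, gtgt = gtgt, grads = list(w = gc$gw, b = gc$gb))
}

maxpool2Fwd <- function(x) {
  d <- dim(x)
  out <- cpp_maxpool2_fwd(x, as.integer(d))
  y <- out$y
  dim(y) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  list(y = y, cache = list(idx = out$idx, xlen = length(x), xdim = d))
}

maxpool2Bwd <- function(gy, cache) {
  gx <- cpp_maxpool2_bwd(cache$idx, gy, cache$xlen)
  dim(gx) <- cache$xdim
  gx
}

gapFwd <- function(x) cpp_chan_mean_cn(x, as.integer(dim(x)))  # C x N

gapBwd <- function(gy, xdim) {
  cpp_bcast_cn(gy, as.integer(xdim), xdim[1] * xdim[2])
}

dropoutFwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  list(y = x * mask, mask = mask)
}

fcFwd <- function(x, w, b) crossprod(w, x) + b  # x: C x N -> K x N

fcBwd <- function(gy, x, w) {
  list(gx = w %*% gy, gw = x %*% t(gy), gb = rowSums(gy))
}

# Softmax cross-entropy on logits (K x N) against 1-based integer labels.
softmaxXent <- function(logits, labels) {
  N <- ncol(logits)
  p <- softmaxProbs(logits)
  idx <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, probs = p, gLogits = g / N)
}

softmaxProbs <- function(logits) {
  mx <- apply(logits, 2, max)
  z <- exp(sweep(logits, 2, mx))
  sweep(z, 2, colSums(z), "/")
}
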