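# Independent oracles used across the suite; deliberately written with
# plain loops, not via the package's own code paths.

# Brute-force pairwise AUC with midrank tie handling.
aucBruteForce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Counting oracle for the four confusion-based metrics.
metricsOracle <- function(labels, preds) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && preds[i] == 1) tp <- tp + 1
    if (labels[i] == 0 && preds[i] == 1) fp <- fp + 1
    if (labels[i] == 0 && preds[i] == 0) tn <- tn + 1
    if (labels[i] == 1 && preds[i] == 0) fn <- fn + 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(labels),
       precision = prec, recall = rec,
       f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

# Reference bilinear resize with half-pixel-center sampling, plain loops.
bilinearOracle <- function(m, outH, outW) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, outH, outW)
  for (i in seq_len(outH)) {
    for (j in seq_len(outW)) {
      sy <- min(max((i - 0.5) * H / outH - 0.5, 0), H - 1)
      sx <- min(max((j - 0.5) * W / outW - 0.5, 0), W - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
      fy <- sy - y0; fx <- sx - x0
      out[i, j] <- m[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
        m[y1 + 1, x0 + 1] * fy * (1 - fx) +
        m[y0 + 1, x1 + 1] * (1 - fy) * fx +
        m[y1 + 1, x1 + 1] * fy * fx
    }
  }
  out
}

# 4-connectivity check by breadth-first search (independent of the
# package's component labelling).
isFourConnected <- function(mask) {
  pos <- which(mask > 0)
  if (!length(pos)) return(FALSE)
  H <- nrow(mask)
  visited <- logical(length(mask))
  queue <- pos[1]
  visited[pos[1]] <- TRUE
  count <- 0
  while (length(queue)) {
    cur <- queue[length(queue)]
    queue <- queue[-length(queue)]
    count <- count + 1
    r <- (cur - 1) %% H + 1
    cidx <- (cur - 1) %/% H + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- cidx + d[2]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= ncol(mask)) {
        k <- (cc - 1) * H + rr
        if (mask[k] > 0 && !visited[k]) {
          visited[k] <- TRUE
          queue <- c(queue, k)
        }
      }
    }
  }
  count == sum(mask > 0)
}
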