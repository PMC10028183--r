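#' @include model.R
NULL

#' Construct a training configuration
#'
#' Defaults follow the published recipe; see [TrainConfig-class].
#'
#' @param batchSizeTrain,batchSizeEval batch sizes (8, 1).
#' @param maxEpochs epoch budget (200).
#' @param baseLr,lrDecayFactor,lrDecayIntervalEpochs learning-rate schedule
#'   (0.002, multiplied by 0.95 every 10 epochs).
#' @param optimizerName only `"rmsprop"`.
#' @param l2Weight L2 coefficient (1e-4).
#' @param kernelMaxnorm per-kernel norm bound (2.0).
#' @param rmspropAlpha,rmspropEps,rmspropMomentum RMSprop internals
#'   (0.99, 1e-8, 0).
#' @param seed training seed.
#' @param nFolds cross-validation folds (5).
#' @param testFraction held-out patient fraction (0.2).
#' @param valFraction validation fraction of the training patients (0.15).
#' @param augment random right-angle rotation / diagonal transpose
#'   augmentation during training.
#' @return a validated [TrainConfig-class].
#' @export
trainConfig <- function(batchSizeTrain = 8L, batchSizeEval = 1L,
                        maxEpochs = 200L,
                        baseLr = 0.002, lrDecayFactor = 0.95,
                        lrDecayIntervalEpochs = 10L,
                        optimizerName = "rmsprop",
                        l2Weight = 1e-4, kernelMaxnorm = 2.0,
                        rmspropAlpha = 0.99, rmspropEps = 1e-8,
                        rmspropMomentum = 0,
                        seed = 1L, nFolds = 5L,
                        testFraction = 0.2, valFraction = 0.15,
                        augment = FALSE) {
  new("TrainConfig",
      batchSizeTrain = as.integer(batchSizeTrain),
      batchSizeEval = as.integer(batchSizeEval),
      maxEpochs = as.integer(maxEpochs),
      baseLr = baseLr, lrDecayFactor = lrDecayFactor,
      lrDecayIntervalEpochs = as.integer(lrDecayIntervalEpochs),
      optimizerName = optimizerName,
      l2Weight = l2Weight, kernelMaxnorm = kernelMaxnorm,
      rmspropAlpha = rmspropAlpha, rmspropEps = rmspropEps,
      rmspropMomentum = rmspropMomentum,
      seed = as.integer(seed), nFolds = as.integer(nFolds),
      testFraction = testFraction, valFraction = valFraction,
      augment = augment)
}

# Allocate a per-class share of `total` draws proportionally, largest
# fractional remainder first, at least `minPer` per class.
stratumQuota <- function(classCounts, fraction, total) {
  exact <- classCounts * fraction
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(exact - base)
    take <- ord[seq_len(-rem)]
    base[take] <- base[take] - 1
  }
  pmin(pmax(base, 0), classCounts)
}

#' Patient-wise stratified train/validation/test split
#'
#' Holds out `round(testFraction * n)` patients as the test set, stratified
#' by class, then carves `valFraction` of the remaining training patients
#' (again stratified) as the validation set used for checkpoint selection.
#' All images of a patient travel together; the plan is deterministic in
#' the seed.
#'
#' @param metadata data.frame with columns `patient_id` and `label` (a
#'   [PhantomCohort-class] or [RoiPatchSet-class] is also accepted).
#' @param testFraction held-out fraction (default 0.2).
#' @param valFraction validation fraction of the training patients.
#' @param seed integer seed.
#' @param nFolds when > 0, also attach a [kfoldPlan()] over the non-test
#'   patients.
#' @return a [SplitPlan-class].
#' @examples
#' md <- data.frame(patient_id = sprintf("P%03d", 1:20),
#'                  label = rep(c("luminal", "non_luminal"), 10))
#' patientSplit(md, seed = 1)
#' @export
patientSplit <- function(metadata, testFraction = 0.2, valFraction = 0.15,
                         seed = 1L, nFolds = 0L) {
  if (is(metadata, "PhantomCohort")) metadata <- metadata@metadata
  if (is(metadata, "RoiPatchSet")) metadata <- metadata@metadata
  ids <- metadata$patient_id
  labels <- metadata$label
  if (anyDuplicated(ids)) stopNamed("cambnet_split_error",
                                    "duplicate patient ids")
  counts <- table(labels)
  if (length(counts) < 2)
    stopNamed("cambnet_split_error", "both classes must be present")
  if (any(counts < 2))
    stopNamed("cambnet_split_error",
              "every class needs at least 2 patients")
  withSeed(seed, {
    classes <- names(counts)
    nTest <- round(testFraction * length(ids))
    quota <- stratumQuota(as.numeric(counts), testFraction, nTest)
    testIds <- character()
    for (k in seq_along(classes)) {
      pool <- ids[labels == classes[k]]
      testIds <- c(testIds, sample(pool, quota[k]))
    }
    rest <- setdiff(ids, testIds)
    restLabels <- labels[match(rest, ids)]
    restCounts <- table(factor(restLabels, levels = classes))
    nVal <- round(valFraction * length(rest))
    vq <- stratumQuota(as.numeric(restCounts), valFraction, nVal)
    valIds <- character()
    for (k in seq_along(classes)) {
      pool <- rest[restLabels == classes[k]]
      valIds <- c(valIds, sample(pool, vq[k]))
    }
    trainIds <- setdiff(rest, valIds)
    folds <- if (nFolds > 0) {
      kfoldPlan(rest, setNames(restLabels, rest), nFolds,
                seed = sample.int(.Machine$integer.max, 1))
    } else integer()
    new("SplitPlan", trainIds = trainIds, valIds = valIds,
        testIds = testIds, foldAssignments = folds)
  })
}

#' Patient-level stratified k-fold plan
#'
#' Assigns each patient to exactly one fold such that fold sizes differ by
#' at most one and the class ratio of every fold is within one patient of
#' the global ratio.
#'
#' @param ids patient ids.
#' @param labels class labels, named by id or parallel to `ids`.
#' @param nFolds number of folds (must not exceed the number of patients).
#' @param seed integer seed.
#' @return named integer vector mapping patient id to fold index (1-based).
#' @export
kfoldPlan <- function(ids, labels, nFolds = 5L, seed = 1L) {
  nFolds <- as.integer(nFolds)
  if (nFolds > length(ids))
    stopNamed("cambnet_split_error", "nFolds exceeds number of patients")
  if (!is.null(names(labels))) labels <- labels[ids]
  withSeed(seed, {
    ordered <- character()
    for (cl in sort(unique(labels))) {
      pool <- ids[labels == cl]
      ordered <- c(ordered, sample(pool))
    }
    folds <- ((seq_along(ordered) - 1L) %% nFolds) + 1L
    setNames(folds, ordered)[ids]
  })
}

#' Learning rate at a given epoch
#'
#' Closed-form step decay: `baseLr * lrDecayFactor ^ floor(epoch /
#' lrDecayIntervalEpochs)` with 0-based epochs.
#'
#' @param epoch epoch index (0-based; vectorized).
#' @param config a [TrainConfig-class].
#' @return learning rate(s).
#' @examples
#' lrAt(0, trainConfig())   # 0.002
#' lrAt(25, trainConfig())  # 0.002 * 0.95^2
#' @export
lrAt <- function(epoch, config = trainConfig()) {
  config@baseLr * config@lrDecayFactor ^ (epoch %/% config@lrDecayIntervalEpochs)
}

#' Apply a right-angle rotation and/or diagonal transpose to a patch
#'
#' @param patch square array `H x H x C` (or matrix).
#' @param rotations number of 90-degree clockwise rotations (0-3).
#' @param transpose flip about the main diagonal.
#' @return the transformed patch, same shape and label semantics.
#' @export
applyDihedral <- function(patch, rotations = 0L, transpose = FALSE) {
  asMat <- is.matrix(patch)
  if (asMat) dim(patch) <- c(dim(patch), 1L)
  d <- dim(patch)
  if (d[1] != d[2])
    stopNamed("cambnet_augment_error", "patch must be square")
  rot1 <- function(m) t(m[nrow(m):1, , drop = FALSE]) # 90 degrees clockwise
  out <- patch
  for (ch in seq_len(d[3])) {
    m <- out[, , ch]
    r <- rotations %% 4L
    while (r > 0) { m <- rot1(m); r <- r - 1L }
    if (transpose) m <- t(m)
    out[, , ch] <- m
  }
  if (asMat) dim(out) <- d[1:2]
  out
}

#' Randomly augment a patch
#'
#' Draws a random multiple-of-90-degree rotation and/or a transpose about
#' the main diagonal, the augmentation family used during training.
#'
#' @param patch square array `H x H x C`.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (as inside the training loop).
#' @return the augmented patch.
#' @export
augmentPatch <- function(patch, seed = NULL) {
  draw <- function() applyDihedral(patch, sample(0:3, 1),
                                   sample(c(TRUE, FALSE), 1))
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

isKernelLeaf <- function(name) name %in% c("w", "w1", "w2")

# One RMSprop step over the nested parameter list; applies L2 to kernel
# weights before the update and the per-kernel max-norm clamp after it.
optimStep <- function(params, grads, vstate, mstate, lr, config) {
  step <- function(p, g, v, m, name) {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- step(p[[nm]], g[[nm]], v[[nm]], m[[nm]], nm)
        p[[nm]] <- r$p; v[[nm]] <- r$v; m[[nm]] <- r$m
      }
      return(list(p = p, v = v, m = m))
    }
    isKernel <- isKernelLeaf(name)
    if (isKernel && config@l2Weight > 0) g <- g + config@l2Weight * p
    v <- config@rmspropAlpha * v + (1 - config@rmspropAlpha) * g * g
    upd <- g / (sqrt(v) + config@rmspropEps)
    if (config@rmspropMomentum > 0) {
      m <- config@rmspropMomentum * m + upd
      upd <- m
    }
    p <- p - lr * upd
    if (isKernel && is.finite(config@kernelMaxnorm) &&
        config@kernelMaxnorm > 0) {
      d <- dim(p)
      if (!is.null(d)) {
        pm <- matrix(p, prod(d[-length(d)]), d[length(d)])
        nrm <- sqrt(colSums(pm * pm))
        sc <- pmin(1, config@kernelMaxnorm / pmax(nrm, 1e-12))
        pm <- sweep(pm, 2, sc, "*")
        p <- array(pm, dim = d)
      }
    }
    list(p = p, v = v, m = m)
  }
  step(params, grads, vstate, mstate, "")
}

zeroLike <- function(p) {
  if (is.list(p)) lapply(p, zeroLike) else p * 0
}

labelIndices <- function(labels, classLevels = NULL) {
  if (is.null(classLevels)) classLevels <- sort(unique(labels))
  idx <- match(labels, classLevels)
  if (anyNA(idx)) stopNamed("cambnet_label_error", "unknown class label")
  list(idx = idx, levels = classLevels)
}

#' Train CAMBNET on a patch set
#'
#' End-to-end training with cross-entropy loss, RMSprop, the step-decay
#' learning-rate schedule, L2 regularization, a per-kernel max-norm clamp
#' after each step, and best-on-validation checkpointing. A leakage guard
#' asserts that the training and test patient sets are disjoint before any
#' optimization happens.
#'
#' @param model a freshly built [CambnetModel-class].
#' @param patches a [RoiPatchSet-class].
#' @param plan a [SplitPlan-class] over the patch set's patients.
#' @param config a [TrainConfig-class].
#' @param labelColumn metadata column holding the class labels.
#' @return list with `model` (the best-on-validation checkpoint), `history`
#'   (data.frame: `epoch` 0-based, `lr`, `train_loss`, `val_acc`),
#'   `bestEpoch`, and `classLevels` (label order of the logit units).
#' @export
trainCambnet <- function(model, patches, plan, config = trainConfig(),
                         labelColumn = "label") {
  meta <- patches@metadata
  if (length(intersect(plan@trainIds, plan@testIds)) ||
      length(intersect(plan@valIds, plan@testIds)))
    stopNamed("cambnet_leakage_error",
              "train/val and test patient sets overlap")
  trainIdx <- which(meta$patient_id %in% plan@trainIds)
  valIdx <- which(meta$patient_id %in% plan@valIds)
  if (!length(trainIdx))
    stopNamed("cambnet_split_error", "empty training set")
  if (!length(valIdx))
    stopNamed("cambnet_split_error", "empty validation set")
  lab <- labelIndices(meta[[labelColumn]])
  yAll <- lab$idx
  x <- patches@data
  B <- config@batchSizeTrain

  withSeed(config@seed, {
    vstate <- zeroLike(model@params)
    mstate <- zeroLike(model@params)
    history <- data.frame(epoch = integer(), lr = numeric(),
                          train_loss = numeric(), val_acc = numeric())
    bestAcc <- -Inf
    bestModel <- model
    bestEpoch <- -1L
    for (epoch in seq_len(config@maxEpochs) - 1L) {
      lr <- lrAt(epoch, config)
      ord <- sample(trainIdx)
      losses <- numeric()
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + B - 1L, length(ord))
        sel <- ord[i:j]
        xb <- x[, , , sel, drop = FALSE]
        if (config@augment) {
          for (k in seq_along(sel))
            xb[, , , k] <- augmentPatch(xb[, , , k, drop = TRUE])
        }
        yb <- yAll[sel]
        fw <- cambnetForward(model, xb, training = TRUE, keepCache = TRUE)
        model@state <- fw$state
        sm <- softmaxXent(fw$logits, yb)
        losses <- c(losses, sm$loss)
        bw <- cambnetBackward(model, fw$cache, sm$gLogits)
        upd <- optimStep(model@params, bw$grads, vstate, mstate, lr, config)
        model@params <- upd$p
        vstate <- upd$v
        mstate <- upd$m
        i <- j + 1L
      }
      pv <- predict(model, x[, , , valIdx, drop = FALSE],
                    batchSize = config@batchSizeEval)
      valAcc <- mean(pv$pred == yAll[valIdx])
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, train_loss = mean(losses), val_acc = valAcc))
      if (valAcc > bestAcc) {
        bestAcc <- valAcc
        bestModel <- model
        bestEpoch <- epoch
      }
    }
    list(model = bestModel, history = history, bestEpoch = bestEpoch,
         classLevels = lab$levels)
  })
}
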