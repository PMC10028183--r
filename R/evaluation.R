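#' @include model.R
NULL

#' Confusion-matrix counts
#'
#' @param labels binary vector (0/1 or logical), 1 = positive.
#' @param predictions binary vector of the same length.
#' @return a [ConfusionCounts-class].
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))  # TP 1 FN 1 TN 1 FP 1
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stopNamed("cambnet_metric_error",
              "labels and predictions must have equal length")
  l <- as.integer(labels)
  p <- as.integer(predictions)
  if (!all(l %in% 0:1) || !all(p %in% 0:1))
    stopNamed("cambnet_metric_error", "entries must be binary (0/1)")
  new("ConfusionCounts",
      tp = sum(l == 1L & p == 1L), fp = sum(l == 0L & p == 1L),
      tn = sum(l == 0L & p == 0L), fn = sum(l == 1L & p == 0L))
}

safeRatio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); reporting 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); Precision = TP/(TP+FP);
#' Recall = TP/(TP+FN); F1 = 2*Precision*Recall/(Precision+Recall).
#' When a denominator is zero the metric is reported as 0 with a warning.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
computeMetrics <- function(counts) {
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  total <- tp + fp + tn + fn
  if (total == 0)
    stopNamed("cambnet_metric_error", "no samples to evaluate")
  precision <- safeRatio(tp, tp + fp, "precision")
  recall <- safeRatio(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("f1 undefined (zero denominator); reporting 0", call. = FALSE)
    0
  } else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

#' ROC AUC via the rank (Mann-Whitney) statistic
#'
#' Area under the ROC curve computed with the midrank convention, so the
#' value equals the Mann-Whitney U statistic normalized by `n1 * n0`
#' (ties between a positive and a negative score contribute 1/2).
#'
#' @param scores real-valued scores, larger = more positive.
#' @param labels binary vector (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, labels) {
  l <- as.integer(labels)
  if (length(scores) != length(l))
    stopNamed("cambnet_metric_error", "scores/labels length mismatch")
  n1 <- sum(l == 1L)
  n0 <- sum(l == 0L)
  if (n1 == 0 || n0 == 0)
    stopNamed("cambnet_metric_error", "both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[l == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Threshold sweep over the unique score values; returns the (FPR, TPR)
#' staircase used for plotting.
#'
#' @inheritParams rocAuc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
rocCurve <- function(scores, labels) {
  l <- as.integer(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(l == 1L); n0 <- sum(l == 0L)
  tpr <- vapply(th, function(t) sum(scores >= t & l == 1L) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & l == 0L) / n0, numeric(1))
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

buildReport <- function(labels01, pred01, scores, averaging = "macro") {
  counts <- confusionCounts(labels01, pred01)
  pos <- computeMetrics(counts)
  negCounts <- confusionCounts(1 - labels01, 1 - pred01)
  neg <- computeMetrics(negCounts)
  perClass <- data.frame(
    class = c("positive", "negative"),
    precision = c(pos$precision, neg$precision),
    recall = c(pos$recall, neg$recall),
    f1 = c(pos$f1, neg$f1)
  )
  auc <- rocAuc(scores, labels01)
  aucNeg <- rocAuc(-scores, 1 - labels01)
  if (averaging == "macro") {
    precision <- mean(perClass$precision)
    recall <- mean(perClass$recall)
    f1 <- mean(perClass$f1)
  } else {
    precision <- pos$precision
    recall <- pos$recall
    f1 <- pos$f1
  }
  new("MetricsReport",
      accuracy = pos$accuracy, precision = precision, recall = recall,
      f1 = f1, auc = auc, aucMacro = mean(c(auc, aucNeg)),
      averagingMode = averaging, perClass = perClass, counts = counts,
      n = length(labels01))
}

#' Evaluate a trained model on a patch set
#'
#' Softmax scores, argmax predictions, confusion counts and the four
#' headline metrics plus AUC from the positive-class probability. With
#' `averaging = "macro"` (default) precision/recall/F1 are macro averages
#' over the two classes; `"per-class"` reports the positive class.
#'
#' @param model a [CambnetModel-class].
#' @param patches a [RoiPatchSet-class].
#' @param positiveClass label treated as positive (default
#'   `"non_luminal"`).
#' @param averaging `"macro"` or `"per-class"`.
#' @param labelColumn metadata column with the ground-truth labels.
#' @param classLevels label order of the model's logit units (defaults to
#'   the sorted unique labels, the order [trainCambnet()] uses).
#' @param batchSize evaluation batch size.
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, patches, positiveClass = "non_luminal",
                          averaging = "macro", labelColumn = "label",
                          classLevels = NULL, batchSize = 1L) {
  meta <- patches@metadata
  if (!nrow(meta)) stopNamed("cambnet_metric_error", "empty evaluation set")
  labels <- meta[[labelColumn]]
  lab <- labelIndices(labels, classLevels)
  posIdx <- match(positiveClass, lab$levels)
  if (is.na(posIdx))
    stopNamed("cambnet_label_error", "positiveClass not among class labels")
  pv <- predict(model, patches, batchSize = batchSize)
  labels01 <- as.integer(lab$idx == posIdx)
  pred01 <- as.integer(pv$pred == posIdx)
  scores <- pv$probs[, posIdx]
  buildReport(labels01, pred01, scores, averaging)
}

#' Relabel four-way subtype labels under a binary scheme
#'
#' Schemes follow the subgroup analyses: `"luminal_vs_nonluminal"` maps
#' HER2 and TN to positive; `"TN_vs_rest"` maps triple-negative to
#' positive and luminalA/luminalB/HER2 to negative; `"luminalA_vs_rest"`
#' maps luminalA to positive.
#'
#' @param label4 character vector of `"luminalA"`, `"luminalB"`, `"HER2"`,
#'   `"TN"`.
#' @param scheme one of the three scheme names.
#' @return integer vector, 1 = positive.
#' @export
relabelScheme <- function(label4,
                          scheme = c("luminal_vs_nonluminal", "TN_vs_rest",
                                     "luminalA_vs_rest")) {
  scheme <- match.arg(scheme)
  if (!all(label4 %in% SUBTYPES4))
    stopNamed("cambnet_label_error", "unknown four-way label")
  pos <- switch(scheme,
                luminal_vs_nonluminal = c("HER2", "TN"),
                TN_vs_rest = "TN",
                luminalA_vs_rest = "luminalA")
  as.integer(label4 %in% pos)
}

#' Subset a patch set by index
#'
#' @param patches a [RoiPatchSet-class].
#' @param keep integer or logical index over patches.
#' @return the subset [RoiPatchSet-class].
#' @export
subsetPatchSet <- function(patches, keep) {
  new("RoiPatchSet",
      data = patches@data[, , , keep, drop = FALSE],
      metadata = patches@metadata[keep, , drop = FALSE],
      normMean = patches@normMean, normSd = patches@normSd)
}

#' Stratified subgroup evaluation
#'
#' Splits the evaluation set at a covariate threshold (age at menarche
#' 14 years, or tumor size 20 mm), relabels the ground truth under a binary
#' label scheme, and evaluates each stratum. The two strata (`<=` threshold
#' versus `>`) partition the cohort; an empty stratum is reported as
#' missing (NA metrics) rather than silently dropped.
#'
#' The model's positive-class score (probability of the non-luminal logit)
#' is used as the ranking score under every scheme; predictions are scored
#' against the scheme's relabeled ground truth.
#'
#' @param model a [CambnetModel-class].
#' @param patches a [RoiPatchSet-class] whose metadata has `label4`,
#'   `menarche_age` and `tumor_size_mm` columns.
#' @param covariate `"menarche_age"` or `"tumor_size"`.
#' @param threshold stratification threshold (defaults: 14 years, 20 mm).
#' @param scheme a [relabelScheme()] scheme name.
#' @param averaging,classLevels,batchSize passed to the underlying
#'   evaluation.
#' @return data.frame with one row per stratum (`stratum`, `n`, `accuracy`,
#'   `precision`, `recall`, `f1`, `auc`).
#' @export
subgroupEval <- function(model, patches, covariate = c("menarche_age",
                                                       "tumor_size"),
                         threshold = NULL,
                         scheme = "luminal_vs_nonluminal",
                         averaging = "macro", classLevels = NULL,
                         batchSize = 1L) {
  covariate <- match.arg(covariate)
  if (is.null(threshold))
    threshold <- if (covariate == "menarche_age") 14 else 20
  meta <- patches@metadata
  values <- if (covariate == "menarche_age") meta$menarche_age
            else meta$tumor_size_mm
  labels <- meta$label
  lab <- labelIndices(labels, classLevels)
  posIdx <- match("non_luminal", lab$levels)
  pv <- predict(model, patches, batchSize = batchSize)
  scores <- pv$probs[, posIdx]
  predPos <- as.integer(pv$pred == posIdx)
  truth <- relabelScheme(meta$label4, scheme)
  # under the training scheme the model's positive prediction is the
  # scheme's positive; for other schemes threshold the score at 0.5
  predScheme <- if (scheme == "luminal_vs_nonluminal") predPos
                else as.integer(scores > 0.5)

  strata <- list(small = values <= threshold, large = values > threshold)
  rows <- lapply(names(strata), function(nm) {
    keep <- strata[[nm]]
    if (!any(keep)) {
      return(data.frame(stratum = nm, n = 0L, accuracy = NA_real_,
                        precision = NA_real_, recall = NA_real_,
                        f1 = NA_real_, auc = NA_real_))
    }
    l <- truth[keep]; p <- predScheme[keep]; s <- scores[keep]
    auc <- if (length(unique(l)) < 2) NA_real_ else rocAuc(s, l)
    rep <- suppressWarnings(buildReportSafe(l, p, s, averaging, auc))
    data.frame(stratum = nm, n = sum(keep), accuracy = rep$accuracy,
               precision = rep$precision, recall = rep$recall,
               f1 = rep$f1, auc = rep$auc)
  })
  out <- do.call(rbind, rows)
  out$covariate <- covariate
  out$threshold <- threshold
  out$scheme <- scheme
  out
}

# Report assembly tolerant of single-class strata (AUC supplied by caller).
buildReportSafe <- function(labels01, pred01, scores, averaging, auc) {
  counts <- confusionCounts(labels01, pred01)
  pos <- computeMetrics(counts)
  neg <- computeMetrics(confusionCounts(1 - labels01, 1 - pred01))
  if (averaging == "macro") {
    list(accuracy = pos$accuracy,
         precision = mean(c(pos$precision, neg$precision)),
         recall = mean(c(pos$recall, neg$recall)),
         f1 = mean(c(pos$f1, neg$f1)), auc = auc)
  } else {
    list(accuracy = pos$accuracy, precision = pos$precision,
         recall = pos$recall, f1 = pos$f1, auc = auc)
  }
}
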