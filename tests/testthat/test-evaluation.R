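test_that("confusion counts follow the four definitions", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(c(cc@tp, cc@fn, cc@tn, cc@fp), c(1L, 1L, 1L, 1L))
  perfect <- confusionCounts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(perfect@fp, perfect@fn), c(0L, 0L))
  inverted <- confusionCounts(c(1, 0, 1), c(0, 1, 0))
  expect_equal(c(inverted@tp, inverted@tn), c(0L, 0L))
  expect_error(confusionCounts(c(1, 0), c(1, 0, 1)),
               class = "cambnet_metric_error")
})

test_that("metrics match the direct formulas and the degenerate policy", {
  m <- computeMetrics(new("ConfusionCounts", tp = 3L, fp = 1L, tn = 4L,
                          fn = 2L))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  ones <- computeMetrics(new("ConfusionCounts", tp = 1L, fp = 0L, tn = 1L,
                             fn = 0L))
  expect_true(all(unlist(ones) == 1))
  w <- capture_warnings(
    z <- computeMetrics(new("ConfusionCounts", tp = 0L, fp = 0L, tn = 3L,
                            fn = 1L)))
  expect_true(any(grepl("precision", w)))
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
})

test_that("metrics agree with a counting oracle on random confusion tables", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    labels <- rbinom(n, 1, 0.5)
    preds <- rbinom(n, 1, 0.5)
    cc <- confusionCounts(labels, preds)
    got <- suppressWarnings(computeMetrics(cc))
    want <- metricsOracle(labels, preds)
    expect_equal(c(cc@tp, cc@fp, cc@tn, cc@fn),
                 c(want$tp, want$fp, want$tn, want$fn))
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f1, want$f1)
  }
})

test_that("AUC equals the pairwise Mann-Whitney statistic, ties at 1/2", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  s <- c(0.1, 0.4, 0.4, 0.6, 0.6, 0.6, 0.8, 0.9)
  l <- c(0, 0, 1, 0, 1, 1, 0, 1)
  expect_equal(rocAuc(s, l), aucBruteForce(s, l))
  expect_error(rocAuc(c(1, 2), c(1, 1)), class = "cambnet_metric_error")
})

test_that("AUC is invariant under monotone transforms and matches pROC", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1) # rounding forces ties
    a <- rocAuc(s, l)
    expect_equal(a, aucBruteForce(s, l))
    expect_equal(rocAuc(exp(2 * s), l), a)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(a, ref)
    }
  }
})

test_that("a constant-prediction model scores the majority fraction", {
  co <- smallCohort()
  ps <- preprocessCohort(co)
  m <- buildCambnet(seed = 31)
  m@params$fc$w[] <- 0
  m@params$fc$b <- c(5, 0) # always predicts class 1 (luminal)
  rep <- suppressWarnings(evaluateModel(m, ps, averaging = "per-class"))
  md <- patchMetadata(ps)
  expect_equal(rep@accuracy, mean(md$label == "luminal"))
  expect_equal(rep@counts@tp, 0L) # never predicts the positive class
})

test_that("the report assembles per-class and macro values consistently", {
  set.seed(9)
  labels01 <- c(rep(1, 8), rep(0, 12))
  scores <- runif(20)
  pred01 <- as.integer(scores > 0.5)
  rep <- suppressWarnings(
    cambnet:::buildReport(labels01, pred01, scores, "macro"))
  want <- metricsOracle(labels01, pred01)
  wantNeg <- metricsOracle(1 - labels01, 1 - pred01)
  expect_equal(rep@accuracy, want$accuracy)
  expect_equal(rep@precision, mean(c(want$precision, wantNeg$precision)))
  expect_equal(rep@recall, mean(c(want$recall, wantNeg$recall)))
  expect_equal(rep@f1, mean(c(want$f1, wantNeg$f1)))
  expect_equal(rep@auc, aucBruteForce(scores, labels01))
  expect_equal(rep@perClass$precision[1], want$precision)
  perClass <- suppressWarnings(
    cambnet:::buildReport(labels01, pred01, scores, "per-class"))
  expect_equal(perClass@precision, want$precision)
})

test_that("label schemes map four-way subtypes as in the subgroup tables", {
  l4 <- c("luminalA", "luminalB", "HER2", "TN")
  expect_equal(relabelScheme(l4, "luminal_vs_nonluminal"), c(0L, 0L, 1L, 1L))
  expect_equal(relabelScheme(l4, "TN_vs_rest"), c(0L, 0L, 0L, 1L))
  expect_equal(relabelScheme(l4, "luminalA_vs_rest"), c(1L, 0L, 0L, 0L))
  expect_error(relabelScheme("basal", "TN_vs_rest"),
               class = "cambnet_label_error")
})

test_that("subgroup evaluation equals a filter-then-evaluate oracle", {
  co <- smallCohort()
  ps <- preprocessCohort(co)
  m <- buildCambnet(seed = 32)
  tab <- suppressWarnings(
    subgroupEval(m, ps, covariate = "menarche_age", threshold = 14))
  md <- patchMetadata(ps)
  expect_equal(sum(tab$n), nrow(md)) # strata partition the cohort
  pv <- predict(m, ps)
  lab <- cambnet:::labelIndices(md$label)
  posIdx <- match("non_luminal", lab$levels)
  for (stratum in c("small", "large")) {
    keep <- if (stratum == "small") md$menarche_age <= 14
            else md$menarche_age > 14
    if (!any(keep)) next
    truth <- relabelScheme(md$label4[keep], "luminal_vs_nonluminal")
    predPos <- as.integer(pv$pred[keep] == posIdx)
    want <- metricsOracle(truth, predPos)
    row <- tab[tab$stratum == stratum, ]
    expect_equal(row$n, sum(keep))
    expect_equal(row$accuracy, want$accuracy)
    if (length(unique(truth)) == 2)
      expect_equal(row$auc, aucBruteForce(pv$probs[keep, posIdx], truth))
  }
})
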