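mkMeta <- function(n, labels) {
  data.frame(patient_id = sprintf("P%03d", seq_len(n)), label = labels,
             stringsAsFactors = FALSE)
}

test_that("patient split holds out the configured fraction, stratified", {
  md <- mkMeta(160, rep(c("luminal", "non_luminal"), times = c(84, 76)))
  plan <- patientSplit(md, testFraction = 0.2, seed = 1)
  expect_length(plan@testIds, 32)
  all3 <- c(plan@trainIds, plan@valIds, plan@testIds)
  expect_setequal(all3, md$patient_id)
  expect_equal(anyDuplicated(all3), 0L)
  # stratification: test-set class counts within 1 of the proportional share
  lab <- md$label[match(plan@testIds, md$patient_id)]
  expect_lte(abs(sum(lab == "luminal") - 0.2 * 84), 1)
  expect_identical(plan, patientSplit(md, testFraction = 0.2, seed = 1))
  expect_false(identical(plan@testIds,
                         patientSplit(md, seed = 2)@testIds))
  expect_error(patientSplit(mkMeta(3, c("a", "a", "b"))),
               class = "cambnet_split_error")
})

test_that("k-fold plans are balanced, stratified patient partitions", {
  md <- mkMeta(10, rep(c("luminal", "non_luminal"), 5))
  f <- kfoldPlan(md$patient_id, setNames(md$label, md$patient_id), 5,
                 seed = 3)
  expect_equal(as.vector(table(f)), rep(2L, 5))
  expect_setequal(names(f), md$patient_id)
  md2 <- mkMeta(20, rep(c("luminal", "non_luminal"), times = c(12, 8)))
  f2 <- kfoldPlan(md2$patient_id, setNames(md2$label, md2$patient_id), 5,
                  seed = 4)
  for (k in 1:5) {
    ids <- names(f2)[f2 == k]
    nl <- sum(md2$label[match(ids, md2$patient_id)] == "luminal")
    expect_lte(abs(nl - 12 / 5), 1)
  }
  expect_error(kfoldPlan(md$patient_id[1:3], md$label[1:3], 5),
               class = "cambnet_split_error")
})

test_that("learning rate follows the closed-form step decay", {
  cfg <- trainConfig()
  expect_equal(lrAt(0, cfg), 0.002)
  expect_equal(lrAt(9, cfg), 0.002)
  expect_equal(lrAt(10, cfg), 0.002 * 0.95)
  expect_equal(lrAt(25, cfg), 0.002 * 0.95^2)
})

test_that("augmentation is the dihedral family and preserves shape", {
  p <- array(rnorm(64 * 64 * 3), dim = c(64, 64, 3))
  expect_identical(applyDihedral(p, 0, FALSE), p)
  expect_identical(applyDihedral(applyDihedral(p, 0, TRUE), 0, TRUE), p)
  r <- p
  for (k in 1:4) r <- applyDihedral(r, 1)
  expect_identical(r, p)
  expect_equal(applyDihedral(p, 2), applyDihedral(applyDihedral(p, 1), 1))
  a <- augmentPatch(p, seed = 5)
  expect_equal(dim(a), dim(p))
  expect_identical(augmentPatch(p, seed = 5), a)
  expect_error(applyDihedral(array(0, dim = c(4, 6, 1))),
               class = "cambnet_augment_error")
})

test_that("the training loop checkpoints on validation and logs the schedule", {
  co <- smallCohort()
  ps <- preprocessCohort(co)
  plan <- patientSplit(patchMetadata(ps), seed = 21)
  cfg <- trainConfig(maxEpochs = 3L, seed = 21,
                     lrDecayIntervalEpochs = 2L)
  fit <- trainCambnet(buildCambnet(seed = 21), ps, plan, cfg)
  h <- fit$history
  expect_equal(nrow(h), 3)
  expect_equal(h$lr, lrAt(h$epoch, cfg))
  expect_equal(max(h$val_acc), h$val_acc[fit$bestEpoch + 1])
  # restored checkpoint reproduces the best validation accuracy
  valIdx <- which(patchMetadata(ps)$patient_id %in% plan@valIds)
  pv <- predict(fit$model, patchArray(ps)[, , , valIdx, drop = FALSE])
  lab <- cambnet:::labelIndices(patchMetadata(ps)$label)
  expect_equal(mean(pv$pred == lab$idx[valIdx]), max(h$val_acc))
})

test_that("training is reproducible and guards against patient leakage", {
  co <- smallCohort()
  ps <- preprocessCohort(co)
  plan <- patientSplit(patchMetadata(ps), seed = 22)
  cfg <- trainConfig(maxEpochs = 2L, seed = 22)
  f1 <- trainCambnet(buildCambnet(seed = 22), ps, plan, cfg)
  f2 <- trainCambnet(buildCambnet(seed = 22), ps, plan, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@params, f2$model@params)

  bad <- plan
  bad@trainIds <- c(bad@trainIds, bad@testIds[1])
  expect_error(trainCambnet(buildCambnet(seed = 1), ps, bad, cfg),
               class = "cambnet_leakage_error")
})

test_that("one optimizer step at the base learning rate reduces batch loss", {
  co <- smallCohort()
  ps <- preprocessCohort(co)
  lab <- cambnet:::labelIndices(patchMetadata(ps)$label)
  x <- patchArray(ps)[, , , 1:8, drop = FALSE]
  y <- lab$idx[1:8]
  m <- buildCambnet(cambnetConfig(dropoutRate = 0), seed = 23)
  cfg <- trainConfig(seed = 23)
  fw <- cambnetForward(m, x, training = TRUE, keepCache = TRUE)
  sm <- cambnet:::softmaxXent(fw$logits, y)
  bw <- cambnet:::cambnetBackward(m, fw$cache, sm$gLogits)
  upd <- cambnet:::optimStep(m@params, bw$grads,
                             cambnet:::zeroLike(m@params),
                             cambnet:::zeroLike(m@params), 0.002, cfg)
  m2 <- m
  m2@params <- upd$p
  m2@state <- fw$state
  fw2 <- cambnetForward(m2, x, training = TRUE)
  sm2 <- cambnet:::softmaxXent(fw2$logits, y)
  expect_lt(sm2$loss, sm$loss)
})

test_that("the max-norm constraint bounds every kernel after a step", {
  co <- smallCohort()
  ps <- preprocessCohort(co)
  plan <- patientSplit(patchMetadata(ps), seed = 24)
  cfg <- trainConfig(maxEpochs = 1L, seed = 24, kernelMaxnorm = 0.5)
  fit <- trainCambnet(buildCambnet(seed = 24), ps, plan, cfg)
  walk <- function(p, name) {
    if (is.list(p)) {
      for (nm in names(p)) walk(p[[nm]], nm)
    } else if (name %in% c("w", "w1", "w2")) {
      d <- dim(p)
      pm <- matrix(p, prod(d[-length(d)]), d[length(d)])
      expect_lte(max(sqrt(colSums(pm^2))), 0.5 + 1e-8)
    }
  }
  walk(fit$model@params, "")
})
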