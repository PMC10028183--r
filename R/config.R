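#' @include training.R evaluation.R explain.R io.R preprocess.R
NULL

runConfigDefaults <- function() {
  list(
    seed = 1L,
    phantom = list(
      image_side = 256L, n_channels = 3L,
      lesion_radius_min = 12, lesion_radius_max = 36,
      spiculation_amplitude = 0.35, ring_contrast = 0.35,
      background_noise_scale = 0.12, pixel_spacing = 0.5
    ),
    cohort = list(n_cases = 160L, class_balance = 84 / 160),
    preprocess = list(margin = 10L, size = 64L, norm_mean = 0.5,
                      norm_sd = 0.5),
    model = list(
      n_classes = 2L, se_reduction_ratio = 16L, dropout_rate = 0.5,
      attention_kernel_size = 7L, attention_wiring = "ch1_sp2"
    ),
    train = list(
      batch_size_train = 8L, batch_size_eval = 1L, max_epochs = 200L,
      base_lr = 0.002, lr_decay_factor = 0.95,
      lr_decay_interval_epochs = 10L, optimizer = "rmsprop",
      l2_weight = 1e-4, kernel_maxnorm = 2.0, n_folds = 5L,
      test_fraction = 0.2, val_fraction = 0.15, augment = FALSE
    ),
    strata = list(
      list(covariate = "menarche_age", threshold = 14,
           scheme = "luminal_vs_nonluminal"),
      list(covariate = "menarche_age", threshold = 14,
           scheme = "luminalA_vs_rest"),
      list(covariate = "tumor_size", threshold = 20,
           scheme = "luminal_vs_nonluminal"),
      list(covariate = "tumor_size", threshold = 20,
           scheme = "TN_vs_rest")
    ),
    output = list(dir = "cambnet_run", n_explain = 8L)
  )
}

checkRange <- function(value, lo, hi, path, openLo = FALSE, openHi = FALSE) {
  bad <- (openLo && value <= lo) || (!openLo && value < lo) ||
    (openHi && value >= hi) || (!openHi && value > hi)
  if (bad)
    stopNamed("cambnet_config_error", sprintf(
      "%s: value %s outside allowed range %s%s, %s%s", path,
      format(value), if (openLo) "(" else "[", format(lo), format(hi),
      if (openHi) ")" else "]"))
  value
}

mergeConfig <- function(defaults, raw, path = "") {
  if (is.null(raw)) return(defaults)
  if (!is.list(raw))
    stopNamed("cambnet_config_error",
              paste0(path, ": expected a mapping"))
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stopNamed("cambnet_config_error", paste0(
      "unknown config key(s): ",
      paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", ")))
  out <- defaults
  for (nm in names(raw)) {
    if (nm == "strata") { out$strata <- raw$strata; next }
    if (is.list(defaults[[nm]])) {
      out[[nm]] <- mergeConfig(defaults[[nm]], raw[[nm]],
                               paste0(sub("^\\.", "", paste0(path, ".", nm))))
    } else {
      val <- raw[[nm]]
      if (!is.null(defaults[[nm]]) && is.numeric(defaults[[nm]]) &&
          !is.numeric(val))
        stopNamed("cambnet_config_error", sprintf(
          "%s: expected a number, got '%s'",
          sub("^\\.", "", paste0(path, ".", nm)), format(val)))
      out[[nm]] <- val
    }
  }
  out
}

#' Validate and materialize a run configuration
#'
#' Accepts a YAML file path, YAML text, or a nested list; fills every
#' missing key with the pipeline defaults (10-px margin, 64 x 64 patches,
#' batch sizes 8/1, learning rate 0.002 decayed by 0.95 every 10 epochs,
#' 200 epochs, 5 folds, stratification thresholds 14 years / 20 mm),
#' rejects unknown keys, and range-checks the sensitive values with their
#' key paths in the error message.
#'
#' @param raw `NULL` (all defaults), a YAML file path, YAML text, or a
#'   nested list.
#' @return a list with materialized objects: `spec` ([PhantomSpec-class]),
#'   `cambnet` ([CambnetConfig-class]), `train` ([TrainConfig-class]),
#'   `preprocess`, `cohort`, `strata`, `output`, `seed`, and `raw` (the
#'   filled plain-list form, round-trippable through YAML).
#' @examples
#' cfg <- validateConfig(list(cohort = list(n_cases = 40)))
#' cfg$raw$train$base_lr
#' @export
validateConfig <- function(raw = NULL) {
  if (is.character(raw)) {
    raw <- if (length(raw) == 1 && file.exists(raw)) yaml::read_yaml(raw)
           else yaml::yaml.load(paste(raw, collapse = "\n"))
  }
  cfg <- mergeConfig(runConfigDefaults(), raw)
  checkRange(cfg$train$test_fraction, 0, 1, "train.test_fraction",
             openLo = TRUE, openHi = TRUE)
  checkRange(cfg$train$val_fraction, 0, 1, "train.val_fraction",
             openHi = TRUE)
  checkRange(cfg$train$lr_decay_factor, 0, 1, "train.lr_decay_factor",
             openLo = TRUE)
  checkRange(cfg$phantom$spiculation_amplitude, 0, 1,
             "phantom.spiculation_amplitude", openHi = TRUE)
  checkRange(cfg$model$dropout_rate, 0, 1, "model.dropout_rate",
             openHi = TRUE)
  checkRange(cfg$cohort$class_balance, 0, 1, "cohort.class_balance",
             openLo = TRUE, openHi = TRUE)
  for (s in cfg$strata) {
    if (!s$covariate %in% c("menarche_age", "tumor_size"))
      stopNamed("cambnet_config_error",
                paste0("strata.covariate: unknown covariate ", s$covariate))
  }
  spec <- phantomSpec(
    imageSide = cfg$phantom$image_side, nChannels = cfg$phantom$n_channels,
    lesionRadiusRange = c(cfg$phantom$lesion_radius_min,
                          cfg$phantom$lesion_radius_max),
    spiculationAmplitude = cfg$phantom$spiculation_amplitude,
    ringContrast = cfg$phantom$ring_contrast,
    backgroundNoiseScale = cfg$phantom$background_noise_scale,
    pixelSpacing = cfg$phantom$pixel_spacing,
    seed = cfg$seed)
  cambnet <- cambnetConfig(
    inChannels = cfg$phantom$n_channels,
    nClasses = cfg$model$n_classes,
    seReductionRatio = cfg$model$se_reduction_ratio,
    dropoutRate = cfg$model$dropout_rate,
    attentionKernelSize = cfg$model$attention_kernel_size,
    attentionWiring = cfg$model$attention_wiring)
  train <- trainConfig(
    batchSizeTrain = cfg$train$batch_size_train,
    batchSizeEval = cfg$train$batch_size_eval,
    maxEpochs = cfg$train$max_epochs,
    baseLr = cfg$train$base_lr,
    lrDecayFactor = cfg$train$lr_decay_factor,
    lrDecayIntervalEpochs = cfg$train$lr_decay_interval_epochs,
    optimizerName = cfg$train$optimizer,
    l2Weight = cfg$train$l2_weight,
    kernelMaxnorm = cfg$train$kernel_maxnorm,
    seed = cfg$seed, nFolds = cfg$train$n_folds,
    testFraction = cfg$train$test_fraction,
    valFraction = cfg$train$val_fraction,
    augment = isTRUE(cfg$train$augment))
  list(seed = as.integer(cfg$seed), spec = spec, cambnet = cambnet,
       train = train, preprocess = cfg$preprocess, cohort = cfg$cohort,
       strata = cfg$strata, output = cfg$output, raw = cfg)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture config, all parameters, the
#' batch-norm running statistics and the class-level order.
#'
#' @param model a [CambnetModel-class].
#' @param path checkpoint file path.
#' @param classLevels optional label order to embed.
#' @return `saveCambnet` invisibly returns `path`; `loadCambnet` returns a
#'   list with `model` and `classLevels`.
#' @export
saveCambnet <- function(model, path, classLevels = NULL) {
  saveRDS(list(config = model@config, params = model@params,
               state = model@state, classLevels = classLevels), path)
  invisible(path)
}

#' @rdname saveCambnet
#' @export
loadCambnet <- function(path) {
  obj <- readRDS(path)
  list(model = new("CambnetModel", config = obj$config,
                   params = obj$params, state = obj$state),
       classLevels = obj$classLevels)
}

stageWrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopNamed("cambnet_pipeline_error",
              sprintf("pipeline stage '%s' failed: %s", stage,
                      conditionMessage(e)))
  })
}

reportRow <- function(report) {
  data.frame(accuracy = report@accuracy, precision = report@precision,
             recall = report@recall, f1 = report@f1, auc = report@auc,
             auc_macro = report@aucMacro, n = report@n)
}

#' Run the end-to-end pipeline
#'
#' simulate -> preprocess -> split -> train -> evaluate (global and
#' per-stratum) -> explain, writing all artifacts under the configured
#' output directory: `config.yaml` (the materialized config) and
#' `manifest.json` (config MD5, package and R versions), `metrics.csv`,
#' `subgroups.csv`, `history.csv` and `history.jsonl`, `roc.png`,
#' `checkpoint.rds`, and per-case Grad-CAM localization scores in
#' `gradcam.csv`. Re-running with the same config and seed reproduces the
#' metrics exactly. Any stage failure aborts with the stage name and cause.
#'
#' @param config output of [validateConfig()] (or anything it accepts).
#' @param inputDir optional directory of an existing cohort (layout of
#'   [writeCohort()]); when given, simulation is skipped.
#' @return invisibly, a list with the trained fit, the test-set
#'   [MetricsReport-class], the subgroup table and the artifact paths.
#' @export
runPipeline <- function(config = validateConfig(), inputDir = NULL) {
  if (!is.list(config) || is.null(config$raw)) config <- validateConfig(config)
  outDir <- config$output$dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (is.null(inputDir)) {
    stageWrap("simulate",
              generateCohort(config$cohort$n_cases,
                             config$cohort$class_balance,
                             config$spec, seed = config$seed))
  } else {
    stageWrap("read", readCohort(inputDir, config$spec@nChannels))
  }

  patches <- stageWrap("preprocess", preprocessCohort(
    cohort, margin = config$preprocess$margin, size = config$preprocess$size,
    mean = config$preprocess$norm_mean, sd = config$preprocess$norm_sd))

  plan <- stageWrap("split", patientSplit(
    patches@metadata, testFraction = config$train@testFraction,
    valFraction = config$train@valFraction, seed = config$seed,
    nFolds = config$train@nFolds))

  model <- stageWrap("build", buildCambnet(config$cambnet,
                                           seed = config$seed))
  fit <- stageWrap("train", trainCambnet(model, patches, plan,
                                         config$train))

  testIdx <- which(patches@metadata$patient_id %in% plan@testIds)
  testSet <- subsetPatchSet(patches, testIdx)
  report <- stageWrap("evaluate", evaluateModel(
    fit$model, testSet, classLevels = fit$classLevels))

  subgroups <- stageWrap("subgroups", do.call(rbind, lapply(
    config$strata, function(s) subgroupEval(
      fit$model, testSet, covariate = s$covariate, threshold = s$threshold,
      scheme = s$scheme, classLevels = fit$classLevels))))

  explain <- stageWrap("explain", {
    nExp <- min(config$output$n_explain, length(testIdx))
    rows <- lapply(seq_len(nExp), function(k) {
      i <- testIdx[k]
      case <- cohort@cases[[i]]
      sal <- gradCam(fit$model, patches@data[, , , i, drop = TRUE])
      box <- extractBoundingBox(case@mask, config$preprocess$margin)
      pm <- maskToPatch(case@mask, box, config$preprocess$size)
      data.frame(patient_id = case@patientId,
                 target_class = sal@targetClass,
                 localization = localizationScore(sal, pm),
                 uniform_baseline = mean(pm > 0))
    })
    do.call(rbind, rows)
  })

  # artifacts
  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config$raw, cfgPath)
  manifest <- list(config_md5 = unname(tools::md5sum(cfgPath)),
                   package = "cambnet",
                   package_version = as.character(utils::packageVersion("cambnet")),
                   r_version = R.version.string,
                   seed = config$seed)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write.csv(reportRow(report), file.path(outDir, "metrics.csv"),
            row.names = FALSE)
  write.csv(subgroups, file.path(outDir, "subgroups.csv"), row.names = FALSE)
  write.csv(fit$history, file.path(outDir, "history.csv"), row.names = FALSE)
  writeLines(vapply(seq_len(nrow(fit$history)), function(i)
    jsonlite::toJSON(as.list(fit$history[i, ]), auto_unbox = TRUE,
                     digits = NA),
    character(1)), file.path(outDir, "history.jsonl"))
  write.csv(explain, file.path(outDir, "gradcam.csv"), row.names = FALSE)
  saveCambnet(fit$model, file.path(outDir, "checkpoint.rds"),
              fit$classLevels)

  # ROC curve for the test set (positive class = non-luminal)
  lab <- labelIndices(testSet@metadata$label, fit$classLevels)
  posIdx <- match("non_luminal", lab$levels)
  pv <- predict(fit$model, testSet, batchSize = config$train@batchSizeEval)
  rc <- rocCurve(pv$probs[, posIdx], as.integer(lab$idx == posIdx))
  grDevices::png(file.path(outDir, "roc.png"), width = 600, height = 600)
  graphics::plot(rc$fpr, rc$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", report@auc))
  graphics::abline(0, 1, lty = 2, col = "grey")
  grDevices::dev.off()

  invisible(list(fit = fit, report = report, subgroups = subgroups,
                 explain = explain, plan = plan,
                 dir = normalizePath(outDir)))
}
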