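# Shared fixtures, built once per test run and cached. The 200-case cohort
# and the 30-epoch trained model realize the study conditions the heavier
# checks run under; lighter tests use the small cohort.

.fixtureEnv <- new.env(parent = emptyenv())

fixtureMemo <- function(name, builder) {
  if (is.null(.fixtureEnv[[name]])) .fixtureEnv[[name]] <- builder()
  .fixtureEnv[[name]]
}

smallCohort <- function() {
  fixtureMemo("smallCohort", function() {
    generateCohort(16, spec = phantomSpec(imageSide = 128), seed = 101)
  })
}

studyCohort <- function() {
  fixtureMemo("studyCohort", function() {
    generateCohort(200, spec = phantomSpec(), seed = 1)
  })
}

studyPatches <- function() {
  fixtureMemo("studyPatches", function() preprocessCohort(studyCohort()))
}

studyFit <- function() {
  fixtureMemo("studyFit", function() {
    ps <- studyPatches()
    plan <- patientSplit(patchMetadata(ps), seed = 1)
    model <- buildCambnet(seed = 1)
    fit <- trainCambnet(model, ps, plan, trainConfig(maxEpochs = 30L,
                                                     seed = 1))
    list(fit = fit, plan = plan)
  })
}

studyTestSet <- function() {
  ps <- studyPatches()
  plan <- studyFit()$plan
  idx <- which(patchMetadata(ps)$patient_id %in% plan@testIds)
  list(patches = subsetPatchSet(ps, idx), idx = idx)
}
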