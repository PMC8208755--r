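# Shared fixtures, built lazily and cached for the whole run. The
# reference fixture (seed 7: 2000 samples x 200 taxa, true latent dim 5,
# depth 10000) is the dataset every cross-module property refers to;
# smaller datasets serve the per-module unit tests.

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, build(), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# small dataset for fast unit tests
smallData <- function() {
  .cached("small", function()
    generateSyntheticDataset(syntheticConfig(
      nSamples = 300L, nTaxa = 40L, nPhyla = 6L, trueLatentDim = 3L,
      depth = 2000L, seed = 5L)))
}

smallSplit <- function() {
  .cached("smallSplit", function()
    splitDataset(sampleIds(smallData()$abundance), 0.2, k = 2L, seed = 2L))
}

smallConfig <- function(...) {
  args <- utils::modifyList(list(latentDim = 4L, hidden = 32L,
                                 epochs = 30L, patience = 5L, seed = 4L),
                            list(...))
  do.call(architectureConfig, args)
}

# the reference fixture at the study conditions
fixtureData <- function() {
  .cached("fixture", function() generateSyntheticDataset(syntheticConfig()))
}

fixtureSplit <- function() {
  .cached("fixtureSplit", function()
    splitDataset(sampleIds(fixtureData()$abundance), 0.1, k = 5L,
                 seed = 1L))
}

fixtureConfig <- function(...) {
  args <- utils::modifyList(list(latentDim = 10L, hidden = 256L,
                                 normalization = "tss",
                                 loss = "braycurtis", seed = 3L),
                            list(...))
  do.call(architectureConfig, args)
}

# train/early-stop/test partition of the fixture: the first CV fold's
# validation samples drive early stopping
fixtureParts <- function() {
  .cached("fixtureParts", function() {
    ds <- fixtureData(); sp <- fixtureSplit()
    fit <- cvFolds(sp)[[1L]]$fit; es <- cvFolds(sp)[[1L]]$val
    list(trainOtu = ds$abundance[, fit], trainEnv = ds$environment[fit, ],
         valOtu = ds$abundance[, es], valEnv = ds$environment[es, ],
         testOtu = ds$abundance[, testIds(sp)],
         testEnv = ds$environment[testIds(sp), ],
         testActual = tssNormalize(ds$abundance[, testIds(sp)]),
         fitIds = fit, esIds = es)
  })
}

# reference OTU autoencoder on the fixture
fixtureAE <- function() {
  .cached("fixtureAE", function() {
    p <- fixtureParts()
    trainOtuAutoencoder(p$trainOtu, p$valOtu, fixtureConfig())
  })
}

# combined-latent-space prediction model on the fixture
fixtureCombinedModel <- function() {
  .cached("fixtureCombined", function() {
    p <- fixtureParts()
    fitPredictionPipeline(p$trainOtu, p$trainEnv, p$valOtu, p$valEnv,
                          fixtureConfig(), mode = "combined")
  })
}

# evaluate a tss prediction table against the fixture test set
evalOnFixtureTest <- function(pred) {
  evaluateComposition(pred, fixtureParts()$testActual)
}

# recompute composition proportions from the generator's true mapping for
# arbitrary environmental settings (the generator oracle)
truthProportions <- function(truth, envDf) {
  ranges <- list(age = c(0, 20), temperature = c(50, 90), rain = c(0, 5))
  vocab <- list(line = paste0("L", 1:4), variety = paste0("V", 1:6))
  cols <- lapply(names(ranges), function(f)
    (envDf[[f]] - mean(ranges[[f]])) / (diff(ranges[[f]]) / 2))
  m <- do.call(cbind, cols)
  for (f in names(vocab))
    m <- cbind(m, outer(envDf[[f]], vocab[[f]], `==`) * 1)
  z <- tanh(sweep(m %*% truth$B, 2L, truth$b0, "+"))
  logits <- sweep(z %*% truth$W, 2L, truth$b, "+")
  e <- exp(logits - apply(logits, 1L, max))
  t(e / rowSums(e))
}

# tiny abundance/taxonomy/environment TSV fixtures written on the fly
writeTempTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
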