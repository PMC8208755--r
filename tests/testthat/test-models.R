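# Autoencoder training, latent predictor, assembly, grid machinery,
# persistence. Heavier fixture-scale properties live in
# test-acceptance.R; these tests use the small dataset.

smallParts <- function() {
  ds <- smallData(); sp <- smallSplit()
  f <- cvFolds(sp)[[1L]]
  list(trO = ds$abundance[, f$fit], trE = ds$environment[f$fit, ],
       vaO = ds$abundance[, f$val], vaE = ds$environment[f$val, ],
       teO = ds$abundance[, testIds(sp)],
       teE = ds$environment[testIds(sp), ])
}

test_that("training improves reconstruction over the untrained network", {
  p <- smallParts()
  cfg <- smallConfig()
  ae <- trainOtuAutoencoder(p$trO, p$vaO, cfg)
  ae0 <- trainOtuAutoencoder(p$trO, p$vaO, smallConfig(epochs = 0L))
  actual <- tssNormalize(p$teO)
  rTrained <- evaluateComposition(reconstructComposition(ae, p$teO), actual)
  rUntrained <- evaluateComposition(reconstructComposition(ae0, p$teO),
                                    actual)
  expect_gt(pearsonMean(rTrained), pearsonMean(rUntrained))
  # untrained net is no better than the default mean predictor
  def <- fitDefaultBaseline(tssNormalize(p$trO))
  rDef <- evaluateComposition(predictBaseline(def, p$teE), actual)
  expect_lte(pearsonMean(rUntrained), pearsonMean(rDef) + 0.05)
  expect_gt(nrow(trainingHistory(ae)), 0L)
})

test_that("training is reproducible under a fixed seed", {
  p <- smallParts()
  cfg <- smallConfig(epochs = 10L)
  a <- trainOtuAutoencoder(p$trO, p$vaO, cfg)
  b <- trainOtuAutoencoder(p$trO, p$vaO, cfg)
  expect_identical(trainingHistory(a)$val_loss,
                   trainingHistory(b)$val_loss)
  expect_identical(a@decoder$W, b@decoder$W)
})

test_that("divergence raises an error naming the epoch", {
  p <- smallParts()
  bad <- smallConfig(learningRate = 1e154, epochs = 5L,
                     activation = "relu", normalization = "tss_clr",
                     loss = "mse")
  expect_error(trainOtuAutoencoder(p$trO, p$vaO, bad), "epoch")
})

test_that("combined AE aligns latents and reconstructs from both encoders", {
  p <- smallParts()
  cfg <- smallConfig(epochs = 60L, patience = 10L)
  ae <- trainCombinedAutoencoder(p$trO, p$trE, p$vaO, p$vaE, cfg)
  # alignment at convergence is far below the untrained-network alignment
  ae0 <- trainCombinedAutoencoder(p$trO, p$trE, p$vaO, p$vaE,
                                  smallConfig(epochs = 0L))
  alignOf <- function(m) mean((latentCodes(m, p$vaO) -
                               envLatentCodes(m, p$vaE))^2)
  expect_lt(alignOf(ae), alignOf(ae0))
  # trend over the last recorded epochs is non-increasing
  h <- trainingHistory(ae)
  if (nrow(h) >= 10L) {
    last10 <- tail(h$align, 10L)
    # no late-phase growth beyond minibatch noise
    expect_lte(mean(tail(last10, 5L)), mean(head(last10, 5L)) * 1.15)
  }
  # zero alignment weight: no collapse of the latent distance
  aeW0 <- trainCombinedAutoencoder(p$trO, p$trE, p$vaO, p$vaE,
                                   smallConfig(epochs = 20L,
                                               alignWeight = 0))
  expect_gt(alignOf(aeW0), alignOf(ae0) / 10)
  # env-path reconstruction close to otu-path reconstruction
  actual <- tssNormalize(p$teO)
  rOtu <- evaluateComposition(reconstructComposition(ae, p$teO), actual)
  predEnv <- predictComposition(assemblePredictionModel(ae, "combined"),
                                p$teE)
  rEnv <- evaluateComposition(predEnv, actual)
  expect_gte(pearsonMean(rEnv), pearsonMean(rOtu) - 0.15)
})

test_that("latent predictor recovers a linear map and beats nothing less", {
  set.seed(9)
  E <- matrix(rnorm(600), 200, 3)
  B <- matrix(rnorm(12), 3, 4)
  Z <- E %*% B + matrix(rnorm(800, sd = 0.05), 200, 4)
  pr <- trainLatentPredictor(E[1:160, ], Z[1:160, ],
                             smallConfig(epochs = 300L, patience = 30L))
  zp <- LatentMicrobiome:::.nnForward(pr, E[161:200, ])$out
  zt <- Z[161:200, ]
  r2 <- 1 - sum((zp - zt)^2) / sum(sweep(zt, 2, colMeans(zt))^2)
  expect_gte(r2, 0.95)
  # OLS oracle on the same data attains a comparable fit
  ols <- lm.fit(cbind(1, E[1:160, ]), Z[1:160, ])
  zo <- cbind(1, E[161:200, ]) %*% ols$coefficients
  r2o <- 1 - sum((zo - zt)^2) / sum(sweep(zt, 2, colMeans(zt))^2)
  expect_gte(r2, r2o - 0.05)
  # constant targets are reproduced with ~zero error
  Zc <- matrix(0.3, 160, 2)
  prc <- trainLatentPredictor(E[1:160, ], Zc,
                              smallConfig(epochs = 100L, patience = 20L))
  zc <- LatentMicrobiome:::.nnForward(prc, E[161:200, ])$out
  expect_lt(mean((zc - 0.3)^2), 5e-3)
  # determinism
  pr2 <- trainLatentPredictor(E[1:160, ], Z[1:160, ],
                              smallConfig(epochs = 300L, patience = 30L))
  expect_identical(pr$W, pr2$W)
})

test_that("assembled models emit simplex predictions and persist bit-identically", {
  p <- smallParts()
  model <- fitPredictionPipeline(p$trO, p$trE, p$vaO, p$vaE,
                                 smallConfig(), mode = "otu_latent")
  pred <- predictComposition(model, p$teE)
  expect_equal(unname(colSums(abundanceValues(pred))),
               rep(1, ncol(abundanceValues(pred))), tolerance = 1e-9)
  expect_true(all(abundanceValues(pred) >= 0))
  dir <- tempfile()
  saveModel(model, dir)
  back <- loadModel(dir)
  expect_identical(abundanceValues(predictComposition(back, p$teE)),
                   abundanceValues(pred))
  expect_identical(parameterDigest(back), parameterDigest(model))
  # missing components are refused
  ae <- trainOtuAutoencoder(p$trO, p$vaO, smallConfig(epochs = 2L))
  expect_error(assemblePredictionModel(ae, "otu_latent"), "predictor")
  expect_error(assemblePredictionModel(ae, "combined"), "environmental")
})

test_that("frozen decoder is bit-identical through predictor training", {
  p <- smallParts()
  ae <- trainOtuAutoencoder(p$trO, p$vaO, smallConfig())
  digBefore <- parameterDigest(ae)
  enc <- encodeEnvironment(p$trE)
  pr <- trainLatentPredictor(enc$matrix, latentCodes(ae, p$trO),
                             smallConfig())
  m <- assemblePredictionModel(ae, "otu_latent", predictor = pr,
                               schema = enc$schema)
  expect_identical(parameterDigest(m), digBefore)
  expect_true(m@frozen)
})

test_that("grid enumeration counts match a brute-force constraint check", {
  full <- enumerateGrid(filterInvalid = FALSE, epochs = 1L)
  expect_length(full, 1296L)
  valid <- enumerateGrid(epochs = 1L)
  # brute-force count of valid loss x normalization pairs over the grid
  nValid <- 0L
  for (lo in c("mse", "crossentropy", "braycurtis"))
    for (no in c("tss", "tss_clr"))
      if (lo == "mse" || no == "tss") nValid <- nValid + 1L
  expect_length(valid, 1296L / 6L * nValid)
  expect_true(all(vapply(valid, function(c)
    c$loss == "mse" || c$normalization == "tss", logical(1))))
})

test_that("grid search of one config returns it ranked first", {
  ds <- smallData()
  sp <- smallSplit()
  res <- gridSearch(ds$abundance, ds$environment,
                    list(smallConfig(epochs = 5L)), sp)
  expect_equal(nrow(res), 1L)
  expect_equal(res$rank, 1L)
  expect_true(all(c("pearson", "braycurtis") %in% colnames(res)))
})
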