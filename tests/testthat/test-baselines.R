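# The three reference predictors and their contracts.

test_that("default baseline stores the closed mean and ignores features", {
  m <- matrix(c(0.2, 0.8, 0.4, 0.6), 2,
              dimnames = list(c("t1", "t2"), c("s1", "s2")))
  def <- fitDefaultBaseline(AbundanceTable(m, scale = "tss"))
  env <- EnvironmentTable(data.frame(x = c(1, 99),
                                     row.names = c("a", "b")))
  pred <- predictBaseline(def, env)
  expect_equal(unname(abundanceValues(pred)[, 1]), c(0.3, 0.7))
  expect_equal(abundanceValues(pred)[, 1], abundanceValues(pred)[, 2])
  expect_equal(sum(abundanceValues(pred)[, 1]), 1)
  expect_error(fitDefaultBaseline(AbundanceTable(m * 2)), "tss scale")
})

test_that("default predictor scores RRSE 1 on the set defining its mean", {
  ds <- smallData()
  tss <- tssNormalize(ds$abundance)
  def <- fitDefaultBaseline(tss)
  env <- ds$environment
  rr <- rrsePerOtu(abundanceValues(predictBaseline(def, env)),
                   abundanceValues(tss))
  expect_equal(unname(as.numeric(rr)), rep(1, length(rr)),
               tolerance = 1e-9)
})

test_that("linear baseline fits realizable targets and reduces to the mean", {
  set.seed(6)
  n <- 60
  env <- EnvironmentTable(data.frame(x = runif(n), y = runif(n),
                                     row.names = paste0("s", 1:n)))
  # targets exactly linear in features on the clr scale
  E <- cbind(1, as.matrix(environmentData(env)))
  B <- matrix(rnorm(3 * 5), 3, 5)
  Yclr <- E %*% B
  Yclr <- Yclr - rowMeans(Yclr)
  counts <- round(t(exp(Yclr) / rowSums(exp(Yclr))) * 1e6)
  dimnames(counts) <- list(paste0("t", 1:5), paste0("s", 1:n))
  tab <- AbundanceTable(counts)
  lin <- fitLinearBaseline(env, tab, NormalizationState("tss_clr", 1e-9))
  pred <- predictBaseline(lin, env)
  expect_gt(as.numeric(meanPearson(abundanceValues(pred),
                                   abundanceValues(tssNormalize(tab)))),
            0.999)
  # intercept-only design reproduces the default predictor
  flat <- EnvironmentTable(data.frame(z = rep(1, n),
                                      row.names = paste0("s", 1:n)))
  lin0 <- suppressWarnings(fitLinearBaseline(flat, tab))
  def <- fitDefaultBaseline(tssNormalize(tab))
  expect_equal(abundanceValues(predictBaseline(lin0, flat)),
               abundanceValues(predictBaseline(def, flat)),
               tolerance = 1e-6)
})

test_that("zero-hidden MLP approaches the linear solve's held-out loss", {
  ds <- smallData(); sp <- smallSplit()
  f <- cvFolds(sp)[[1L]]
  cfg <- smallConfig(hidden = integer(), normalization = "tss_clr",
                     loss = "mse", epochs = 400L, patience = 40L,
                     learningRate = 0.01)
  mlp <- fitMlpBaseline(ds$environment[f$fit, ], ds$abundance[, f$fit],
                        ds$environment[f$val, ], ds$abundance[, f$val],
                        cfg)
  lin <- suppressWarnings(
    fitLinearBaseline(ds$environment[f$fit, ], ds$abundance[, f$fit],
                      NormalizationState("tss_clr", 1)))
  te <- testIds(sp)
  actual <- abundanceValues(tssNormalize(ds$abundance[, te]))
  mseOf <- function(model) mean((abundanceValues(
    predictBaseline(model, ds$environment[te, ])) - actual)^2)
  expect_lte(mseOf(mlp), mseOf(lin) * 1.2 + 1e-8)
  # determinism under fixed seed
  mlp2 <- fitMlpBaseline(ds$environment[f$fit, ], ds$abundance[, f$fit],
                         ds$environment[f$val, ], ds$abundance[, f$val],
                         cfg)
  expect_identical(mlp@fit$net$W, mlp2@fit$net$W)
})

test_that("all baselines emit simplex predictions", {
  ds <- smallData(); sp <- smallSplit()
  f <- cvFolds(sp)[[1L]]
  te <- ds$environment[testIds(sp), ]
  models <- list(
    fitDefaultBaseline(tssNormalize(ds$abundance[, f$fit])),
    suppressWarnings(
      fitLinearBaseline(ds$environment[f$fit, ], ds$abundance[, f$fit])),
    fitMlpBaseline(ds$environment[f$fit, ], ds$abundance[, f$fit],
                   ds$environment[f$val, ], ds$abundance[, f$val],
                   smallConfig(hidden = 16L, epochs = 5L)))
  for (m in models) {
    v <- abundanceValues(predictBaseline(m, te))
    expect_true(all(v >= 0))
    expect_equal(unname(colSums(v)), rep(1, ncol(v)), tolerance = 1e-9)
  }
})
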