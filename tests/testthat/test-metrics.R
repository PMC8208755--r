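# Metric definitions against hand values and brute-force oracles.

test_that("Bray-Curtis matches hand values and is symmetric and bounded", {
  expect_equal(brayCurtis(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(brayCurtis(c(1, 0), c(0, 1)), 1)
  expect_equal(brayCurtis(c(0.7, 0.3), c(0.5, 0.5)), 0.2)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(brayCurtis(c(-1, 2), c(1, 0)), "nonnegative")
  set.seed(1)
  for (i in 1:20) {
    u <- runif(10); v <- runif(10)
    expect_equal(brayCurtis(u, v), brayCurtis(v, u))
    expect_gte(brayCurtis(u, v), 0)
    expect_lte(brayCurtis(u, v), 1)
  }
})

test_that("mean Pearson handles both orientations and excludes constants", {
  set.seed(2)
  a <- matrix(runif(100), 10, dimnames = list(paste0("t", 1:10),
                                              paste0("s", 1:10)))
  expect_equal(as.numeric(meanPearson(a, a)), 1)
  # per-sample anti-correlation: reflect each sample around its mean
  refl <- 2 * matrix(colMeans(a), 10, 10, byrow = TRUE) - a
  expect_equal(as.numeric(meanPearson(refl, a, "per_sample")), -1)
  # constant prediction per taxon: per-otu undefined, per-sample finite
  const <- matrix(rowMeans(a), 10, 10, dimnames = dimnames(a))
  expect_error(meanPearson(const, a, "per_otu"), "undefined")
  expect_true(is.finite(meanPearson(const, a, "per_sample")))
})

test_that("error metrics match hand arithmetic and the zero-exclusion rule", {
  em <- errorMetrics(c(1.1, 1.8), c(1, 2))
  expect_equal(em$mae, 0.15)
  expect_equal(em$mse, 0.025)
  expect_equal(em$mape, 0.1)
  expect_equal(errorMetrics(1:5, 1:5)[c("mae", "mse", "mape")],
               list(mae = 0, mse = 0, mape = 0))
  em0 <- errorMetrics(c(0.5, 2), c(0, 2))
  expect_equal(em0$mape, 0)
  expect_equal(em0$mape_n, 1L)
})

test_that("per-taxon RRSE is 1 for the mean predictor and 0 for perfection", {
  set.seed(3)
  a <- matrix(runif(50), 10, 5, dimnames = list(paste0("t", 1:10),
                                                paste0("s", 1:5)))
  mu <- matrix(rowMeans(a), 10, 5, dimnames = dimnames(a))
  expect_equal(unname(as.numeric(rrsePerOtu(mu, a))), rep(1, 10))
  expect_equal(unname(as.numeric(rrsePerOtu(a, a))), rep(0, 10))
  # zero-variance taxa are excluded and reported
  a2 <- a; a2["t3", ] <- 0.2
  rr <- rrsePerOtu(mu, a2)
  expect_false("t3" %in% names(rr))
  expect_equal(attr(rr, "excluded"), "t3")
})

test_that("metrics agree with brute-force loops on random matrices", {
  set.seed(4)
  for (rep in 1:5) {
    p <- matrix(runif(200), 20, 10)
    a <- matrix(runif(200), 20, 10)
    dimnames(p) <- dimnames(a) <- list(paste0("t", 1:20), paste0("s", 1:10))
    bfSample <- mean(sapply(1:10, function(j) cor(p[, j], a[, j])))
    bfOtu <- mean(sapply(1:20, function(i) cor(p[i, ], a[i, ])))
    expect_equal(as.numeric(meanPearson(p, a, "per_sample")), bfSample,
                 tolerance = 1e-12)
    expect_equal(as.numeric(meanPearson(p, a, "per_otu")), bfOtu,
                 tolerance = 1e-12)
    bfRrse <- sapply(1:20, function(i)
      sqrt(sum((p[i, ] - a[i, ])^2) / sum((a[i, ] - mean(a[i, ]))^2)))
    expect_equal(unname(as.numeric(rrsePerOtu(p, a))), bfRrse,
                 tolerance = 1e-12)
  }
})

test_that("best-predicted ranking takes the ceiling and reports phyla", {
  rr <- setNames(seq(0.1, 4, length.out = 40), sprintf("t%02d", 1:40))
  tax <- TaxonomyTable(data.frame(
    Kingdom = "B", Phylum = rep(c("PA", "PB", "PC", "PD"), each = 10),
    Class = "c", Order = "o", Family = "f", Genus = "g",
    Species = names(rr), row.names = names(rr)))
  top <- rankBestPredicted(rr, tax, 0.05)
  expect_equal(nrow(top$taxa), 2L)  # ceiling(0.05 * 40)
  top10 <- rankBestPredicted(rr, tax, 0.25)
  expect_equal(nrow(top10$taxa), 10L)
  expect_equal(unname(top10$phylum_percent["PA"]), 100)
  # ties broken by taxon id: deterministic
  tied <- setNames(rep(1, 40), names(rr))
  t1 <- rankBestPredicted(tied, tax, 0.1)
  expect_identical(t1$taxa$taxon_id, sort(names(rr))[1:4])
})

test_that("training losses match definitions and are minimized at truth", {
  pred <- matrix(c(0.3, 0.7), 1)
  expect_equal(lossValue("braycurtis", pred, pred), 0)
  expect_equal(lossValue("mse", matrix(c(0, 1), 1), matrix(c(1, 1), 1)),
               0.5)
  # crossentropy on the simplex is minimized at pred == target
  targ <- matrix(c(0.2, 0.5, 0.3), 1)
  atTruth <- lossValue("crossentropy", targ, targ)
  for (d in list(c(0.05, -0.05, 0), c(-0.1, 0.02, 0.08)))
    expect_gt(lossValue("crossentropy", targ + rbind(d), targ), atTruth)
  # invalid configuration: simplex losses under clr normalization
  expect_error(architectureConfig(loss = "braycurtis",
                                  normalization = "tss_clr"),
               "configuration error")
})

test_that("evaluation report composes the panel on the tss scale only", {
  ds <- smallData()
  tss <- tssNormalize(ds$abundance[, 1:20])
  rep <- evaluateComposition(tss, tss)
  expect_equal(pearsonMean(rep), 1)
  expect_equal(brayCurtisMean(rep), 0)
  expect_equal(rep@mae, 0)
  expect_error(evaluateComposition(ds$abundance[, 1:20], tss), "tss scale")
  f <- tempfile(fileext = ".json")
  writeEvaluationReport(rep, f)
  expect_true(file.exists(f))
  back <- jsonlite::read_json(f)
  expect_equal(back$pearson_mean, 1)
})
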