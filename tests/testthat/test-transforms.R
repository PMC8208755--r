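# Normalization algebra, inverses, aggregation, feature encoding.

test_that("tss divides columns by their sums and rejects zero depth", {
  m <- matrix(c(2, 2, 4), 3, dimnames = list(paste0("t", 1:3), "s1"))
  tss <- tssNormalize(AbundanceTable(m))
  expect_equal(unname(abundanceValues(tss)[, 1]), c(0.25, 0.25, 0.5))

  one <- AbundanceTable(matrix(7, 1, dimnames = list("t1", "s1")))
  expect_equal(unname(abundanceValues(tssNormalize(one))[, 1]), 1)

  z <- AbundanceTable(matrix(0, 3, 1,
                             dimnames = list(paste0("t", 1:3), "sZ")))
  expect_error(tssNormalize(z), "zero-depth sample: sZ")
})

test_that("clr matches the hand-computed geometric-mean form", {
  # proportions (1,2,4,8)/15: geometric mean 2^1.5/15, clr = +/-(1.5, 0.5)*log 2
  p <- matrix(c(1, 2, 4, 8) / 15, 4)
  got <- LatentMicrobiome:::.clrOfProportions(p)
  expect_equal(unname(got[, 1]),
               c(-1.5, -0.5, 0.5, 1.5) * log(2), tolerance = 1e-12)
  # scale invariance of the ratio transform
  expect_equal(LatentMicrobiome:::.clrOfProportions(p * 10), got,
               tolerance = 1e-12)

  eq <- AbundanceTable(matrix(1, 4, 1,
                              dimnames = list(paste0("t", 1:4), "s1")))
  expect_equal(unname(abundanceValues(clrTransform(eq, 1))[, 1]),
               rep(0, 4))
  expect_error(clrTransform(tssNormalize(eq)), "counts-scale")
})

test_that("inverseToRelative inverts clr and clips/re-closes tss output", {
  clrState <- NormalizationState("tss_clr", 1)
  sym <- inverseToRelative(matrix(0, 3, 1,
                                  dimnames = list(paste0("t", 1:3), "s")),
                           clrState)
  expect_equal(unname(abundanceValues(sym)[, 1]), rep(1 / 3, 3))

  p <- matrix(c(0.2, 0.3, 0.5), 3, dimnames = list(paste0("t", 1:3), "s"))
  back <- inverseToRelative(LatentMicrobiome:::.clrOfProportions(p),
                            clrState)
  expect_equal(abundanceValues(back), p, tolerance = 1e-9)

  tssState <- NormalizationState("tss")
  out <- inverseToRelative(matrix(c(0.5, -0.1, 0.7), 3,
                                  dimnames = list(paste0("t", 1:3), "s")),
                           tssState)
  expect_equal(unname(abundanceValues(out)[, 1]),
               c(0.41666667, 0, 0.58333333), tolerance = 1e-7)
})

test_that("taxonomic aggregation sums lineage groups and conserves mass", {
  m <- matrix(c(3, 2, 5), 3, dimnames = list(paste0("t", 1:3), "s1"))
  tax <- TaxonomyTable(data.frame(
    Kingdom = "B", Phylum = c("P1", "P1", "P2"), Class = "c", Order = "o",
    Family = "f", Genus = "g", Species = paste0("t", 1:3),
    row.names = paste0("t", 1:3)))
  agg <- aggregateTaxa(AbundanceTable(m), tax, "Phylum")
  expect_equal(unname(abundanceValues(agg)[, 1]), c(5, 5))
  expect_error(aggregateTaxa(
    AbundanceTable(matrix(0.1, 3, 1,
                          dimnames = list(paste0("t", 1:3), "s")) ,
                   scale = "clr"), tax, "Phylum"), "clr")

  ds <- smallData()
  agg2 <- aggregateTaxa(ds$abundance, ds$taxonomy, "Phylum")
  expect_lte(nrow(abundanceValues(agg2)), 6L)
  expect_identical(colSums(abundanceValues(agg2)),
                   colSums(abundanceValues(ds$abundance)))
})

test_that("fixture taxonomy with declared rank sizes aggregates to those row counts", {
  # rank-size template from the maize study: 16 phyla, 45 classes.
  # Each of 45 class labels nests under one of 16 phyla; 120 taxa cycle
  # through the classes, so every phylum and class occurs.
  nTaxa <- 120L
  ids <- sprintf("t%03d", seq_len(nTaxa))
  classIdx <- rep_len(seq_len(45L), nTaxa)
  phylumOfClass <- rep_len(seq_len(16L), 45L)
  tax <- TaxonomyTable(data.frame(
    Kingdom = "B", Phylum = sprintf("P%02d", phylumOfClass[classIdx]),
    Class = sprintf("C%02d", classIdx),
    Order = "o", Family = "f", Genus = "g", Species = ids,
    row.names = ids))
  m <- matrix(1, nTaxa, 2, dimnames = list(ids, c("s1", "s2")))
  tab <- AbundanceTable(m)
  expect_equal(nrow(abundanceValues(aggregateTaxa(tab, tax, "Phylum"))),
               16L)
  expect_equal(nrow(abundanceValues(aggregateTaxa(tab, tax, "Class"))),
               45L)
})

test_that("environment encoding learns training statistics and vocabulary", {
  df <- data.frame(temperature = c(50, 60, 70),
                   line = c("B73", "Mo17", "B73"),
                   row.names = paste0("s", 1:3))
  env <- EnvironmentTable(df)
  enc <- encodeEnvironment(env)
  expect_equal(unname(enc$matrix[, "temperature"]),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(unname(enc$matrix[1, c("line=B73", "line=Mo17")]),
               c(1, 0))
  # transforming training data with its own schema: mean 0, population sd 1
  expect_equal(mean(enc$matrix[, "temperature"]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(enc$matrix[, "temperature"]^2)), 1,
               tolerance = 1e-9)

  new <- EnvironmentTable(data.frame(temperature = 55, line = "W22",
                                     row.names = "sx"))
  expect_warning(out <- encodeEnvironment(new, schema = enc$schema),
                 "unseen")
  expect_equal(unname(out$matrix[1, c("line=B73", "line=Mo17")]), c(0, 0))

  flat <- EnvironmentTable(data.frame(x = c(1, 1, 1),
                                      row.names = paste0("s", 1:3)))
  expect_warning(ze <- encodeEnvironment(flat), "zero-variance")
  expect_equal(unname(ze$matrix[, 1]), c(0, 0, 0))
})
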