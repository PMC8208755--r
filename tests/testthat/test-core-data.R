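# Container validity, TSV parsing, splitting.

test_that("abundance TSV parsing honors orientation and rejects bad input", {
  f <- writeTempTsv(c("taxon_id\ts1\ts2", "OTU1\t3\t0", "OTU2\t2\t5",
                      "OTU3\t5\t5"))
  tab <- loadAbundanceTable(f)
  expect_s4_class(tab, "AbundanceTable")
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(abundanceScale(tab), "counts")
  expect_equal(unname(abundanceValues(tab)[, 1]), c(3, 2, 5))

  ft <- writeTempTsv(c("sample_id\tOTU1\tOTU2\tOTU3", "s1\t3\t2\t5",
                       "s2\t0\t5\t5"))
  expect_equal(abundanceValues(loadAbundanceTable(ft, "samples")),
               abundanceValues(tab))

  dup <- writeTempTsv(c("taxon_id\ts1", "OTU1\t3", "OTU1\t2"))
  expect_error(loadAbundanceTable(dup), "OTU1")
  neg <- writeTempTsv(c("taxon_id\ts1", "OTU1\t-1"))
  expect_error(loadAbundanceTable(neg), "negative abundance")
  txt <- writeTempTsv(c("taxon_id\ts1", "OTU1\tabc"))
  expect_error(loadAbundanceTable(txt), "non-numeric")
})

test_that("write/load round-trip preserves values and identifier order", {
  ds <- smallData()
  tss <- tssNormalize(ds$abundance[, 1:5])
  f <- tempfile(fileext = ".tsv")
  writeAbundanceTable(tss, f)
  back <- loadAbundanceTable(f)
  expect_identical(taxonIds(back), taxonIds(tss))
  expect_identical(sampleIds(back), sampleIds(tss))
  expect_identical(abundanceValues(back), abundanceValues(tss))
})

test_that("metadata loading drops incomplete rows with a logged count", {
  f <- writeTempTsv(c("sample_id\ttemp\tline", "s1\t50\tA", "s2\t\tB",
                      "s3\t70\tA"))
  expect_message(env <- loadEnvironmentTable(f), "dropped 1")
  expect_equal(sampleIds(env), c("s1", "s3"))
  expect_equal(unname(featureKinds(env)),
               c("numeric", "categorical"))
})

test_that("container validity rejects malformed tables", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(AbundanceTable(m * -1), "negative")
  expect_error(AbundanceTable(m, scale = "tss"), "sum to 1")
  expect_silent(AbundanceTable(sweep(m, 2, colSums(m), "/"), scale = "tss"))
})

test_that("splitDataset sizes, fold balance and determinism", {
  sp <- splitDataset(paste0("s", 1:100), 0.1, k = 5, seed = 1)
  expect_length(testIds(sp), 10L)
  expect_true(all(lengths(lapply(cvFolds(sp), `[[`, "val")) == 18L))
  expect_true(all(lengths(lapply(cvFolds(sp), `[[`, "fit")) == 72L))

  sp2 <- splitDataset(paste0("s", 1:10), 0.3, k = 2, seed = 3)
  expect_length(testIds(sp2), 3L)
  expect_setequal(lengths(lapply(cvFolds(sp2), `[[`, "val")), c(4L, 3L))

  a <- splitDataset(paste0("s", 1:50), 0.2, k = 3, seed = 42)
  b <- splitDataset(paste0("s", 1:50), 0.2, k = 3, seed = 42)
  expect_identical(a, b)

  expect_error(splitDataset(paste0("s", 1:10), 0.5, k = 9, seed = 1),
               "exceed")
})

test_that("splits partition samples disjointly and exhaustively", {
  for (n in c(23, 57, 200)) for (fr in c(0.1, 0.3)) for (k in c(2, 5)) {
    ids <- paste0("x", seq_len(n))
    sp <- splitDataset(ids, fr, k = k, seed = n + k)
    expect_setequal(c(trainIds(sp), testIds(sp)), ids)
    expect_length(intersect(trainIds(sp), testIds(sp)), 0L)
    vals <- unlist(lapply(cvFolds(sp), `[[`, "val"))
    expect_setequal(vals, trainIds(sp))
    expect_false(anyDuplicated(vals) > 0)
    for (f in cvFolds(sp))
      expect_setequal(c(f$fit, f$val), trainIds(sp))
  }
})
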