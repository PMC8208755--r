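# Seeded generator of synthetic datasets with the statistical structure
# the method assumes: environmental covariates drive a low-dimensional
# latent factor which determines compositional abundances, observed
# through multinomial sequencing noise.

#' Configuration for the synthetic-data generator
#'
#' Defaults define the package's reference fixture: 2000 samples of 200
#' taxa over 12 phyla, a true latent dimension of 5, sequencing depth
#' 10000, and five environmental features mirroring a maize rhizosphere
#' design — plant age 0-20 weeks, temperature 50-90 deg F, precipitation
#' 0-5 inches, plus a categorical line (4 levels) and variety (6 levels).
#' The env-to-latent map is tanh of a seeded affine map (smooth, bounded,
#' learnable by the model family); a configurable fraction of taxa get
#' strongly negative intercepts so most counts are zero, matching
#' microbiome sparsity. All randomness flows from one root seed through
#' fixed per-stage offsets, so sub-datasets are independently
#' reproducible.
#'
#' @param nSamples,nTaxa,nPhyla,trueLatentDim,depth,seed integers.
#' @param latentNoiseSd sd of Gaussian noise added to the latent factors.
#' @param loadingScale sd of the latent-to-logit loading matrix.
#' @param sparseFraction fraction of taxa with strongly negative
#'   intercepts (rare taxa).
#' @param sparseShift intercept shift applied to that fraction.
#' @return named list of generator settings.
#' @export
syntheticConfig <- function(nSamples = 2000L, nTaxa = 200L, nPhyla = 12L,
                            trueLatentDim = 5L, depth = 10000L,
                            latentNoiseSd = 0.1, loadingScale = 1,
                            sparseFraction = 0.3, sparseShift = -3,
                            seed = 7L) {
  stopifnot(nSamples >= 2, nTaxa >= 2, nPhyla >= 1, trueLatentDim >= 1,
            depth >= 1, latentNoiseSd >= 0, sparseFraction >= 0,
            sparseFraction <= 1)
  list(nSamples = as.integer(nSamples), nTaxa = as.integer(nTaxa),
       nPhyla = as.integer(nPhyla), trueLatentDim = as.integer(trueLatentDim),
       depth = as.integer(depth), latentNoiseSd = latentNoiseSd,
       loadingScale = loadingScale, sparseFraction = sparseFraction,
       sparseShift = sparseShift, seed = as.integer(seed))
}

# env design for the truth mapping: numerics scaled to [-1, 1], one-hot
# categoricals
.truthDesign <- function(df, ranges, vocab) {
  cols <- list()
  for (f in names(ranges)) {
    r <- ranges[[f]]
    cols[[f]] <- (df[[f]] - mean(r)) / (diff(r) / 2)
  }
  m <- do.call(cbind, cols)
  for (f in names(vocab)) {
    oh <- outer(df[[f]], vocab[[f]], `==`) * 1
    colnames(oh) <- paste(f, vocab[[f]], sep = "=")
    m <- cbind(m, oh)
  }
  m
}

.rowSoftmax <- function(z) {
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

.makeTaxonomy <- function(nTaxa, nPhyla, seed) {
  withSeed(seed, {
    ids <- sprintf("OTU%04d", seq_len(nTaxa))
    phy <- sprintf("P%02d", sample.int(nPhyla, nTaxa, replace = TRUE))
    sub <- function(parent, k) paste0(parent, ".",
                                      sample.int(k, nTaxa, replace = TRUE))
    cls <- sub(phy, 2L); ord <- sub(cls, 2L)
    fam <- sub(ord, 2L); gen <- sub(fam, 2L)
    TaxonomyTable(data.frame(
      Kingdom = "Bacteria", Phylum = phy, Class = cls, Order = ord,
      Family = fam, Genus = gen, Species = ids, row.names = ids,
      stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic microbiome dataset
#'
#' Environmental features are drawn uniformly over their ranges
#' (categoricals uniformly over their levels); the true latent factors
#' are \code{tanh(affine(env)) + noise}; per-taxon logits are a linear
#' loading of the latent factors plus intercepts; proportions are the
#' row softmax of the logits; and observed counts are multinomial draws
#' of the configured depth from those proportions. The truth bundle
#' (mapping coefficients, latent factors, proportions) is returned for
#' oracle checks.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{abundance} (counts
#'   \linkS4class{AbundanceTable}), \code{taxonomy}
#'   (\linkS4class{TaxonomyTable}), \code{environment}
#'   (\linkS4class{EnvironmentTable}) and \code{truth} (list: design
#'   matrix, coefficients \code{B}, \code{b0}, loadings \code{W},
#'   intercepts \code{b}, \code{zTrue}, \code{proportions}).
#' @export
generateSyntheticDataset <- function(config = syntheticConfig()) {
  n <- config$nSamples; p <- config$nTaxa; d <- config$trueLatentDim
  ranges <- list(age = c(0, 20), temperature = c(50, 90), rain = c(0, 5))
  vocab <- list(line = paste0("L", 1:4), variety = paste0("V", 1:6))
  ids <- sprintf("S%05d", seq_len(n))
  env <- withSeed(config$seed + 1L, {
    df <- data.frame(
      age = runif(n, 0, 20), temperature = runif(n, 50, 90),
      rain = runif(n, 0, 5),
      line = sample(vocab$line, n, replace = TRUE),
      variety = sample(vocab$variety, n, replace = TRUE),
      row.names = ids, stringsAsFactors = FALSE)
    EnvironmentTable(df, units = c(age = "weeks", temperature = "degF",
                                   rain = "inches"))
  })
  M <- .truthDesign(environmentData(env), ranges, vocab)
  q <- ncol(M)
  maps <- withSeed(config$seed + 2L, {
    list(B = matrix(rnorm(q * d, sd = 1), q, d),
         b0 = rnorm(d, sd = 0.5),
         W = matrix(rnorm(d * p, sd = config$loadingScale), d, p),
         b = rnorm(p, sd = 1) +
           ifelse(seq_len(p) <= round(config$sparseFraction * p),
                  config$sparseShift, 0))
  })
  zTrue <- withSeed(config$seed + 3L, {
    tanh(sweep(M %*% maps$B, 2L, maps$b0, "+")) +
      matrix(rnorm(n * d, sd = config$latentNoiseSd), n, d)
  })
  logits <- sweep(zTrue %*% maps$W, 2L, maps$b, "+")
  props <- .rowSoftmax(logits)
  taxa <- sprintf("OTU%04d", seq_len(p))
  counts <- withSeed(config$seed + 4L, {
    vapply(seq_len(n), function(i)
      as.numeric(rmultinom(1L, config$depth, props[i, ])), numeric(p))
  })
  dimnames(counts) <- list(taxa, ids)
  propsT <- t(props)
  dimnames(propsT) <- dimnames(counts)
  list(abundance = AbundanceTable(counts, scale = "counts"),
       taxonomy = .makeTaxonomy(p, config$nPhyla, config$seed + 5L),
       environment = env,
       truth = list(design = M, B = maps$B, b0 = maps$b0, W = maps$W,
                    b = maps$b, zTrue = zTrue, proportions = propsT,
                    config = config))
}

#' Derive a small transfer dataset with alternative features
#'
#' Emulates a small study measuring entirely different covariates:
#' selects \code{n} samples (disjoint from \code{excludeIds}) and emits
#' three new feature columns — stand-ins for soil pH and nitrogen/carbon
#' concentration — as deterministic nonlinear functions of the true
#' latent factors plus noise, so the latent space remains recoverable
#' from them by construction.
#'
#' @param dataset output of \code{\link{generateSyntheticDataset}}.
#' @param n number of samples for the small dataset.
#' @param excludeIds sample ids that must not be reused (e.g. the source
#'   model's training ids).
#' @param noiseSd sd of the feature noise.
#' @param seed integer seed (default derives from the generator's).
#' @return list with \code{abundance}, \code{environment} (features pH,
#'   nitrogen, carbon) and \code{ids}.
#' @export
perturbForTransfer <- function(dataset, n = 100L, excludeIds = character(),
                               noiseSd = 0.05,
                               seed = dataset$truth$config$seed + 10L) {
  all <- sampleIds(dataset$abundance)
  pool <- setdiff(all, excludeIds)
  if (length(pool) < n)
    stop("only ", length(pool), " samples available outside excludeIds")
  withSeed(seed, {
    ids <- sort(sample(pool, n))
    z <- dataset$truth$zTrue[match(ids, all), , drop = FALSE]
    d <- ncol(z)
    z2 <- z[, min(2L, d)]; z3 <- z[, min(3L, d)]
    noise <- function() rnorm(n, sd = noiseSd)
    df <- data.frame(
      pH = 6.5 + 1.2 * tanh(z[, 1L] + 0.4 * z2) + noise(),
      nitrogen = 2 + 1.5 * stats::plogis(2 * (z2 - 0.5 * z3)) + noise(),
      carbon = 10 + 2 * z3 + 0.6 * z3^3 + noise(),
      row.names = ids, stringsAsFactors = FALSE)
    list(abundance = dataset$abundance[, ids],
         environment = EnvironmentTable(
           df, units = c(pH = "pH", nitrogen = "mg/kg", carbon = "mg/kg")),
         ids = ids)
  })
}
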