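# Autoencoder architectures, environment->latent predictor, assembly of
# the deployable prediction model, grid search with CV, persistence.

#' Architecture and training configuration
#'
#' Defaults follow the tuned reference configuration: latent size 10, one
#' hidden layer of 256 units, tanh activations, TSS normalization with
#' Bray-Curtis loss, learning rate 0.001, batch size 64, up to 100 epochs
#' with early-stopping patience 10 (Adam optimizer). The crossentropy and
#' Bray-Curtis losses act on simplex-valued outputs and are therefore
#' only valid under \code{normalization = "tss"} (simplex output head);
#' under \code{"tss_clr"} the head is linear and the loss must be MSE.
#'
#' @param latentDim latent space size (grid values 10/50/100).
#' @param hidden integer vector of hidden-layer widths; \code{c(512, 256)},
#'   \code{c(256)} or \code{integer()} in the grid.
#' @param activation encoder/decoder hidden activation: tanh/relu/sigmoid.
#' @param latentActivation latent-layer activation: tanh/sigmoid.
#' @param normalization \code{"tss"} or \code{"tss_clr"}.
#' @param pseudocount pseudocount for the CLR pathway.
#' @param loss \code{"mse"}, \code{"crossentropy"} or \code{"braycurtis"}.
#' @param learningRate Adam learning rate (grid 0.01/0.001).
#' @param batchSize mini-batch size (grid 64/128).
#' @param epochs maximum epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param alignWeight weight of the latent-alignment penalty in the
#'   combined autoencoder.
#' @param seed integer seed governing all randomness (init, shuffling).
#' @return a validated named list.
#' @export
architectureConfig <- function(latentDim = 10L, hidden = c(256L),
                               activation = "tanh",
                               latentActivation = "tanh",
                               normalization = "tss", pseudocount = 1,
                               loss = "braycurtis", learningRate = 0.001,
                               batchSize = 64L, epochs = 100L,
                               patience = 10L, alignWeight = 1,
                               seed = 1L) {
  activation <- match.arg(activation, c("tanh", "relu", "sigmoid"))
  latentActivation <- match.arg(latentActivation, c("tanh", "sigmoid"))
  normalization <- match.arg(normalization, c("tss", "tss_clr"))
  loss <- match.arg(loss, c("mse", "crossentropy", "braycurtis"))
  if (loss != "mse" && normalization != "tss")
    stop("loss '", loss, "' requires simplex predictions; use ",
         "normalization = 'tss' (configuration error)")
  stopifnot(latentDim >= 1, alignWeight >= 0, learningRate > 0,
            batchSize >= 1, epochs >= 0, patience >= 1)
  list(latentDim = as.integer(latentDim), hidden = as.integer(hidden),
       activation = activation, latentActivation = latentActivation,
       normalization = normalization, pseudocount = pseudocount,
       loss = loss, learningRate = learningRate,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       patience = as.integer(patience), alignWeight = alignWeight,
       seed = as.integer(seed))
}

#' Enumerate the hyperparameter grid
#'
#' Crosses the declared value sets (1296 raw cells for the default sets)
#' and, when \code{filterInvalid}, drops the loss/normalization pairs that
#' are not representable (crossentropy or Bray-Curtis under CLR).
#'
#' @param latentDims,hiddens,activations,latentActivations,normalizations,losses,learningRates,batchSizes
#'   value sets; defaults are the declared grid.
#' @param filterInvalid drop invalid loss x normalization combinations.
#' @param ... fixed fields passed to every \code{\link{architectureConfig}}
#'   (e.g. \code{epochs}, \code{seed}).
#' @return list of configs.
#' @export
enumerateGrid <- function(latentDims = c(10L, 50L, 100L),
                          hiddens = list(c(512L, 256L), c(256L), integer()),
                          activations = c("tanh", "relu", "sigmoid"),
                          latentActivations = c("tanh", "sigmoid"),
                          normalizations = c("tss", "tss_clr"),
                          losses = c("mse", "crossentropy", "braycurtis"),
                          learningRates = c(0.01, 0.001),
                          batchSizes = c(64L, 128L),
                          filterInvalid = TRUE, ...) {
  cells <- expand.grid(ld = seq_along(latentDims), hi = seq_along(hiddens),
                       ac = seq_along(activations),
                       la = seq_along(latentActivations),
                       no = seq_along(normalizations),
                       lo = seq_along(losses),
                       lr = seq_along(learningRates),
                       bs = seq_along(batchSizes))
  out <- vector("list", nrow(cells))
  keep <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, ]
    valid <- losses[r$lo] == "mse" || normalizations[r$no] == "tss"
    keep[i] <- valid || !filterInvalid
    if (!keep[i]) next
    if (valid) {
      out[[i]] <- architectureConfig(
        latentDim = latentDims[r$ld], hidden = hiddens[[r$hi]],
        activation = activations[r$ac],
        latentActivation = latentActivations[r$la],
        normalization = normalizations[r$no], loss = losses[r$lo],
        learningRate = learningRates[r$lr], batchSize = batchSizes[r$bs],
        ...)
    } else {
      # raw cell kept for enumeration only; not constructible as a
      # validated config
      out[[i]] <- list(latentDim = latentDims[r$ld],
                       hidden = hiddens[[r$hi]],
                       activation = activations[r$ac],
                       latentActivation = latentActivations[r$la],
                       normalization = normalizations[r$no],
                       loss = losses[r$lo],
                       learningRate = learningRates[r$lr],
                       batchSize = batchSizes[r$bs], valid = FALSE)
    }
  }
  out[keep]
}

# counts table -> samples x taxa matrix on the configured training scale
.modelMatrix <- function(table, state) {
  stopifnot(abundanceScale(table) == "counts")
  if (state@method == "tss") t(abundanceValues(tssNormalize(table)))
  else t(abundanceValues(clrTransform(table, state@pseudocount)))
}

.normState <- function(cfg) {
  NormalizationState(method = cfg$normalization,
                     pseudocount = cfg$pseudocount)
}

.headAct <- function(cfg) {
  if (cfg$normalization == "tss") "softmax" else "linear"
}

#' Train the OTU autoencoder
#'
#' Architecture A: OTU composition -> encoder -> latent -> decoder ->
#' composition. Mini-batch Adam on the configured reconstruction loss
#' with early stopping on validation loss; per-epoch history recorded.
#' Counts are normalized internally per \code{cfg$normalization}.
#'
#' @param train,val counts-scale \linkS4class{AbundanceTable}s (same taxa).
#' @param cfg an \code{\link{architectureConfig}}.
#' @return A \linkS4class{TrainedAE} (no environmental encoder).
#' @export
trainOtuAutoencoder <- function(train, val, cfg = architectureConfig()) {
  state <- .normState(cfg)
  X <- .modelMatrix(train, state)
  Xv <- .modelMatrix(val, state)
  p <- ncol(X)
  withSeed(cfg$seed, {
    nets <- list(enc = .nnNew(p, cfg$hidden, cfg$latentDim,
                              cfg$activation, cfg$latentActivation),
                 dec = .nnNew(cfg$latentDim, rev(cfg$hidden), p,
                              cfg$activation, .headAct(cfg)))
    nets$stE <- .adamNew(nets$enc); nets$stD <- .adamNew(nets$dec)
    stepFn <- function(nets, idx) {
      Xb <- X[idx, , drop = FALSE]
      fe <- .nnForward(nets$enc, Xb)
      fd <- .nnForward(nets$dec, fe$out)
      lg <- .lossAndGrad(cfg$loss, fd$out, Xb)
      bd <- .nnBackward(nets$dec, fd, lg$grad)
      be <- .nnBackward(nets$enc, fe, bd$dInput)
      up <- .adamStep(nets$dec, bd, nets$stD, cfg$learningRate)
      nets$dec <- up$net; nets$stD <- up$st
      up <- .adamStep(nets$enc, be, nets$stE, cfg$learningRate)
      nets$enc <- up$net; nets$stE <- up$st
      list(nets = nets, loss = lg$value)
    }
    valFn <- function(nets) {
      out <- .nnForward(nets$dec, .nnForward(nets$enc, Xv)$out)$out
      .lossAndGrad(cfg$loss, out, Xv)$value
    }
    fit <- .trainDriver(nets, nrow(X), cfg, stepFn, valFn)
    new("TrainedAE", otuEncoder = fit$nets$enc, envEncoder = list(),
        decoder = fit$nets$dec, config = cfg, normalization = state,
        schema = NULL, history = fit$history, taxonIds = taxonIds(train))
  })
}

#' Train the combined (heterogeneous) autoencoder
#'
#' Architecture B: an OTU encoder and an environmental encoder share one
#' decoder. The total loss is the reconstruction loss from the OTU latent
#' plus the reconstruction loss from the environmental latent plus
#' \code{alignWeight} times the mean squared distance between the two
#' latent codes, which forces the two latent spaces to be similar. Both
#' reconstruction paths propagate gradients into the shared decoder.
#'
#' @param trainOtu,valOtu counts-scale \linkS4class{AbundanceTable}s.
#' @param trainEnv,valEnv paired \linkS4class{EnvironmentTable}s (sample
#'   order must match the abundance tables).
#' @param cfg an \code{\link{architectureConfig}}.
#' @param features optional environmental feature subset.
#' @return A \linkS4class{TrainedAE} with both encoders and the fitted
#'   \linkS4class{EncodingSchema}.
#' @export
trainCombinedAutoencoder <- function(trainOtu, trainEnv, valOtu, valEnv,
                                     cfg = architectureConfig(),
                                     features = NULL) {
  stopifnot(identical(sampleIds(trainOtu), sampleIds(trainEnv)),
            identical(sampleIds(valOtu), sampleIds(valEnv)))
  state <- .normState(cfg)
  X <- .modelMatrix(trainOtu, state)
  Xv <- .modelMatrix(valOtu, state)
  encTrain <- encodeEnvironment(trainEnv, features = features)
  E <- encTrain$matrix
  Ev <- encodeEnvironment(valEnv, schema = encTrain$schema)$matrix
  p <- ncol(X); q <- ncol(E); w <- cfg$alignWeight
  withSeed(cfg$seed, {
    nets <- list(encO = .nnNew(p, cfg$hidden, cfg$latentDim,
                               cfg$activation, cfg$latentActivation),
                 encE = .nnNew(q, cfg$hidden, cfg$latentDim,
                               cfg$activation, cfg$latentActivation),
                 dec = .nnNew(cfg$latentDim, rev(cfg$hidden), p,
                              cfg$activation, .headAct(cfg)))
    nets$stO <- .adamNew(nets$encO); nets$stEv <- .adamNew(nets$encE)
    nets$stD <- .adamNew(nets$dec)
    totalLoss <- function(nets, Xm, Em) {
      zo <- .nnForward(nets$encO, Xm)$out
      ze <- .nnForward(nets$encE, Em)$out
      lo <- .lossAndGrad(cfg$loss, .nnForward(nets$dec, zo)$out, Xm)$value
      le <- .lossAndGrad(cfg$loss, .nnForward(nets$dec, ze)$out, Xm)$value
      lo + le + w * mean((zo - ze)^2)
    }
    stepFn <- function(nets, idx) {
      Xb <- X[idx, , drop = FALSE]; Eb <- E[idx, , drop = FALSE]
      fo <- .nnForward(nets$encO, Xb); fe <- .nnForward(nets$encE, Eb)
      zo <- fo$out; ze <- fe$out
      do_ <- .nnForward(nets$dec, zo); de_ <- .nnForward(nets$dec, ze)
      lo <- .lossAndGrad(cfg$loss, do_$out, Xb)
      le <- .lossAndGrad(cfg$loss, de_$out, Xb)
      D <- zo - ze
      alignVal <- mean(D^2)
      gAlign <- 2 * D / length(D)
      bo <- .nnBackward(nets$dec, do_, lo$grad)
      be <- .nnBackward(nets$dec, de_, le$grad)
      gdec <- .addGrads(bo, be)  # shared decoder sees both paths
      go <- .nnBackward(nets$encO, fo, bo$dInput + w * gAlign)
      ge <- .nnBackward(nets$encE, fe, be$dInput - w * gAlign)
      up <- .adamStep(nets$dec, gdec, nets$stD, cfg$learningRate)
      nets$dec <- up$net; nets$stD <- up$st
      up <- .adamStep(nets$encO, go, nets$stO, cfg$learningRate)
      nets$encO <- up$net; nets$stO <- up$st
      up <- .adamStep(nets$encE, ge, nets$stEv, cfg$learningRate)
      nets$encE <- up$net; nets$stEv <- up$st
      list(nets = nets,
           loss = lo$value + le$value + w * alignVal,
           align = alignVal)
    }
    alignTrace <- numeric()
    stepFnTraced <- function(nets, idx) {
      r <- stepFn(nets, idx)
      alignTrace[length(alignTrace) + 1L] <<- r$align
      r
    }
    valFn <- function(nets) totalLoss(nets, Xv, Ev)
    fit <- .trainDriver(nets, nrow(X), cfg, stepFnTraced, valFn)
    if (nrow(fit$history)) {
      perEpoch <- ceiling(length(alignTrace) / nrow(fit$history))
      fit$history$align <- vapply(seq_len(nrow(fit$history)), function(e) {
        i <- ((e - 1L) * perEpoch + 1L):min(e * perEpoch, length(alignTrace))
        mean(alignTrace[i])
      }, numeric(1))
    }
    new("TrainedAE", otuEncoder = fit$nets$encO,
        envEncoder = fit$nets$encE, decoder = fit$nets$dec, config = cfg,
        normalization = state, schema = encTrain$schema,
        history = fit$history, taxonIds = taxonIds(trainOtu))
  })
}

#' Latent codes of compositions under a trained OTU encoder
#'
#' @param ae a \linkS4class{TrainedAE}.
#' @param table a counts-scale \linkS4class{AbundanceTable} with the
#'   encoder's taxa.
#' @return samples x latentDim matrix of codes.
#' @export
latentCodes <- function(ae, table) {
  stopifnot(is(ae, "TrainedAE"))
  if (!identical(taxonIds(table), ae@taxonIds))
    stop("taxa do not match the encoder's input taxa")
  X <- .modelMatrix(table, ae@normalization)
  z <- .nnForward(ae@otuEncoder, X)$out
  rownames(z) <- sampleIds(table)
  z
}

#' Reconstruct compositions through a trained autoencoder
#'
#' Encodes compositions to the latent space and decodes them back,
#' returning relative abundances — the round trip whose fidelity measures
#' how much of the community structure the latent space retains.
#'
#' @param ae a \linkS4class{TrainedAE}.
#' @param table a counts-scale \linkS4class{AbundanceTable}.
#' @return An \linkS4class{AbundanceTable} (\code{tss}).
#' @export
reconstructComposition <- function(ae, table) {
  z <- latentCodes(ae, table)
  out <- t(.nnForward(ae@decoder, z)$out)
  dimnames(out) <- list(ae@taxonIds, sampleIds(table))
  inverseToRelative(out, ae@normalization)
}

#' @rdname latentCodes
#' @param env an \linkS4class{EnvironmentTable}; requires an autoencoder
#'   trained with an environmental encoder.
#' @export
envLatentCodes <- function(ae, env) {
  stopifnot(is(ae, "TrainedAE"))
  if (!length(ae@envEncoder))
    stop("this autoencoder has no environmental encoder")
  E <- encodeEnvironment(env, schema = ae@schema)$matrix
  z <- .nnForward(ae@envEncoder, E)$out
  rownames(z) <- sampleIds(env)
  z
}

#' Train the environment-to-latent predictor
#'
#' A feed-forward regressor (same hidden-layer family as the
#' autoencoders, output activation matching the latent layer) fit by MSE
#' against the OTU-encoder codes of the training samples.
#'
#' @param envMatrix encoded samples x features matrix (training rows).
#' @param latentTargets samples x latentDim matrix of codes.
#' @param cfg an \code{\link{architectureConfig}}.
#' @param valEnvMatrix,valTargets optional validation pair for early
#'   stopping; defaults to a seeded 10\% split of the training rows.
#' @details The regressor's output layer is linear: latent codes live
#'   inside the latent activation's range, so a linear head can always
#'   reach them, while a saturating head could not represent targets
#'   near its asymptotes.
#' @return internal predictor network (list), with the training history
#'   as attribute \code{history}.
#' @export
trainLatentPredictor <- function(envMatrix, latentTargets,
                                 cfg = architectureConfig(),
                                 valEnvMatrix = NULL, valTargets = NULL) {
  envMatrix <- as.matrix(envMatrix)
  latentTargets <- as.matrix(latentTargets)
  if (nrow(envMatrix) != nrow(latentTargets))
    stop("envMatrix and latentTargets disagree on sample count")
  withSeed(cfg$seed + 1L, {
    if (is.null(valEnvMatrix)) {
      n <- nrow(envMatrix)
      vi <- sample.int(n, max(1L, round(0.1 * n)))
      valEnvMatrix <- envMatrix[vi, , drop = FALSE]
      valTargets <- latentTargets[vi, , drop = FALSE]
      envMatrix <- envMatrix[-vi, , drop = FALSE]
      latentTargets <- latentTargets[-vi, , drop = FALSE]
    }
    net <- .nnNew(ncol(envMatrix), cfg$hidden, ncol(latentTargets),
                  cfg$activation, "linear")
    nets <- list(net = net, st = .adamNew(net))
    stepFn <- function(nets, idx) {
      Eb <- envMatrix[idx, , drop = FALSE]
      Zb <- latentTargets[idx, , drop = FALSE]
      fw <- .nnForward(nets$net, Eb)
      lg <- .lossAndGrad("mse", fw$out, Zb)
      bk <- .nnBackward(nets$net, fw, lg$grad)
      up <- .adamStep(nets$net, bk, nets$st, cfg$learningRate)
      nets$net <- up$net; nets$st <- up$st
      list(nets = nets, loss = lg$value)
    }
    valFn <- function(nets)
      .lossAndGrad("mse", .nnForward(nets$net, valEnvMatrix)$out,
                   valTargets)$value
    fit <- .trainDriver(nets, nrow(envMatrix), cfg, stepFn, valFn)
    structure(fit$nets$net, history = fit$history)
  })
}

#' Assemble the deployable prediction model
#'
#' Final architecture C: environmental features -> latent -> (frozen)
#' decoder -> relative abundances. In \code{otu_latent} mode the latent
#' comes from a dedicated predictor trained on OTU-encoder codes; in
#' \code{combined} mode the trained environmental encoder itself is the
#' predictor.
#'
#' @param ae a \linkS4class{TrainedAE}.
#' @param mode \code{"otu_latent"} or \code{"combined"}.
#' @param predictor predictor network from
#'   \code{\link{trainLatentPredictor}} (otu_latent mode).
#' @param schema \linkS4class{EncodingSchema} the predictor's input was
#'   encoded with (otu_latent mode).
#' @return A \linkS4class{PredictionModel}.
#' @export
assemblePredictionModel <- function(ae, mode = c("otu_latent", "combined"),
                                    predictor = NULL, schema = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(ae, "TrainedAE"))
  if (mode == "otu_latent") {
    if (is.null(predictor))
      stop("otu_latent mode requires a trained latent predictor")
    if (is.null(schema))
      stop("otu_latent mode requires the predictor's encoding schema")
  } else {
    if (!length(ae@envEncoder))
      stop("combined mode requires an autoencoder trained with an ",
           "environmental encoder")
    predictor <- ae@envEncoder
    schema <- ae@schema
  }
  attributes(predictor)[setdiff(names(attributes(predictor)),
                                "names")] <- NULL
  new("PredictionModel", predictor = predictor, decoder = ae@decoder,
      mode = mode, schema = schema, normalization = ae@normalization,
      features = schema@features, frozen = TRUE, taxonIds = ae@taxonIds)
}

#' Predict microbial composition from environmental features
#'
#' Runs env -> latent -> decoder and maps the output back to the
#' relative-abundance scale, so every predicted sample is a simplex
#' vector.
#'
#' @param model a \linkS4class{PredictionModel}.
#' @param env an \linkS4class{EnvironmentTable} (or pre-encoded matrix).
#' @return An \linkS4class{AbundanceTable} (\code{tss}), taxa x samples.
#' @export
predictComposition <- function(model, env) {
  stopifnot(is(model, "PredictionModel"))
  if (is(env, "EnvironmentTable")) {
    ids <- sampleIds(env)
    E <- encodeEnvironment(env, schema = model@schema)$matrix
  } else {
    E <- as.matrix(env)
    ids <- rownames(E)
    if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(E)))
  }
  z <- .nnForward(model@predictor, E)$out
  out <- t(.nnForward(model@decoder, z)$out)
  dimnames(out) <- list(model@taxonIds, ids)
  inverseToRelative(out, model@normalization)
}

#' @describeIn predictComposition \code{predict} method delegating to
#'   \code{predictComposition}.
#' @param object a \linkS4class{PredictionModel}.
#' @param ... passed on (first argument: \code{env}).
#' @export
setMethod("predict", "PredictionModel", function(object, ...)
  predictComposition(object, ...))

#' Hyperparameter grid search with k-fold cross-validation
#'
#' For every configuration and CV fold: the autoencoder is trained on the
#' fold's fit samples (an internal seeded 90/10 split of those samples
#' drives early stopping, so fold-validation samples never touch AE
#' training), the assembled prediction model is evaluated on the fold's
#' validation samples, and per-config mean CV Pearson (per-sample) and
#' Bray-Curtis are averaged. Configurations are ranked by descending
#' Pearson with ties broken by ascending Bray-Curtis.
#'
#' @param counts counts-scale \linkS4class{AbundanceTable}.
#' @param env paired \linkS4class{EnvironmentTable}.
#' @param grid list of \code{\link{architectureConfig}}s.
#' @param split a \linkS4class{SplitIndices} providing the folds.
#' @param mode assembly mode (see
#'   \code{\link{assemblePredictionModel}}).
#' @param features optional environmental feature subset.
#' @return data.frame ranked best-first, one row per config, with the
#'   config list stored in attribute \code{configs} (in ranked order).
#' @export
gridSearch <- function(counts, env, grid, split,
                       mode = c("otu_latent", "combined"),
                       features = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(grid) >= 1, is(split, "SplitIndices"))
  rows <- lapply(seq_along(grid), function(ci) {
    cfg <- grid[[ci]]
    pe <- bc <- numeric(length(split@cvFolds))
    for (fi in seq_along(split@cvFolds)) {
      fold <- split@cvFolds[[fi]]
      fitIds <- fold$fit; valIds <- fold$val
      esIdx <- withSeed(cfg$seed + fi, {
        sample.int(length(fitIds), max(1L, round(0.1 * length(fitIds))))
      })
      esIds <- fitIds[esIdx]; coreIds <- fitIds[-esIdx]
      model <- fitPredictionPipeline(
        counts[, coreIds], env[coreIds, ], counts[, esIds], env[esIds, ],
        cfg, mode = mode, features = features)
      pred <- predictComposition(model, env[valIds, ])
      actual <- tssNormalize(counts[, valIds])
      rep <- evaluateComposition(pred, actual)
      pe[fi] <- pearsonMean(rep); bc[fi] <- brayCurtisMean(rep)
    }
    data.frame(config_id = ci, latentDim = cfg$latentDim,
               hidden = paste(cfg$hidden, collapse = "x"),
               activation = cfg$activation,
               latentActivation = cfg$latentActivation,
               normalization = cfg$normalization, loss = cfg$loss,
               learningRate = cfg$learningRate, batchSize = cfg$batchSize,
               pearson = mean(pe), braycurtis = mean(bc),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$pearson, tab$braycurtis)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, configs = grid[tab$config_id])
}

# The latent predictor regresses a handful of outputs, so its epochs are
# cheap and its validation loss is noisy early on: give it a longer
# schedule than the autoencoder it feeds on.
.predictorConfig <- function(cfg) {
  cfg$epochs <- max(cfg$epochs, 300L)
  cfg$patience <- max(cfg$patience, 30L)
  cfg
}

#' Fit the full environment-to-composition pipeline
#'
#' Convenience driver used by grid search, the CLI and the worked
#' examples: trains the appropriate autoencoder on the training tables
#' (validation tables drive early stopping), trains the latent predictor
#' when in \code{otu_latent} mode, and assembles the prediction model.
#'
#' @param trainOtu,valOtu counts-scale \linkS4class{AbundanceTable}s.
#' @param trainEnv,valEnv paired \linkS4class{EnvironmentTable}s.
#' @param cfg an \code{\link{architectureConfig}}.
#' @param mode \code{"otu_latent"} or \code{"combined"}.
#' @param features optional environmental feature subset.
#' @param returnAE also return the trained autoencoder.
#' @return A \linkS4class{PredictionModel}, or (with \code{returnAE})
#'   a list \code{list(model, ae)}.
#' @export
fitPredictionPipeline <- function(trainOtu, trainEnv, valOtu, valEnv,
                                  cfg = architectureConfig(),
                                  mode = c("otu_latent", "combined"),
                                  features = NULL, returnAE = FALSE) {
  mode <- match.arg(mode)
  if (mode == "combined") {
    ae <- trainCombinedAutoencoder(trainOtu, trainEnv, valOtu, valEnv,
                                   cfg, features = features)
    model <- assemblePredictionModel(ae, "combined")
  } else {
    ae <- trainOtuAutoencoder(trainOtu, valOtu, cfg)
    enc <- encodeEnvironment(trainEnv, features = features)
    z <- latentCodes(ae, trainOtu)
    zv <- latentCodes(ae, valOtu)
    Ev <- encodeEnvironment(valEnv, schema = enc$schema)$matrix
    pred <- trainLatentPredictor(enc$matrix, z, .predictorConfig(cfg),
                                 valEnvMatrix = Ev, valTargets = zv)
    model <- assemblePredictionModel(ae, "otu_latent", predictor = pred,
                                     schema = enc$schema)
  }
  if (returnAE) list(model = model, ae = ae) else model
}

# ---- persistence -------------------------------------------------------

.writeMatrixExact <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(matrix(sprintf("%.17g", m), nrow(m)), 1L,
                   paste, collapse = "\t"), con)
}

.readMatrixExact <- function(path) {
  m <- as.matrix(read.delim(path, header = FALSE))
  dimnames(m) <- NULL
  m
}

.writeNet <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(sizes = net$sizes, acts = net$acts),
                       file.path(dir, "meta.json"))
  for (l in seq_along(net$W)) {
    .writeMatrixExact(net$W[[l]], file.path(dir, sprintf("W%d.tsv", l)))
    .writeMatrixExact(matrix(net$b[[l]], nrow = 1L),
                      file.path(dir, sprintf("b%d.tsv", l)))
  }
}

.readNet <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  L <- length(meta$acts)
  W <- b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- .readMatrixExact(file.path(dir, sprintf("W%d.tsv", l)))
    b[[l]] <- as.numeric(.readMatrixExact(file.path(dir,
                                                    sprintf("b%d.tsv", l))))
  }
  list(W = W, b = b, acts = meta$acts, sizes = meta$sizes)
}

.schemaToList <- function(schema) {
  fmt <- function(x) setNames(sprintf("%.17g", x), names(x))
  list(features = schema@features, kinds = as.list(schema@kinds),
       centers = as.list(fmt(schema@centers)),
       scales = as.list(fmt(schema@scales)),
       mins = as.list(fmt(schema@mins)), maxs = as.list(fmt(schema@maxs)),
       levels = schema@levels, units = as.list(schema@units))
}

.schemaFromList <- function(x) {
  num <- function(v) setNames(as.numeric(unlist(v)),
                              names(v))
  chr <- function(v) setNames(as.character(unlist(v)), names(v))
  lv <- lapply(x$levels, function(v) as.character(unlist(v)))
  new("EncodingSchema", features = as.character(unlist(x$features)),
      kinds = chr(x$kinds), centers = num(x$centers),
      scales = num(x$scales), mins = num(x$mins), maxs = num(x$maxs),
      levels = lv,
      units = if (length(x$units)) chr(x$units) else character())
}

#' Persist a model bundle to a directory of plain-text files
#'
#' Network parameters are written with full double precision, so a saved
#' and reloaded model produces bit-identical predictions. Works for
#' \linkS4class{PredictionModel} and \linkS4class{TrainedAE}.
#'
#' @param model the model to save.
#' @param dir target directory (created).
#' @return \code{dir}, invisibly.
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is(model, "PredictionModel")) {
    meta <- list(class = "PredictionModel", mode = model@mode,
                 features = model@features, frozen = model@frozen,
                 taxon_ids = model@taxonIds,
                 normalization = list(
                   method = model@normalization@method,
                   pseudocount = sprintf("%.17g",
                                         model@normalization@pseudocount)),
                 schema = .schemaToList(model@schema))
    jsonlite::write_json(meta, file.path(dir, "model.json"),
                         auto_unbox = TRUE)
    .writeNet(model@predictor, file.path(dir, "predictor"))
    .writeNet(model@decoder, file.path(dir, "decoder"))
  } else if (is(model, "TrainedAE")) {
    meta <- list(class = "TrainedAE", taxon_ids = model@taxonIds,
                 config = model@config,
                 normalization = list(
                   method = model@normalization@method,
                   pseudocount = sprintf("%.17g",
                                         model@normalization@pseudocount)),
                 schema = if (is.null(model@schema)) NULL
                          else .schemaToList(model@schema))
    jsonlite::write_json(meta, file.path(dir, "model.json"),
                         auto_unbox = TRUE)
    .writeNet(model@otuEncoder, file.path(dir, "otu_encoder"))
    if (length(model@envEncoder))
      .writeNet(model@envEncoder, file.path(dir, "env_encoder"))
    .writeNet(model@decoder, file.path(dir, "decoder"))
    write.table(model@history, file.path(dir, "history.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else stop("cannot save objects of class ", class(model))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = FALSE)
  norm <- NormalizationState(method = meta$normalization$method,
                             pseudocount =
                               as.numeric(meta$normalization$pseudocount))
  if (meta$class == "PredictionModel") {
    new("PredictionModel",
        predictor = .readNet(file.path(dir, "predictor")),
        decoder = .readNet(file.path(dir, "decoder")),
        mode = meta$mode, schema = .schemaFromList(meta$schema),
        normalization = norm,
        features = as.character(unlist(meta$features)),
        frozen = isTRUE(meta$frozen),
        taxonIds = as.character(unlist(meta$taxon_ids)))
  } else {
    cfg <- meta$config
    cfg$hidden <- as.integer(unlist(cfg$hidden))
    cfg <- do.call(architectureConfig, cfg)
    hp <- file.path(dir, "history.tsv")
    hist <- if (file.exists(hp) && length(readLines(hp)) > 1L)
      read.delim(hp) else data.frame()
    envDir <- file.path(dir, "env_encoder")
    new("TrainedAE",
        otuEncoder = .readNet(file.path(dir, "otu_encoder")),
        envEncoder = if (dir.exists(envDir)) .readNet(envDir) else list(),
        decoder = .readNet(file.path(dir, "decoder")), config = cfg,
        normalization = norm,
        schema = if (is.null(meta$schema)) NULL
                 else .schemaFromList(meta$schema),
        history = hist,
        taxonIds = as.character(unlist(meta$taxon_ids)))
  }
}

#' Digest of a network's parameters
#'
#' MD5 of the full-precision serialized weights; used to assert that a
#' frozen decoder is bit-identical before and after downstream training.
#'
#' @param net an internal network list, or a
#'   \linkS4class{PredictionModel}/\linkS4class{TrainedAE} whose decoder
#'   is digested.
#' @return a character MD5 digest.
#' @export
parameterDigest <- function(net) {
  if (is(net, "PredictionModel") || is(net, "TrainedAE")) net <- net@decoder
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(sprintf("%.17g", unlist(net$W)),
               sprintf("%.17g", unlist(net$b))), tmp)
  unname(tools::md5sum(tmp))
}
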