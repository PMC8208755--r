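# Reference predictors: default per-taxon mean, multi-output linear
# regression, multi-layer perceptron (no latent space, no autoencoder).

#' Default (mean) baseline predictor
#'
#' Stores the per-taxon mean relative abundance over the training
#' samples, re-closed to sum one, and returns it for every input sample
#' regardless of the features. Its per-taxon RRSE on the set defining the
#' mean is exactly 1 by construction.
#'
#' @param train a \code{tss}-scale \linkS4class{AbundanceTable}.
#' @return A \linkS4class{BaselineModel} of kind \code{"default"}.
#' @export
fitDefaultBaseline <- function(train) {
  stopifnot(is(train, "AbundanceTable"))
  if (abundanceScale(train) != "tss")
    stop("default baseline is defined on the tss scale")
  mu <- rowMeans(abundanceValues(train))
  mu <- mu / sum(mu)
  new("BaselineModel", kind = "default", fit = list(mean = mu),
      schema = NULL, normalization = NormalizationState("tss"),
      taxonIds = taxonIds(train))
}

#' Multi-output linear regression baseline
#'
#' Independent least squares per taxon (one multi-output solve) on the
#' configured normalization scale; predictions are mapped back through
#' \code{\link{inverseToRelative}}. A rank-deficient design falls back to
#' the least-norm solution (Moore-Penrose pseudoinverse) with a warning.
#'
#' @param env training \linkS4class{EnvironmentTable}.
#' @param target counts-scale \linkS4class{AbundanceTable} (paired).
#' @param state \linkS4class{NormalizationState} choosing the training
#'   scale.
#' @param features optional feature subset.
#' @return A \linkS4class{BaselineModel} of kind \code{"linear"}.
#' @export
fitLinearBaseline <- function(env, target, state = NormalizationState(),
                              features = NULL) {
  enc <- encodeEnvironment(env, features = features)
  X <- cbind(`(Intercept)` = 1, enc$matrix)
  Y <- .modelMatrix(target, state)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient design; using least-norm solution")
    B <- MASS::ginv(X) %*% Y
  } else {
    B <- qr.coef(qrX, Y)
  }
  rownames(B) <- colnames(X)
  new("BaselineModel", kind = "linear",
      fit = list(coef = B), schema = enc$schema, normalization = state,
      taxonIds = taxonIds(target))
}

#' Multi-layer perceptron baseline
#'
#' A feed-forward network mapping environmental features directly to the
#' full composition — no bottleneck, no autoencoder — trained with the
#' same conventions (losses, optimizer, early stopping, output head) as
#' the latent-space models. With \code{hidden = integer()} its function
#' class reduces to the linear baseline's.
#'
#' @param env,target,features as in \code{\link{fitLinearBaseline}}.
#' @param valEnv,valTarget validation pair for early stopping.
#' @param cfg an \code{\link{architectureConfig}}; \code{hidden} defaults
#'   to the largest grid entry \code{c(512, 256)} for this baseline.
#' @return A \linkS4class{BaselineModel} of kind \code{"mlp"}.
#' @export
fitMlpBaseline <- function(env, target, valEnv, valTarget,
                           cfg = architectureConfig(hidden = c(512L, 256L)),
                           features = NULL) {
  state <- .normState(cfg)
  enc <- encodeEnvironment(env, features = features)
  E <- enc$matrix
  Ev <- encodeEnvironment(valEnv, schema = enc$schema)$matrix
  Y <- .modelMatrix(target, state)
  Yv <- .modelMatrix(valTarget, state)
  withSeed(cfg$seed, {
    net <- .nnNew(ncol(E), cfg$hidden, ncol(Y), cfg$activation,
                  .headAct(cfg))
    nets <- list(net = net, st = .adamNew(net))
    stepFn <- function(nets, idx) {
      fw <- .nnForward(nets$net, E[idx, , drop = FALSE])
      lg <- .lossAndGrad(cfg$loss, fw$out, Y[idx, , drop = FALSE])
      bk <- .nnBackward(nets$net, fw, lg$grad)
      up <- .adamStep(nets$net, bk, nets$st, cfg$learningRate)
      nets$net <- up$net; nets$st <- up$st
      list(nets = nets, loss = lg$value)
    }
    valFn <- function(nets)
      .lossAndGrad(cfg$loss, .nnForward(nets$net, Ev)$out, Yv)$value
    fit <- .trainDriver(nets, nrow(E), cfg, stepFn, valFn)
    new("BaselineModel", kind = "mlp",
        fit = list(net = fit$nets$net, history = fit$history),
        schema = enc$schema, normalization = state,
        taxonIds = taxonIds(target))
  })
}

#' Predict with a baseline model
#'
#' All baselines emit simplex predictions: outputs are mapped through
#' \code{\link{inverseToRelative}}.
#'
#' @param model a \linkS4class{BaselineModel}.
#' @param env an \linkS4class{EnvironmentTable}.
#' @return An \linkS4class{AbundanceTable} (\code{tss}).
#' @export
predictBaseline <- function(model, env) {
  stopifnot(is(model, "BaselineModel"), is(env, "EnvironmentTable"))
  ids <- sampleIds(env)
  out <- switch(model@kind,
    default = matrix(model@fit$mean, nrow = length(model@taxonIds),
                     ncol = length(ids)),
    linear = {
      E <- cbind(1, encodeEnvironment(env, schema = model@schema)$matrix)
      t(E %*% model@fit$coef)
    },
    mlp = {
      E <- encodeEnvironment(env, schema = model@schema)$matrix
      t(.nnForward(model@fit$net, E)$out)
    })
  dimnames(out) <- list(model@taxonIds, ids)
  inverseToRelative(out, model@normalization)
}

#' @describeIn predictBaseline \code{predict} method delegating to
#'   \code{predictBaseline}.
#' @param object a \linkS4class{BaselineModel}.
#' @param ... passed on (first argument: \code{env}).
#' @export
setMethod("predict", "BaselineModel", function(object, ...)
  predictBaseline(object, ...))
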