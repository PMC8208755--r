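# Compact feed-forward network engine: dense layers on base-R BLAS
# matmuls, analytic backprop, Adam, early stopping. Data layout inside
# the engine is samples x features.

.actForward <- function(z, act) {
  switch(act,
    tanh = tanh(z),
    relu = pmax(z, 0),
    sigmoid = stats::plogis(z),
    linear = z,
    softmax = {
      e <- exp(z - apply(z, 1L, max))
      e / rowSums(e)
    },
    stop("unknown activation: ", act))
}

# dL/dz given dL/da; `a` is the activation output, `z` the pre-activation
.actBackward <- function(g, a, z, act) {
  switch(act,
    tanh = g * (1 - a^2),
    relu = g * (z > 0),
    sigmoid = g * a * (1 - a),
    linear = g,
    softmax = a * (g - rowSums(g * a)),  # full softmax Jacobian product
    stop("unknown activation: ", act))
}

# Glorot-uniform initialization; draws from the current RNG stream.
.nnNew <- function(inDim, hidden, outDim, hiddenAct, outAct) {
  sizes <- c(inDim, hidden, outDim)
  acts <- c(rep(hiddenAct, length(hidden)), outAct)
  W <- b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b, acts = acts, sizes = sizes)
}

.nnForward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    A[[l + 1L]] <- .actForward(Z[[l]], net$acts[l])
  }
  list(out = A[[L + 1L]], A = A, Z = Z)
}

# G = dL/d(out). Returns parameter gradients and dL/d(input).
.nnBackward <- function(net, fw, G) {
  L <- length(net$W)
  dW <- db <- vector("list", L)
  delta <- .actBackward(G, fw$A[[L + 1L]], fw$Z[[L]], net$acts[L])
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fw$A[[l]], delta)
    db[[l]] <- colSums(delta)
    g <- delta %*% t(net$W[[l]])
    if (l > 1L)
      delta <- .actBackward(g, fw$A[[l]], fw$Z[[l - 1L]], net$acts[l - 1L])
    else
      dInput <- g
  }
  list(dW = dW, db = db, dInput = dInput)
}

.adamNew <- function(net) {
  zeros <- function(p) lapply(p, function(x) x * 0)
  list(mW = zeros(net$W), vW = zeros(net$W),
       mb = zeros(net$b), vb = zeros(net$b), t = 0L)
}

.adamStep <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grads$db[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, st = st)
}

.addGrads <- function(g1, g2) {
  list(dW = Map(`+`, g1$dW, g2$dW), db = Map(`+`, g1$db, g2$db))
}

# Generic mini-batch training driver with early stopping.
#  stepFn(nets, batchIdx)  -> list(nets-with-updated-adam, trainLoss)
#  valFn(nets)             -> validation loss
# Snapshots the best nets by validation loss and restores them at the end.
.trainDriver <- function(nets, n, cfg, stepFn, valFn) {
  best <- list(nets = nets, loss = Inf, epoch = 0L)
  hist <- list()
  wait <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batchSize)
    tl <- 0
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batchSize - 1L, n)]
      res <- stepFn(nets, idx)
      nets <- res$nets
      if (!is.finite(res$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      tl <- tl + res$loss * length(idx)
    }
    tl <- tl / n
    vl <- valFn(nets)
    hist[[epoch]] <- c(epoch = epoch, train_loss = tl, val_loss = vl)
    if (vl < best$loss - 1e-12) {
      best <- list(nets = nets, loss = vl, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  history <- if (length(hist)) as.data.frame(do.call(rbind, hist))
             else data.frame(epoch = numeric(), train_loss = numeric(),
                             val_loss = numeric())
  list(nets = best$nets, history = history, bestEpoch = best$epoch,
       bestValLoss = best$loss)
}
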