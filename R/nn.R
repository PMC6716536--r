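# Minimal CNN engine backing the two-head domain-adversarial classifier.
# Layers are plain lists; activations are (H, W, C, N) arrays on the conv
# side and (features x N) matrices on the dense side. Forward passes return
# the output plus a cache; backward passes return the input gradient plus
# per-parameter gradients laid out like the parameters.

heInit <- function(n, fanIn) rnorm(n, sd = sqrt(2 / fanIn))

layerConv <- function(cin, cout, k = 3L) {
  list(type = "conv",
       w = array(heInit(k * k * cin * cout, k * k * cin), c(k, k, cin, cout)),
       b = numeric(cout))
}
layerReLU <- function() list(type = "relu")
layerPool <- function() list(type = "pool")
layerBN <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       runMean = numeric(c), runVar = rep(1, c),
       momentum = momentum, eps = eps)
}
layerDropout <- function(p) list(type = "dropout", p = p)
layerFlatten <- function() list(type = "flatten")
layerDense <- function(nin, nout) {
  list(type = "dense",
       w = matrix(heInit(nout * nin, nin), nout, nin), b = numeric(nout))
}

layerForward <- function(layer, x, train) {
  switch(layer$type,
    conv = {
      y <- .convForward(x, layer$w, layer$b)
      list(out = y, cache = list(x = x))
    },
    relu = {
      out <- .reluInPlace(x)
      list(out = out, cache = list(out = out))
    },
    pool = {
      r <- .maxPoolForward(x)
      list(out = r$y, cache = list(idx = r$idx, dims = dim(x)))
    },
    bn = {
      if (train) {
        st <- .bnStats(x)
        mu <- st$mean
        v <- st$var
        layer$runMean <- layer$momentum * layer$runMean +
          (1 - layer$momentum) * mu
        layer$runVar <- layer$momentum * layer$runVar +
          (1 - layer$momentum) * v
      } else {
        mu <- layer$runMean; v <- layer$runVar
      }
      invstd <- 1 / sqrt(v + layer$eps)
      list(out = .bnApply(x, mu, invstd, layer$gamma, layer$beta),
           layer = layer, cache = list(x = x, mu = mu, invstd = invstd))
    },
    dropout = {
      if (train && layer$p > 0) {
        mask <- (runif(length(x)) >= layer$p) / (1 - layer$p)
        list(out = x * array(mask, dim(x)), cache = list(mask = mask))
      } else list(out = x, cache = list(mask = NULL))
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, ncol = d[4]), cache = list(d = d))
    },
    dense = list(out = sweep(layer$w %*% x, 1, layer$b, `+`),
                 cache = list(x = x)),
    stop("unknown layer type ", layer$type))
}

layerBackward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- .convBackward(cache$x, layer$w, dy)
      list(dx = g$dx, grads = list(w = g$dw, b = g$db))
    },
    relu = list(dx = .reluBackward(cache$out, dy), grads = NULL),
    pool = list(dx = .maxPoolBackward(cache$idx, dy, cache$dims),
                grads = NULL),
    bn = {
      g <- .bnBackward(cache$x, dy, cache$mu, cache$invstd, layer$gamma)
      list(dx = g$dx, grads = list(gamma = g$dgamma, beta = g$dbeta))
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = NULL)
      else list(dx = dy * array(cache$mask, dim(dy)), grads = NULL)
    },
    flatten = list(dx = array(dy, cache$d), grads = NULL),
    dense = list(dx = t(layer$w) %*% dy,
                 grads = list(w = dy %*% t(cache$x), b = rowSums(dy))),
    stop("unknown layer type ", layer$type))
}

# Forward a layer stack. Returns output, caches, and (for train-mode BN)
# the updated layers carrying refreshed running statistics.
stackForward <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layerForward(layers[[i]], x, train)
    if (!is.null(r$layer)) layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches, layers = layers)
}

# Backward a layer stack; returns gradient w.r.t. the stack input and a
# per-layer list of parameter gradients.
stackBackward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layerBackward(layers[[i]], caches[[i]], dy)
    grads[i] <- list(r$grads)    # keep NULL placeholders for param-free layers
    dy <- r$dx
  }
  list(dx = dy, grads = grads)
}

# Plain SGD: theta <- theta - lr * grad, per parameter tensor.
stackUpdate <- function(layers, grads, lr) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * g[[nm]]
  }
  layers
}

# Softmax cross-entropy head with optional label smoothing.
# logits: K x N; labels: integers in 1..K. Smoothed targets put 1 - smooth
# on the true class and smooth/(K - 1) elsewhere, keeping probabilities off
# the saturated 0/1 extremes (better-calibrated decision thresholds).
# Returns mean loss and dlogits (already divided by N).
softmaxLoss <- function(logits, labels, smooth = 0) {
  k <- nrow(logits)
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  p <- sweep(e, 2, colSums(e), `/`)
  n <- ncol(logits)
  tgt <- matrix(smooth / (k - 1), k, n)
  tgt[cbind(labels, seq_len(n))] <- 1 - smooth
  ll <- -mean(colSums(tgt * log(pmax(p, 1e-12))))
  list(loss = ll, dlogits = (p - tgt) / n, probs = p)
}
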