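# Domain-adversarial training core: two-head convolutional classifier with
# gradient reversal, domain-balanced batching, a warmup schedule for the
# adversarial term, and hard-negative mining. The saddle-point updates are
# plain SGD:
#   theta_f <- theta_f - mu * (dLy/dtheta_f - lambda * dLd/dtheta_f)
#   theta_y <- theta_y - mu *  dLy/dtheta_y
#   theta_d <- theta_d - mu * lambda * dLd/dtheta_d
# so during the lambda = 0 warmup both the reversal path and the domain
# head are inert and training reduces exactly to the task-only baseline.

#' Architecture specification for the compact two-head model
#'
#' The shared trunk is two convolutional layers followed by two blocks of
#' convolution + batch normalization + max-pooling, a dropout layer, and a
#' final convolution + batch normalization + max-pooling block. The task
#' head is dense(featureDim) + dense(2); the domain head (reached through
#' the gradient-reversal node placed before any dense layer) is
#' dense(domainHidden) + dense(nDomains).
#'
#' @param inputSize integer (H, W, 3); H and W must be divisible by 8.
#' @param channels five conv output widths for the trunk.
#' @param featureDim width of the task branch's first dense layer (the
#'   feature embedding; 128 by default).
#' @param domainHidden width of the domain branch's hidden dense layer.
#' @param dropout trunk dropout probability, default 0.25.
#' @return validated list of class `ArchitectureSpec`.
#' @export
architectureSpec <- function(inputSize = c(64L, 64L, 3L),
                             channels = c(6L, 8L, 12L, 16L, 24L),
                             featureDim = 128L, domainHidden = 64L,
                             dropout = 0.25) {
  if (length(inputSize) != 3 || inputSize[3] != 3)
    stop("inputSize must be (H, W, 3)")
  if (any(inputSize[1:2] %% 8 != 0))
    stop("input height and width must be divisible by 8 (three 2x2 pools)")
  if (length(channels) != 5) stop("five trunk channel widths are required")
  structure(list(inputSize = as.integer(inputSize),
                 channels = as.integer(channels),
                 featureDim = as.integer(featureDim),
                 domainHidden = as.integer(domainHidden), dropout = dropout),
            class = "ArchitectureSpec")
}

#' Training configuration for the Eq.-style SGD updates
#'
#' @param mu base learning rate, default 0.01 (the compact-model setting).
#' @param lambda domain multiplier applied after warmup, default 1.
#' @param warmupIters iterations with lambda forced to 0, default 100.
#' @param batchSize mini-batch size; must be divisible by the number of
#'   domains for domain-balanced batching. Default 30.
#' @param iters total training iterations, default 300.
#' @param evalEvery validation-check period (iterations) for early
#'   stopping; the parameter snapshot with the best validation F1 is
#'   restored after training. 0 disables early stopping. Only active when
#'   validation data are passed to [trainModel()].
#' @param labelSmooth label-smoothing mass on the task and domain targets
#'   (default 0.1); keeps probabilities off the saturated extremes so the
#'   decision threshold stays meaningful under domain shift.
#' @param seed integer seed controlling batching, geometric augmentation,
#'   color augmentation and dropout.
#' @return validated list of class `TrainConfig`.
#' @export
trainConfig <- function(mu = 0.01, lambda = 1, warmupIters = 100L,
                        batchSize = 30L, iters = 300L, evalEvery = 25L,
                        labelSmooth = 0.1, seed = 1L) {
  if (mu <= 0) stop("mu must be positive")
  if (lambda < 0) stop("lambda must be non-negative")
  if (warmupIters < 0) stop("warmupIters must be non-negative")
  if (labelSmooth < 0 || labelSmooth >= 0.5)
    stop("labelSmooth must lie in [0, 0.5)")
  structure(list(mu = mu, lambda = lambda,
                 warmupIters = as.integer(warmupIters),
                 batchSize = as.integer(batchSize), iters = as.integer(iters),
                 evalEvery = as.integer(evalEvery), labelSmooth = labelSmooth,
                 seed = as.integer(seed)), class = "TrainConfig")
}

#' Build the two-head convolutional model
#'
#' Shared trunk and task head are initialized from `seed`; the domain head
#' (when `adversarial`) from an independent stream, so a task-only baseline
#' and an adversarial model built with the same seed share identical
#' trunk/task initial weights.
#'
#' @param spec an [architectureSpec()].
#' @param nDomains number of domain outputs (>= 2 when adversarial).
#' @param adversarial attach the domain head and gradient-reversal path?
#' @param seed integer seed for weight initialization.
#' @return A [DannModel-class].
#' @export
buildModel <- function(spec = architectureSpec(), nDomains = 2L,
                       adversarial = FALSE, seed = 1L) {
  stopifnot(inherits(spec, "ArchitectureSpec"))
  nDomains <- as.integer(nDomains)
  if (adversarial && nDomains < 2L)
    stop("adversarial training needs at least 2 domains")
  ch <- spec$channels
  flat <- (spec$inputSize[1] %/% 8L) * (spec$inputSize[2] %/% 8L) * ch[5]
  built <- withSeed(seed, {
    trunk <- list(layerConv(3L, ch[1]), layerReLU(),
                  layerConv(ch[1], ch[2]), layerReLU(),
                  layerConv(ch[2], ch[3]), layerBN(ch[3]), layerReLU(),
                  layerPool(),
                  layerConv(ch[3], ch[4]), layerBN(ch[4]), layerReLU(),
                  layerPool(),
                  layerDropout(spec$dropout),
                  layerConv(ch[4], ch[5]), layerBN(ch[5]), layerReLU(),
                  layerPool(),
                  layerFlatten())
    taskHead <- list(layerDense(flat, spec$featureDim), layerReLU(),
                     layerDense(spec$featureDim, 2L))
    list(trunk = trunk, taskHead = taskHead)
  })
  domainHead <- if (adversarial)
    withSeed(seed + 77777L, list(layerDense(flat, spec$domainHidden),
                                 layerReLU(),
                                 layerDense(spec$domainHidden, nDomains)))
  else list()
  new("DannModel", trunk = built$trunk, taskHead = built$taskHead,
      domainHead = domainHead, spec = unclass(spec), nDomains = nDomains,
      adversarial = adversarial, trained = FALSE,
      history = data.frame(iter = integer(0), lossTask = numeric(0),
                           lossDomain = numeric(0), lambda = numeric(0)))
}

#' Gradient reversal
#'
#' Identity in the forward pass; in the backward pass multiplies the
#' incoming gradient by -lambda, so the shared trunk ascends on the domain
#' loss while both heads descend on their own losses.
#'
#' @param grad upstream gradient (any numeric array).
#' @param lambda non-negative domain multiplier.
#' @return `-lambda * grad`.
#' @examples
#' gradientReversal(c(1, -2), 1)   # -1, 2
#' gradientReversal(c(1, -2), 0)   # 0, 0 (warmup regime)
#' @export
gradientReversal <- function(grad, lambda) -lambda * grad

#' One-hot encoding of domain labels
#'
#' @param labels vector of domain labels.
#' @param levels domain levels defining the column order; defaults to the
#'   sorted unique labels.
#' @return N x nDomains 0/1 matrix with unit row sums.
#' @export
domainOneHot <- function(labels, levels = sort(unique(labels))) {
  m <- outer(as.character(labels), as.character(levels), `==`) * 1
  colnames(m) <- as.character(levels)
  m
}

#' Domain-balanced batch index stream
#'
#' Every batch contains exactly `batchSize / nDomains` samples from each
#' domain; domains with fewer records than their quota are sampled with
#' replacement. Uses the caller's RNG stream.
#'
#' @param domains vector of per-record domain labels.
#' @param batchSize batch size; must be divisible by the number of domains.
#' @param nBatches number of batches to emit.
#' @param levels domain levels (defaults to sorted unique labels).
#' @return list of `nBatches` integer index vectors.
#' @export
balancedBatchIndices <- function(domains, batchSize, nBatches,
                                 levels = sort(unique(domains))) {
  nd <- length(levels)
  if (batchSize %% nd != 0)
    stop("batchSize (", batchSize, ") must be divisible by the number of ",
         "domains (", nd, ")")
  pools <- lapply(levels, function(l) which(domains == l))
  empty <- lengths(pools) == 0
  if (any(empty))
    stop("domain(s) with zero records: ",
         paste(levels[empty], collapse = ", "))
  q <- batchSize %/% nd
  lapply(seq_len(nBatches), function(i)
    unlist(lapply(pools, function(p)
      p[sample.int(length(p), q, replace = length(p) < q)])))
}

# random 90-degree rotation + optional flip (used to oversample the
# minority task class with geometric variants)
rotFlipPatch <- function(img, k, flip) {
  for (i in seq_len(k %% 4))
    img <- aperm(img, c(2, 1, 3))[dim(img)[2]:1, , , drop = FALSE]
  if (flip) img <- img[, dim(img)[2]:1, , drop = FALSE]
  img
}

# One combined forward/backward/update step of the saddle-point SGD.
# x: (H, W, 3, N) in [0, 1]; yTask in 1..2 with NA for domain-only (n')
# samples, which contribute to the domain loss but not the task loss;
# yDomain in 1..nDomains or NULL.
dannStep <- function(model, x, yTask, yDomain, mu, lambda, update = TRUE,
                     smooth = 0) {
  ftr <- stackForward(model@trunk, x, train = TRUE)
  model@trunk <- ftr$layers                      # refreshed BN statistics
  labeled <- which(!is.na(yTask))
  fLab <- if (length(labeled) == ncol(ftr$out)) ftr$out
          else ftr$out[, labeled, drop = FALSE]
  fy <- stackForward(model@taskHead, fLab, train = TRUE)
  sy <- softmaxLoss(fy$out, yTask[labeled], smooth)
  by <- stackBackward(model@taskHead, fy$caches, sy$dlogits)
  if (length(labeled) == ncol(ftr$out)) dTrunk <- by$dx
  else {
    dTrunk <- matrix(0, nrow(ftr$out), ncol(ftr$out))
    dTrunk[, labeled] <- by$dx
  }
  lossDomain <- NA_real_
  gDom <- NULL
  if (model@adversarial && !is.null(yDomain)) {
    fd <- stackForward(model@domainHead, ftr$out, train = TRUE)
    sd <- softmaxLoss(fd$out, yDomain, smooth)
    lossDomain <- sd$loss
    if (lambda > 0) {
      bd <- stackBackward(model@domainHead, fd$caches, sd$dlogits)
      gDom <- bd$grads
      dTrunk <- dTrunk + gradientReversal(bd$dx, lambda)
    }
  }
  btr <- stackBackward(model@trunk, ftr$caches, dTrunk)
  if (update) {
    model@trunk <- stackUpdate(model@trunk, btr$grads, mu)
    model@taskHead <- stackUpdate(model@taskHead, by$grads, mu)
    if (!is.null(gDom))
      model@domainHead <- stackUpdate(model@domainHead, gDom, mu * lambda)
  }
  list(model = model, lossTask = sy$loss, lossDomain = lossDomain)
}

#' Train a model with the iterative stochastic saddle-point updates
#'
#' Batches are domain-balanced (the same sampler is used for task-only
#' baselines so that an adversarial run with lambda = 0 reproduces the
#' baseline trajectory exactly at matched seed). Within each domain's quota
#' the two task classes are drawn evenly, and minority-class duplicates
#' receive random rotations/flips. For the first `warmupIters` iterations
#' lambda is forced to 0 (task branch only); afterwards it takes the
#' configured value. Optional online color augmentation is applied per
#' image presentation.
#'
#' @param model a [DannModel-class] from [buildModel()].
#' @param images list of H x W x 3 arrays in \[0, 255\].
#' @param taskLabels integer 0/1 vector, one per image.
#' @param domainLabels vector of domain labels, one per image.
#' @param config a [trainConfig()].
#' @param augConfig optional [augmentationConfig()] for online color
#'   augmentation.
#' @param valImages,valLabels optional validation images and 0/1 labels;
#'   when given (and `config$evalEvery > 0`), validation F1 at the
#'   F1-optimal threshold is tracked every `evalEvery` iterations and the
#'   best parameter snapshot is restored at the end (early stopping).
#' @param domainOnlyImages,domainOnlyDomains optional n' samples for which
#'   only the domain label is known (e.g. unlabeled images from a shifted
#'   target center). They enter the domain loss and the adversarial trunk
#'   update but never the task loss; requires an adversarial model whose
#'   `nDomains` counts these extra domains.
#' @return the trained model; its `history` slot holds per-iteration task
#'   loss, domain loss and the lambda schedule.
#' @export
trainModel <- function(model, images, taskLabels, domainLabels, config,
                       augConfig = NULL, valImages = NULL,
                       valLabels = NULL, domainOnlyImages = NULL,
                       domainOnlyDomains = NULL) {
  stopifnot(is(model, "DannModel"), inherits(config, "TrainConfig"))
  n <- length(images)
  stopifnot(length(taskLabels) == n, length(domainLabels) == n)
  if (!is.null(domainOnlyImages)) {
    if (!model@adversarial)
      stop("domain-only samples require an adversarial model")
    images <- c(images, domainOnlyImages)
    taskLabels <- c(taskLabels, rep(NA_integer_, length(domainOnlyImages)))
    domainLabels <- c(as.character(domainLabels),
                      as.character(domainOnlyDomains))
  }
  levels <- sort(unique(as.character(domainLabels)))
  if (model@adversarial && length(levels) != model@nDomains)
    stop("model expects ", model@nDomains, " domains, data has ",
         length(levels))
  nd <- length(levels)
  if (config$batchSize %% nd != 0)
    stop("batchSize must be divisible by the number of domains")
  q <- config$batchSize %/% nd
  pools <- lapply(levels, function(l) {
    idx <- which(domainLabels == l)
    if (length(idx) == 0) stop("domain with zero records: ", l)
    list(pos = idx[which(taskLabels[idx] == 1L)],
         neg = idx[which(taskLabels[idx] == 0L)],
         all = idx)
  })
  minority <- if (mean(taskLabels == 1L, na.rm = TRUE) <= 0.5) 1L else 0L
  dIndex <- match(as.character(domainLabels), levels)
  hist <- vector("list", config$iters)
  doVal <- !is.null(valImages) && config$evalEvery > 0L
  bestF1 <- -Inf
  bestSnap <- NULL
  model <- withSeed(config$seed + 1L, {
    for (it in seq_len(config$iters)) {
      lambda <- if (it <= config$warmupIters) 0 else config$lambda
      # class-balanced draw within each domain quota
      idx <- unlist(lapply(pools, function(p) {
        npos <- q %/% 2L
        if (length(p$pos) == 0 || length(p$neg) == 0)
          p$all[sample.int(length(p$all), q, replace = length(p$all) < q)]
        else c(p$pos[sample.int(length(p$pos), npos, replace = TRUE)],
               p$neg[sample.int(length(p$neg), q - npos,
                                replace = length(p$neg) < q - npos)])
      }))
      xb <- array(0, c(dim(images[[1]])[1:2], 3L, length(idx)))
      for (j in seq_along(idx)) {
        im <- images[[idx[j]]]
        if (!is.na(taskLabels[idx[j]]) && taskLabels[idx[j]] == minority)
          im <- rotFlipPatch(im, sample(0:3, 1), runif(1) < 0.5)
        if (!is.null(augConfig))
          im <- applyColorAugmentation(im, sampleAugParams(augConfig))
        xb[, , , j] <- im
      }
      st <- dannStep(model, xb / 255, taskLabels[idx] + 1L, dIndex[idx],
                     config$mu, lambda, smooth = config$labelSmooth)
      model <- st$model
      if (!is.finite(st$lossTask) ||
          (!is.na(st$lossDomain) && !is.finite(st$lossDomain)))
        stop("training diverged (non-finite loss) at iteration ", it)
      hist[[it]] <- data.frame(iter = it, lossTask = st$lossTask,
                               lossDomain = st$lossDomain, lambda = lambda)
      # snapshots are only taken in the operating regime (after warmup):
      # during warmup an adversarial model is still a plain task model and
      # selecting it would discard the invariance being trained
      if (doVal && it > config$warmupIters &&
          (it %% config$evalEvery == 0L || it == config$iters)) {
        pv <- predictProb(model, valImages)
        f1 <- f1Score(valLabels, pv, optimalThreshold(valLabels, pv))
        if (f1 > bestF1) {
          bestF1 <- f1
          bestSnap <- list(trunk = model@trunk, taskHead = model@taskHead,
                           domainHead = model@domainHead)
        }
      }
    }
    if (doVal && !is.null(bestSnap)) {
      model@trunk <- bestSnap$trunk
      model@taskHead <- bestSnap$taskHead
      model@domainHead <- bestSnap$domainHead
    }
    model
  })
  model@history <- do.call(rbind, hist)
  model@trained <- TRUE
  model
}

# Evaluation-mode forward through trunk (+ optional head layers).
evalForward <- function(model, images, head = "task", batchSize = 200L) {
  n <- length(images)
  out <- NULL
  for (s in seq(1L, n, by = batchSize)) {
    idx <- s:min(n, s + batchSize - 1L)
    xb <- array(0, c(dim(images[[1]])[1:2], 3L, length(idx)))
    for (j in seq_along(idx)) xb[, , , j] <- images[[idx[j]]]
    f <- stackForward(model@trunk, xb / 255, train = FALSE)$out
    o <- switch(head,
      trunk = f,
      features = stackForward(model@taskHead[1:2], f, train = FALSE)$out,
      task = stackForward(model@taskHead, f, train = FALSE)$out,
      domain = stackForward(model@domainHead, f, train = FALSE)$out)
    out <- cbind(out, o)
  }
  out
}

#' Predict task probabilities
#'
#' Evaluation-mode forward pass (dropout off, batch-norm running
#' statistics) through trunk and task head only; the domain label of a test
#' image is never read.
#'
#' @param model a trained [DannModel-class].
#' @param images list of H x W x 3 arrays in \[0, 255\].
#' @return numeric vector of positive-class probabilities.
#' @export
predictProb <- function(model, images) {
  logits <- evalForward(model, images, head = "task")
  e <- exp(sweep(logits, 2, apply(logits, 2, max)))
  p <- sweep(e, 2, colSums(e), `/`)
  as.numeric(p[2, ])
}

#' @describeIn predictProb predicted domain-class probabilities
#'   (nDomains x N matrix) from the domain head of an adversarial model.
#' @export
predictDomainProb <- function(model, images) {
  if (!model@adversarial) stop("model has no domain head")
  logits <- evalForward(model, images, head = "domain")
  e <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(e, 2, colSums(e), `/`)
}

#' @describeIn predictProb feature activations as an N x d matrix:
#'   `layer = "embedding"` (default) gives the task branch's first
#'   dense-layer activations (featureDim wide, the embedding exported for
#'   visualization); `layer = "trunk"` gives the shared trunk output
#'   theta_f, the representation the adversarial update acts on.
#' @param layer which representation to extract.
#' @export
extractFeatures <- function(model, images,
                            layer = c("embedding", "trunk")) {
  layer <- match.arg(layer)
  t(evalForward(model, images,
                head = if (layer == "trunk") "trunk" else "features"))
}

#' Hard-negative mining bootstrap
#'
#' Trains an initial task-only model on the positives versus a random draw
#' of candidate negatives, scores every candidate, and keeps those whose
#' predicted positive probability exceeds `threshold`. If nothing clears
#' the threshold, the `topK` highest-scoring candidates are returned with a
#' warning. The mined set is intended to be computed once and reused
#' unchanged across all strategy combinations.
#'
#' @param positives list of positive-class images.
#' @param candidates list of candidate negative images (must not overlap
#'   positive windows).
#' @param config a [trainConfig()] for the bootstrap model.
#' @param spec an [architectureSpec()] matching the image size.
#' @param threshold mining threshold on the positive probability,
#'   default 0.5.
#' @param topK fallback size when no candidate clears the threshold;
#'   default `min(length(candidates), length(positives))`.
#' @param nRandomNeg number of random candidates used as bootstrap
#'   negatives; default `2 * length(positives)`.
#' @return list with `indices` (into `candidates`), `scores` (all
#'   candidates), and `model` (the bootstrap model).
#' @export
mineHardNegatives <- function(positives, candidates, config,
                              spec = architectureSpec(),
                              threshold = 0.5, topK = NULL,
                              nRandomNeg = NULL) {
  if (is.null(topK)) topK <- min(length(candidates), length(positives))
  if (is.null(nRandomNeg))
    nRandomNeg <- min(length(candidates), 2L * length(positives))
  boot <- withSeed(config$seed + 31L,
                   sample.int(length(candidates), nRandomNeg))
  images <- c(positives, candidates[boot])
  labels <- c(rep(1L, length(positives)), rep(0L, nRandomNeg))
  model <- buildModel(spec, nDomains = 2L, adversarial = FALSE,
                      seed = config$seed)
  model <- trainModel(model, images, labels,
                      domainLabels = rep("D1", length(images)),
                      config = config)
  scores <- predictProb(model, candidates)
  mined <- which(scores > threshold)
  if (length(mined) == 0L) {
    warning("no candidate cleared the mining threshold ", threshold,
            "; falling back to the top ", topK, " scoring candidates")
    mined <- order(scores, decreasing = TRUE)[seq_len(topK)]
  }
  list(indices = sort(mined), scores = scores, model = model)
}
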