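ss <- asNamespace("stainShift")

test_that("gradient reversal is -lambda times the upstream gradient", {
  g <- c(1, -2, 0.5)
  expect_identical(gradientReversal(g, 0), c(0, 0, 0))
  expect_identical(gradientReversal(g, 1), -g)
  expect_equal(gradientReversal(matrix(g, 1), 2.5), matrix(-2.5 * g, 1))
})

test_that("model builder enforces the two-head contract", {
  spec <- tinySpec()
  base <- buildModel(spec, nDomains = 3, adversarial = FALSE, seed = 2)
  dann <- buildModel(spec, nDomains = 3, adversarial = TRUE, seed = 2)
  expect_length(base@domainHead, 0)
  expect_gt(length(dann@domainHead), 0)
  # the domain head only adds parameters after the branch point
  expect_identical(base@trunk, dann@trunk)
  expect_identical(base@taskHead, dann@taskHead)
  expect_error(buildModel(spec, nDomains = 1, adversarial = TRUE),
               "at least 2 domains")
  # reversal is identity at inference: task predictions agree
  set.seed(3)
  imgs <- lapply(1:4, function(i)
    array(sample(0:255, 16 * 16 * 3, replace = TRUE), c(16, 16, 3)))
  expect_identical(predictProb(base, imgs), predictProb(dann, imgs))
})

test_that("one SGD step matches the hand-derived saddle-point update", {
  # 1 scalar feature; linear trunk (w_f, b_f); linear 2-class task and
  # domain heads. The oracle below spells out the chain rule by hand.
  wf <- 0.8; bf <- -0.2
  Wy <- matrix(c(0.5, -0.3), 2, 1); by <- c(0.1, 0)
  Wd <- matrix(c(-0.4, 0.6), 2, 1); bd <- c(0, 0.2)
  x <- matrix(c(1.2, -0.7, 0.4), 1)          # 3 samples
  yT <- c(1L, 2L, 1L); yD <- c(2L, 1L, 2L)
  mu <- 0.05; lam <- 0.7
  model <- new("DannModel",
               trunk = list(list(type = "dense", w = matrix(wf), b = bf)),
               taskHead = list(list(type = "dense", w = Wy, b = by)),
               domainHead = list(list(type = "dense", w = Wd, b = bd)),
               spec = list(), nDomains = 2L, adversarial = TRUE,
               trained = FALSE, history = data.frame())
  st <- ss$dannStep(model, x, yT, yD, mu, lam)

  # --- independent oracle -------------------------------------------------
  n <- 3
  f <- wf * x + bf                            # 1 x n features
  softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  gW <- function(W, b, labels) {
    dW <- matrix(0, 2, 1); db <- c(0, 0); df <- numeric(n); L <- 0
    for (i in 1:n) {
      p <- softmax(W %*% f[i] + b)
      L <- L - log(p[labels[i]])
      d <- p; d[labels[i]] <- d[labels[i]] - 1   # dlogits
      dW <- dW + d %*% t(f[i]); db <- db + d
      df[i] <- sum(d * W)
    }
    list(dW = dW / n, db = db / n, df = df / n, loss = L / n)
  }
  gy <- gW(Wy, by, yT)
  gd <- gW(Wd, bd, yD)
  dLy_dwf <- sum(gy$df * x); dLy_dbf <- sum(gy$df)
  dLd_dwf <- sum(gd$df * x); dLd_dbf <- sum(gd$df)
  # the three update rules
  wf2 <- wf - mu * (dLy_dwf - lam * dLd_dwf)
  bf2 <- bf - mu * (dLy_dbf - lam * dLd_dbf)
  Wy2 <- Wy - mu * gy$dW; by2 <- by - mu * gy$db
  Wd2 <- Wd - mu * lam * gd$dW; bd2 <- bd - mu * lam * gd$db

  m2 <- st$model
  expect_equal(m2@trunk[[1]]$w[1], wf2, tolerance = 1e-6)
  expect_equal(m2@trunk[[1]]$b, bf2, tolerance = 1e-6)
  expect_equal(m2@taskHead[[1]]$w, Wy2, tolerance = 1e-6)
  expect_equal(m2@taskHead[[1]]$b, as.numeric(by2), tolerance = 1e-6)
  expect_equal(m2@domainHead[[1]]$w, Wd2, tolerance = 1e-6)
  expect_equal(m2@domainHead[[1]]$b, as.numeric(bd2), tolerance = 1e-6)
  expect_equal(st$lossTask, gy$loss, tolerance = 1e-9)
  expect_equal(st$lossDomain, gd$loss, tolerance = 1e-9)
})

test_that("realized updates match finite differences on a small model", {
  # dense trunk 2 -> 2 plus two linear heads (~10 parameters per group)
  set.seed(80)
  mkDense <- function(nin, nout)
    list(type = "dense", w = matrix(rnorm(nout * nin, sd = 0.5), nout, nin),
         b = rnorm(nout, sd = 0.2))
  model <- new("DannModel",
               trunk = list(mkDense(2, 2), list(type = "relu")),
               taskHead = list(mkDense(2, 2)),
               domainHead = list(mkDense(2, 3)),
               spec = list(), nDomains = 3L, adversarial = TRUE,
               trained = FALSE, history = data.frame())
  x <- matrix(rnorm(10), 2, 5)
  yT <- sample(1:2, 5, replace = TRUE)
  yD <- sample(1:3, 5, replace = TRUE)
  mu <- 0.1; lam <- 0.6; eps <- 1e-5
  lossAt <- function(m) {
    f <- ss$stackForward(m@trunk, x, train = TRUE)$out
    ly <- ss$softmaxLoss(ss$stackForward(m@taskHead, f, TRUE)$out, yT)$loss
    ld <- ss$softmaxLoss(ss$stackForward(m@domainHead, f, TRUE)$out, yD)$loss
    c(ly, ld)
  }
  st <- ss$dannStep(model, x, yT, yD, mu, lam)
  for (part in c("trunk", "taskHead", "domainHead")) {
    for (li in seq_along(slot(model, part))) {
      lay <- slot(model, part)[[li]]
      for (nm in intersect(names(lay), c("w", "b"))) {
        for (id in seq_along(lay[[nm]])) {
          mp <- model; mm <- model
          slot(mp, part)[[li]][[nm]][id] <- lay[[nm]][id] + eps
          slot(mm, part)[[li]][[nm]][id] <- lay[[nm]][id] - eps
          fd <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
          grad <- switch(part, trunk = fd[1] - lam * fd[2],
                         taskHead = fd[1], domainHead = fd[2])
          lr <- if (part == "domainHead") mu * lam else mu
          realized <- (lay[[nm]][id] -
                         slot(st$model, part)[[li]][[nm]][id]) / lr
          expect_lt(abs(realized - grad), 1e-4)
        }
      }
    }
  }
})

test_that("lambda = 0 training reproduces the baseline trajectory exactly", {
  coh <- smallCohort(seed = 11)
  tr <- which(coh$manifest$partition == "train")
  spec <- tinySpec()
  tc <- trainConfig(iters = 10L, warmupIters = 4L, seed = 6)
  tc0 <- tc; tc0$lambda <- 0
  base <- trainModel(buildModel(spec, 3, FALSE, seed = 9),
                     coh$images[tr], coh$manifest$task_label[tr],
                     coh$manifest$domain_label[tr], tc)
  dann <- trainModel(buildModel(spec, 3, TRUE, seed = 9),
                     coh$images[tr], coh$manifest$task_label[tr],
                     coh$manifest$domain_label[tr], tc0)
  expect_identical(base@trunk, dann@trunk)
  expect_identical(base@taskHead, dann@taskHead)
  expect_identical(base@history$lossTask, dann@history$lossTask)
})

test_that("warmup freezes the adversarial path and is recorded", {
  coh <- smallCohort(seed = 12)
  tr <- which(coh$manifest$partition == "train")
  spec <- tinySpec()
  m0 <- buildModel(spec, 3, TRUE, seed = 4)
  tc <- trainConfig(iters = 8L, warmupIters = 8L, seed = 2)
  m <- trainModel(m0, coh$images[tr], coh$manifest$task_label[tr],
                  coh$manifest$domain_label[tr], tc)
  expect_identical(m@history$lambda, rep(0, 8))
  # Eq. 6 scales the domain-head update by mu * lambda: frozen during warmup
  expect_identical(m@domainHead, m0@domainHead)
  # trunk did move (task gradient flows)
  expect_false(identical(m@trunk, m0@trunk))
  tc2 <- trainConfig(iters = 10L, warmupIters = 7L, seed = 2)
  m2 <- trainModel(buildModel(spec, 3, TRUE, seed = 4),
                   coh$images[tr], coh$manifest$task_label[tr],
                   coh$manifest$domain_label[tr], tc2)
  expect_identical(m2@history$lambda, c(rep(0, 7), rep(1, 3)))
  expect_false(identical(m2@domainHead, m0@domainHead))
})

test_that("training is deterministic under a fixed config and seed", {
  coh <- smallCohort(seed = 13)
  tr <- which(coh$manifest$partition == "train")
  spec <- tinySpec()
  tc <- trainConfig(iters = 6L, warmupIters = 2L, seed = 8)
  run <- function() trainModel(buildModel(spec, 3, TRUE, seed = 5),
                               coh$images[tr],
                               coh$manifest$task_label[tr],
                               coh$manifest$domain_label[tr], tc)
  m1 <- run(); m2 <- run()
  expect_identical(m1@history, m2@history)
  expect_identical(m1@trunk, m2@trunk)
})

test_that("domain-balanced batches have exact per-domain composition", {
  doms <- rep(c("A", "B", "C"), times = c(50, 9, 120))
  batches <- withr::with_seed(1, balancedBatchIndices(doms, 30L, 100L))
  expect_length(batches, 100)
  for (b in batches) {
    expect_length(b, 30)
    expect_true(all(table(doms[b]) == 10))
  }
  expect_error(balancedBatchIndices(doms, 31L, 2L), "divisible")
  expect_error(balancedBatchIndices(factor(doms, levels = c("A", "B", "C", "D")),
                                    40L, 1L, levels = c("A", "B", "C", "D")),
               "zero records")
})

test_that("one-hot domain vectors have length nDomains and unit sum", {
  oh <- domainOneHot(c("C2", "C1", "C2"), levels = c("C1", "C2", "C3"))
  expect_identical(dim(oh), c(3L, 3L))
  expect_true(all(rowSums(oh) == 1))
  expect_identical(oh[1, ], c(C1 = 0, C2 = 1, C3 = 0))
})

test_that("domain-only samples train the domain head but not the task head", {
  coh <- smallCohort(seed = 14)
  man <- coh$manifest
  tr <- which(man$partition == "train")
  ext <- which(man$partition == "external_test")
  spec <- tinySpec()
  m <- buildModel(spec, nDomains = 4L, adversarial = TRUE, seed = 3)
  tc <- trainConfig(iters = 8L, warmupIters = 2L, batchSize = 32L, seed = 5)
  m <- trainModel(m, coh$images[tr], man$task_label[tr],
                  man$domain_label[tr], tc,
                  domainOnlyImages = coh$images[ext],
                  domainOnlyDomains = man$domain_label[ext])
  expect_true(all(is.finite(m@history$lossTask)))
  expect_true(all(is.finite(m@history$lossDomain)))
  dp <- predictDomainProb(m, coh$images[ext[1:3]])
  expect_identical(nrow(dp), 4L)
  expect_error(trainModel(buildModel(spec, 3, FALSE, seed = 1),
                          coh$images[tr], man$task_label[tr],
                          man$domain_label[tr], tc,
                          domainOnlyImages = coh$images[ext],
                          domainOnlyDomains = man$domain_label[ext]),
               "adversarial")
})

test_that("mined hard negatives are a subset with top-k fallback", {
  coh <- smallCohort(seed = 15)
  man <- coh$manifest
  tr <- which(man$partition == "train")
  pos <- coh$images[tr[man$task_label[tr] == 1]]
  neg <- coh$images[tr[man$task_label[tr] == 0]]
  tc <- trainConfig(iters = 8L, warmupIters = 8L, batchSize = 10L, seed = 7)
  mined <- mineHardNegatives(pos, neg, tc, spec = tinySpec(),
                             threshold = 0.5)
  expect_true(all(mined$indices %in% seq_along(neg)))
  expect_length(mined$scores, length(neg))
  # impossible threshold falls back to the top-k scorers with a warning
  expect_warning(
    fb <- mineHardNegatives(pos, neg, tc, spec = tinySpec(),
                            threshold = 1),
    "falling back")
  expect_length(fb$indices, min(length(neg), length(pos)))
  expect_identical(fb$indices,
                   sort(order(fb$scores, decreasing = TRUE)[
                     seq_along(fb$indices)]))
})

test_that("feature extraction yields the configured embedding width", {
  coh <- smallCohort(seed = 16)
  m <- buildModel(tinySpec(), 3, FALSE, seed = 1)
  feats <- extractFeatures(m, coh$images[1:7])
  expect_identical(dim(feats), c(7L, 16L))
})
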