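# Shared fixtures, built in code.

# scalar oracle for the tissue-heatmap transform, independent of the
# vectorized implementation
heatmapOracle <- function(p) {
  h1 <- tanh(2 * (p[3] - p[1]) / (p[2] + 1) + 0.5) + 0.5
  h2 <- tanh((640 - p[1] - p[2] - p[3]) / 300 + 0.5) + 0.5
  0.5 * tanh(h1 * h2 - 1.75) + 0.5
}

# angle between vectors in degrees
angleDeg <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cs))) * 180 / pi
}

# mean per-row angular estimation error against the generating stain
# matrix, minimized over the two row assignments (row naming is a
# convention, not part of the estimate)
stainAngleError <- function(est, truth) {
  E <- stainCoefficients(est); S <- stainCoefficients(truth)
  direct <- (angleDeg(E[1, ], S[1, ]) + angleDeg(E[2, ], S[2, ])) / 2
  crossed <- (angleDeg(E[1, ], S[2, ]) + angleDeg(E[2, ], S[1, ])) / 2
  min(direct, crossed)
}

# random non-negative unit-row stain matrix with row separation in
# [minSep, maxSep] degrees
randomStainMatrix <- function(minSep = 20, maxSep = 70) {
  repeat {
    v1 <- abs(rnorm(3)); v2 <- abs(rnorm(3))
    a <- angleDeg(v1, v2)
    if (a >= minSep && a <= maxSep) return(StainMatrix(rbind(v1, v2)))
  }
}

# concentration map with pure-stain bands plus a zero-concentration
# (background) band, suitable for estimator and normalization fixtures
phantomWithBackground <- function(size = 64) {
  conc <- deconvolutionPhantom(size)
  conc[seq_len(max(4, round(size / 5))), , ] <- 0
  conc
}

# small cohort shared by the quicker integration tests
smallCohort <- function(seed = 11, patchSize = 16L,
                        nPatches = c(train = 45L, validation = 12L,
                                     internal_test = 18L,
                                     external_test = 36L)) {
  makeCohort(cohortConfig(nPatches = nPatches, patchSize = patchSize,
                          seed = seed))
}

tinySpec <- function(patchSize = 16L) {
  architectureSpec(inputSize = c(patchSize, patchSize, 3L),
                   channels = c(4L, 4L, 6L, 6L, 8L), featureDim = 16L,
                   domainHidden = 8L)
}

# brute-force AUC: loop over all positive-negative pairs, ties 0.5
bruteAUC <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# brute-force F1 from counts
bruteF1 <- function(labels, pred) {
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

# exact two-sided Wilcoxon signed-rank p-value by enumerating all 2^n
# sign assignments of the ranked |d|
enumWilcoxonP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  stats <- vapply(seq_len(2^n) - 1L, function(m) {
    signs <- as.integer(intToBits(m))[seq_len(n)]
    sum(r[signs == 1])
  }, 0)
  mu <- n * (n + 1) / 4
  min(1, mean(abs(stats - mu) >= abs(v - mu)))
}
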