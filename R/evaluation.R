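# Internal / external evaluation protocol: F1 and AUC, multi-seed
# aggregation (mean +/- sd), Wilcoxon signed-rank method comparison, and
# feature-embedding export for qualitative inspection of domain mixing.

#' F1 score at a probability threshold
#'
#' Harmonic mean of precision and recall at the given decision threshold.
#' Conventions for degenerate cases: precision and recall are 0 when their
#' denominator is 0, and F1 is 0 when precision + recall is 0 (e.g., no
#' predicted positives while positives are present).
#'
#' @param labels 0/1 true labels.
#' @param probs predicted positive-class probabilities.
#' @param threshold decision threshold, default 0.5.
#' @return scalar F1.
#' @examples
#' f1Score(c(1, 1, 0), c(0.9, 0.8, 0.1))  # 1
#' @export
f1Score <- function(labels, probs, threshold = 0.5) {
  pred <- probs >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted 0.5 (rank formulation; threshold-free, so it complements F1 when
#' the operating threshold is far from 0.5).
#'
#' @param labels 0/1 true labels (both classes must be present).
#' @param scores predicted scores.
#' @return scalar AUC in \[0, 1\].
#' @export
aucScore <- function(labels, scores) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stop("AUC is undefined with a single class present")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Select the F1-optimal decision threshold on a validation set
#'
#' @param labels 0/1 validation labels.
#' @param probs validation probabilities.
#' @return the threshold among the observed probabilities maximizing F1.
#' @export
optimalThreshold <- function(labels, probs) {
  cand <- sort(unique(probs))
  f1 <- vapply(cand, function(th) f1Score(labels, probs, th), 0)
  cand[which.max(f1)]
}

#' Paired Wilcoxon signed-rank comparison of two prediction sets
#'
#' Two-sided Wilcoxon signed-rank test on paired per-record values
#' (positive-class probabilities by default; optionally 0/1 correctness
#' indicators). Zero differences are dropped (classic treatment); with all
#' differences zero the sets are identical and p = 1 is returned by
#' convention. The exact null distribution is used for n <= 25 untied
#' pairs, the normal approximation otherwise.
#'
#' @param probsA,probsB paired per-record values from the two methods (same
#'   records, same order).
#' @param labels optional 0/1 labels; when given with
#'   `pairing = "correct"`, the paired values are correctness indicators at
#'   `threshold`.
#' @param pairing `"probability"` (default) or `"correct"`.
#' @param threshold decision threshold for the correctness pairing.
#' @return list with `statistic`, `p.value`, `n` (non-zero pairs).
#' @export
compareMethods <- function(probsA, probsB, labels = NULL,
                           pairing = c("probability", "correct"),
                           threshold = 0.5) {
  pairing <- match.arg(pairing)
  if (length(probsA) != length(probsB))
    stop("prediction sets must be paired (same records)")
  a <- probsA; b <- probsB
  if (pairing == "correct") {
    if (is.null(labels)) stop("labels are required for correctness pairing")
    a <- as.numeric((probsA >= threshold) == (labels == 1))
    b <- as.numeric((probsB >= threshold) == (labels == 1))
  }
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = NA_real_, p.value = 1, n = 0L))
  wt <- suppressWarnings(wilcox.test(d, exact = n <= 25, correct = TRUE))
  list(statistic = as.numeric(wt$statistic), p.value = wt$p.value, n = n)
}

#' Aggregate per-seed results into mean +/- sd summaries
#'
#' @param runs data.frame with columns `method`, `seed`, `partition`, and
#'   metric columns `f1`, `auc`.
#' @return data.frame with per method x partition mean and sample (n - 1)
#'   standard deviation of each metric and the seed count; sd is `NA` for a
#'   single seed.
#' @export
aggregateResults <- function(runs) {
  stopifnot(all(c("method", "seed", "partition", "f1", "auc") %in%
                  names(runs)))
  agg <- aggregate(cbind(f1, auc) ~ method + partition, data = runs,
                   FUN = mean)
  names(agg)[names(agg) == "f1"] <- "f1_mean"
  names(agg)[names(agg) == "auc"] <- "auc_mean"
  sdOrNA <- function(x) if (length(x) > 1) sd(x) else NA_real_
  aggSd <- aggregate(cbind(f1, auc) ~ method + partition, data = runs,
                     FUN = sdOrNA)
  cnt <- aggregate(seed ~ method + partition, data = runs, FUN = length)
  agg$f1_sd <- aggSd$f1
  agg$auc_sd <- aggSd$auc
  agg$nSeeds <- cnt$seed
  agg
}

#' Format an aggregated results table as "mean (+/-sd)" cells
#'
#' Rows are metric x partition, columns are method combinations, mirroring
#' the layout used for multi-strategy comparisons.
#'
#' @param agg output of [aggregateResults()].
#' @return character matrix.
#' @export
formatResultsTable <- function(agg) {
  methods <- unique(agg$method)
  parts <- unique(agg$partition)
  rows <- as.vector(outer(c("f1", "auc"), parts, paste, sep = " | "))
  out <- matrix("", length(rows), length(methods),
                dimnames = list(rows, methods))
  for (i in seq_len(nrow(agg))) {
    for (metric in c("f1", "auc")) {
      r <- paste(metric, agg$partition[i], sep = " | ")
      m <- agg[[paste0(metric, "_mean")]][i]
      s <- agg[[paste0(metric, "_sd")]][i]
      out[r, agg$method[i]] <- if (is.na(s)) sprintf("%.4f", m)
      else sprintf("%.4f (±%.4f)", m, s)
    }
  }
  out
}

#' Export a 2-D projection of task-branch feature embeddings
#'
#' Randomly samples `nSamples` records, extracts the task branch's first
#' dense-layer activations (the featureDim-wide embedding) and projects
#' them to 2-D with a linear principal-component projection, returning a
#' plotting table.
#'
#' @param model a trained [DannModel-class].
#' @param images list of images.
#' @param manifest data.frame with `task_label` and `domain_label` columns
#'   aligned with `images`.
#' @param nSamples number of records to embed, default 80.
#' @param seed sampling seed.
#' @return data.frame (id, dim1, dim2, task_label, domain_label).
#' @export
exportEmbeddings <- function(model, images, manifest, nSamples = 80L,
                             seed = 1L) {
  stopifnot(nSamples <= length(images))
  ids <- withSeed(seed, sample.int(length(images), nSamples))
  feats <- extractFeatures(model, images[ids])
  pc <- prcomp(feats, center = TRUE, scale. = FALSE, rank. = 2)
  data.frame(id = ids, dim1 = pc$x[, 1], dim2 = pc$x[, 2],
             task_label = manifest$task_label[ids],
             domain_label = manifest$domain_label[ids])
}

#' k-NN domain-purity score of a feature embedding
#'
#' Mean fraction, over points, of the k nearest neighbours (excluding the
#' point itself) sharing the point's domain label. Chance level is the mean
#' domain frequency; lower purity means better domain mixing.
#'
#' @param features N x d feature matrix.
#' @param domains length-N domain labels.
#' @param k neighbourhood size, default 5.
#' @return scalar purity in \[0, 1\].
#' @export
knnDomainPurity <- function(features, domains, k = 5L) {
  dm <- as.matrix(dist(features))
  diag(dm) <- Inf
  same <- outer(domains, domains, `==`)
  mean(vapply(seq_len(nrow(dm)), function(i) {
    nb <- order(dm[i, ])[seq_len(k)]
    mean(same[i, nb])
  }, 0))
}

#' Linear domain probe accuracy on a feature embedding
#'
#' Fits a multinomial logistic regression predicting the domain from the
#' features on a random train split and reports held-out accuracy. Lower
#' accuracy (closer to chance) means the features carry less center
#' information.
#'
#' @param features N x d feature matrix.
#' @param domains length-N domain labels.
#' @param trainFrac training fraction, default 0.7.
#' @param seed split seed.
#' @param nSplits number of random train/test splits averaged (default 3;
#'   a single high-dimensional multinomial fit is a noisy accuracy
#'   estimator).
#' @param decay ridge penalty of the multinomial fit, default 1
#'   (roughly n/d for the default cohort's probe set; an unregularized
#'   128-dimensional fit on a few hundred samples mostly measures
#'   overfitting noise).
#' @return held-out accuracy in \[0, 1\], averaged over splits.
#' @export
domainProbe <- function(features, domains, trainFrac = 0.7, seed = 1L,
                        nSplits = 3L, decay = 1) {
  n <- nrow(features)
  df <- data.frame(domain = factor(domains), features)
  accs <- withSeed(seed, vapply(seq_len(nSplits), function(k) {
    tr <- sample.int(n, round(trainFrac * n))
    fit <- nnet::multinom(domain ~ ., data = df[tr, ], trace = FALSE,
                          MaxNWts = 100000, maxit = 200, decay = decay)
    pred <- predict(fit, newdata = df[-tr, ])
    mean(as.character(pred) == as.character(df$domain[-tr]))
  }, 0))
  mean(accs)
}
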