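# Heatmap-guided selection of tissue patch locations from unannotated RGB
# slide rasters. The heuristic combines a purple-hue score h1 and a
# darkness score h2 on the raw 0-255 channels (the constants 640 and 300
# are calibrated for that scale):
#   h1 = tanh(2(B - R)/(G + 1) + 0.5) + 0.5
#   h2 = tanh((640 - R - G - B)/300 + 0.5) + 0.5
#   h  = 0.5 tanh(h1 h2 - 1.75) + 0.5
# Locations with h above the threshold (default 0.65) are tissue.

#' Compute the tissue heatmap of an RGB image
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @return H x W matrix with values in \[0, 1\].
#' @examples
#' computeHeatmap(array(c(100, 60, 150), c(1, 1, 3)))  # tissue-like: ~0.665
#' @export
computeHeatmap <- function(img) {
  assertRGBImage(img)
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  h1 <- tanh(2 * (B - R) / (G + 1) + 0.5) + 0.5
  h2 <- tanh((640 - R - G - B) / 300 + 0.5) + 0.5
  h <- 0.5 * tanh(h1 * h2 - 1.75) + 0.5
  matrix(h, nrow = dim(img)[1])
}

#' Patch-extraction configuration
#'
#' @param threshold heatmap threshold in (0, 1), default 0.65.
#' @param patchSize patch edge length in pixels.
#' @param nPatches number of patch locations to sample.
#' @param rule `"center"` (default): a location is positive when the
#'   heatmap at the patch center exceeds the threshold; `"mean"`: when the
#'   window mean exceeds it.
#' @param magnification free-text metadata (e.g. `"10X"`); the operation
#'   itself is resolution-agnostic.
#' @param seed integer seed for location sampling.
#' @return validated list of class `ExtractionConfig`.
#' @export
extractionConfig <- function(threshold = 0.65, patchSize = 64L,
                             nPatches = 100L, rule = c("center", "mean"),
                             magnification = "10X", seed = 1L) {
  rule <- match.arg(rule)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (nPatches < 1) stop("nPatches must be >= 1")
  structure(list(threshold = threshold, patchSize = as.integer(patchSize),
                 nPatches = as.integer(nPatches), rule = rule,
                 magnification = magnification, seed = as.integer(seed)),
            class = "ExtractionConfig")
}

#' Sample patch locations from a thresholded heatmap
#'
#' Uniform random sample without replacement of top-left patch origins
#' (0-based, half-open windows) whose window lies inside the image and
#' whose heatmap score is positive under the config rule. Exactly
#' `min(nPatches, available)` locations are returned (a warning is issued
#' when fewer than requested are available, or when none are).
#'
#' @param hm heatmap matrix from [computeHeatmap()].
#' @param config an [extractionConfig()].
#' @return data.frame with 0-based integer columns `x`, `y`.
#' @export
sampleLocations <- function(hm, config) {
  stopifnot(inherits(config, "ExtractionConfig"))
  size <- config$patchSize
  H <- nrow(hm); W <- ncol(hm)
  if (H < size || W < size) {
    warning("image smaller than patch size; no locations")
    return(data.frame(x = integer(0), y = integer(0)))
  }
  nx <- W - size + 1L; ny <- H - size + 1L
  if (config$rule == "center") {
    off <- size %/% 2L
    score <- hm[seq_len(ny) + off, seq_len(nx) + off, drop = FALSE]
  } else {
    cs <- rbind(0, apply(hm, 2, cumsum)); cs <- cbind(0, t(apply(cs, 1, cumsum)))
    winSum <- cs[seq_len(ny) + size, seq_len(nx) + size] -
      cs[seq_len(ny) + size, seq_len(nx)] -
      cs[seq_len(ny), seq_len(nx) + size] + cs[seq_len(ny), seq_len(nx)]
    score <- winSum / (size * size)
  }
  pos <- which(score > config$threshold)
  if (length(pos) == 0L) {
    warning("no locations above the heatmap threshold")
    return(data.frame(x = integer(0), y = integer(0)))
  }
  take <- min(config$nPatches, length(pos))
  if (take < config$nPatches)
    warning("only ", length(pos), " eligible locations for ",
            config$nPatches, " requested patches")
  sel <- withSeed(config$seed, sample(pos, take))
  data.frame(x = as.integer((sel - 1L) %/% ny),
             y = as.integer((sel - 1L) %% ny))
}

#' Extract patch crops at given locations
#'
#' Coordinates are 0-based top-left origins with half-open
#' \[x, x+size) x \[y, y+size) windows; crops are returned in input order.
#'
#' @param img H x W x 3 array.
#' @param locations data.frame with columns `x`, `y` (0-based).
#' @param patchSize patch edge length.
#' @return list of patchSize x patchSize x 3 arrays.
#' @export
extractPatches <- function(img, locations, patchSize) {
  assertRGBImage(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  lapply(seq_len(nrow(locations)), function(i) {
    x <- locations$x[i]; y <- locations$y[i]
    if (x < 0 || y < 0 || x + patchSize > W || y + patchSize > H)
      stop("patch window out of bounds at (x = ", x, ", y = ", y, ")")
    img[y + seq_len(patchSize), x + seq_len(patchSize), , drop = FALSE]
  })
}
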