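# Macenko stain-matrix estimation and template-based stain normalization,
# with CIELAB brightness standardization applied first.

#' Standardize image brightness in CIELAB space
#'
#' Converts the image to CIELAB and rescales the L channel so that its 95th
#' percentile maps to the maximum lightness (i.e., at least 5% of the pixels
#' become white), then converts back to sRGB. Idempotent up to conversion
#' round-off.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @return brightness-standardized H x W x 3 array in \[0, 255\].
#' @export
standardizeBrightness <- function(img) {
  assertRGBImage(img)
  d <- dim(img)
  lab <- grDevices::convertColor(matrix(img / 255, ncol = 3),
                                 from = "sRGB", to = "Lab")
  p95 <- as.numeric(quantile(lab[, 1], 0.95, names = FALSE))
  if (p95 > 0) lab[, 1] <- pmin(lab[, 1] * (100 / p95), 100)
  out <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  array(round(clip255(out * 255)), d)
}

#' Estimate the stain matrix of an image (Macenko method)
#'
#' Pixels are mapped to optical density; background pixels (OD at or below
#' `odThreshold` in every channel) are discarded; the 2-D plane spanned by the
#' two principal directions of the OD point cloud is found by SVD (of the
#' mean-centered cloud, the plane containing the origin-anchored stain
#' directions); retained pixels are projected onto the plane and the
#' directions at the `anglePercentile`-th and (100 - `anglePercentile`)-th
#' percentile angles are taken as the two stain vectors. Rows are
#' unit-normalized and labeled by proximity to the canonical H/E
#' directions (hematoxylin first).
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param odThreshold transparent-pixel exclusion threshold (OD), default
#'   0.15.
#' @param anglePercentile extreme-angle clipping percentile, default 1.
#' @param background background intensity I0.
#' @param minPixels minimum number of retained tissue pixels.
#' @return A [StainMatrix-class].
#' @export
estimateStainMatrix <- function(img, odThreshold = 0.15,
                                anglePercentile = 1, background = 255,
                                minPixels = 50) {
  od <- matrix(rgbToOD(img, background), ncol = 3)
  keep <- rowSums(od > odThreshold) > 0L
  nk <- sum(keep)
  if (nk < minPixels)
    stop("too few tissue pixels for stain estimation: ", nk,
         " above OD threshold ", odThreshold, " (need ", minPixels, ")")
  odk <- od[keep, , drop = FALSE]
  sv <- svd(scale(odk, center = TRUE, scale = FALSE), nu = 0)
  if (sv$d[2] < 1e-6 * max(sv$d[1], 1e-12))
    stop("degenerate OD point cloud: pixels are collinear ",
         "(single-stain image?)")
  basis <- sv$v[, 1:2]
  proj <- odk %*% basis
  if (mean(proj[, 1]) < 0) { basis[, 1] <- -basis[, 1]; proj[, 1] <- -proj[, 1] }
  phi <- atan2(proj[, 2], proj[, 1])
  lo <- as.numeric(quantile(phi, anglePercentile / 100, names = FALSE))
  hi <- as.numeric(quantile(phi, 1 - anglePercentile / 100, names = FALSE))
  if (hi - lo < 5 * pi / 180)
    stop("degenerate OD point cloud: angular spread below 5 degrees ",
         "(single-stain image?)")
  v1 <- as.numeric(basis %*% c(cos(lo), sin(lo)))
  v2 <- as.numeric(basis %*% c(cos(hi), sin(hi)))
  if (sum(v1) < 0) v1 <- -v1
  if (sum(v2) < 0) v2 <- -v2
  v1 <- pmax(v1, 0) / sqrt(sum(pmax(v1, 0)^2))
  v2 <- pmax(v2, 0) / sqrt(sum(pmax(v2, 0)^2))
  # label rows by proximity to the canonical H/E directions (robust to
  # strongly shifted stains, where a red-absorbance rule can flip)
  canon <- canonicalStains()@coefficients
  ang <- function(u, v) acos(min(1, max(-1, sum(u * v))))
  direct <- ang(v1, canon[1, ]) + ang(v2, canon[2, ])
  swapped <- ang(v1, canon[2, ]) + ang(v2, canon[1, ])
  rows <- if (direct <= swapped) rbind(v1, v2) else rbind(v2, v1)
  StainMatrix(rows)
}

#' Estimate per-pixel stain concentrations
#'
#' Solves, per pixel, the non-negative least-squares problem
#' OD ~ C . S for the length-2 concentration vector C (exact active-set
#' solution for two stains); negatives are clipped to zero.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param stain a [StainMatrix-class].
#' @param background background intensity I0.
#' @return H x W x 2 non-negative concentration array.
#' @export
estimateConcentrations <- function(img, stain, background = 255) {
  stopifnot(is(stain, "StainMatrix"))
  S <- stain@coefficients
  A <- S %*% t(S)
  if (abs(det(A)) < 1e-10) stop("singular stain matrix")
  od <- matrix(rgbToOD(img, background), ncol = 3)
  B <- od %*% t(S)                       # N x 2 cross-products
  Ainv <- solve(A)
  C <- B %*% t(Ainv)                     # unconstrained LS solution
  neg1 <- C[, 1] < 0; neg2 <- C[, 2] < 0
  # active-set: when one coefficient is negative, refit the other alone
  if (any(neg1)) C[neg1, 2] <- B[neg1, 2] / A[2, 2]
  if (any(neg2)) C[neg2, 1] <- B[neg2, 1] / A[1, 1]
  C[C < 0] <- 0
  d <- dim(img)
  array(C, c(d[1], d[2], 2))
}

#' Fit a normalization template from a reference image
#'
#' Brightness-standardizes the image, estimates its stain matrix and
#' concentrations, and records the 99th percentile of each concentration
#' channel as the robust per-stain scale.
#'
#' @inheritParams estimateStainMatrix
#' @param maxConcQuantile robust concentration-scale quantile, default 0.99.
#' @return A [NormalizationTemplate-class].
#' @export
fitTemplate <- function(img, odThreshold = 0.15, anglePercentile = 1,
                        background = 255, maxConcQuantile = 0.99) {
  std <- standardizeBrightness(img)
  st <- estimateStainMatrix(std, odThreshold, anglePercentile, background)
  conc <- estimateConcentrations(std, st, background)
  mc <- c(quantile(conc[, , 1], maxConcQuantile, names = FALSE),
          quantile(conc[, , 2], maxConcQuantile, names = FALSE))
  mc <- pmax(mc, 1e-6)
  new("NormalizationTemplate", stain = st, maxConc = mc,
      background = background)
}

#' Normalize an image into a template's color frame
#'
#' The source image is brightness-standardized; its own stain matrix and
#' concentrations are estimated; concentrations are rescaled channel-wise by
#' template.maxConc / source.maxConc and the patch is re-rendered through
#' the template stain matrix.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param template a [NormalizationTemplate-class] from [fitTemplate()].
#' @inheritParams fitTemplate
#' @param sourceId optional identifier carried into error messages.
#' @return normalized H x W x 3 array in \[0, 255\].
#' @export
normalizeStains <- function(img, template, odThreshold = 0.15,
                            anglePercentile = 1,
                            maxConcQuantile = 0.99, sourceId = NULL) {
  stopifnot(is(template, "NormalizationTemplate"))
  std <- standardizeBrightness(img)
  st <- tryCatch(
    estimateStainMatrix(std, odThreshold, anglePercentile,
                        template@background),
    error = function(e) stop("stain estimation failed",
                             if (!is.null(sourceId))
                               paste0(" for source '", sourceId, "'"),
                             ": ", conditionMessage(e)))
  conc <- estimateConcentrations(std, st, template@background)
  mc <- c(quantile(conc[, , 1], maxConcQuantile, names = FALSE),
          quantile(conc[, , 2], maxConcQuantile, names = FALSE))
  mc <- pmax(mc, 1e-6)
  scl <- template@maxConc / mc
  conc <- sweep(conc, 3, scl, `*`)
  renderPatch(template@stain, conc, template@background)
}

#' Serialize / restore a normalization template as JSON
#'
#' @param template a [NormalizationTemplate-class].
#' @param path JSON file path.
#' @return `writeTemplate` invisibly returns `path`; `readTemplate` returns
#'   the restored template.
#' @export
writeTemplate <- function(template, path) {
  jsonlite::write_json(list(stain = template@stain@coefficients,
                            maxConc = template@maxConc,
                            background = template@background),
                       path, digits = NA)
  invisible(path)
}

#' @rdname writeTemplate
#' @export
readTemplate <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("NormalizationTemplate",
      stain = StainMatrix(matrix(unlist(x$stain), nrow = 2)),
      maxConc = as.numeric(x$maxConc),
      background = as.numeric(x$background))
}
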