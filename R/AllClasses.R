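#' @import methods
#' @importFrom stats rnorm runif quantile sd aggregate prcomp chisq.test
#'   wilcox.test dist predict
#' @importFrom utils write.csv read.csv
#' @importFrom tools file_ext
#' @useDynLib stainShift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' StainMatrix: per-channel absorbance coefficients of the two H&E stains
#'
#' A 2 x 3 matrix of non-negative absorbance coefficients in optical-density
#' space; row 1 is hematoxylin, row 2 is eosin, columns are R, G, B. Rows are
#' stored unit-normalized (the Euclidean norm is carried by the concentration
#' map instead), which removes the scale ambiguity of the S.C factorization.
#'
#' @slot coefficients numeric 2 x 3 matrix with unit-norm, linearly
#'   independent, non-negative rows.
#' @export
setClass("StainMatrix", representation(coefficients = "matrix"))

setValidity("StainMatrix", function(object) {
  m <- object@coefficients
  if (!is.numeric(m) || !identical(dim(m), c(2L, 3L)))
    return("coefficients must be a numeric 2 x 3 matrix")
  if (any(!is.finite(m)) || any(m < -1e-9))
    return("absorbance coefficients must be finite and non-negative")
  nrm <- sqrt(rowSums(m^2))
  if (any(abs(nrm - 1) > 1e-6))
    return("rows must have unit Euclidean norm")
  if (abs(sum(m[1, ] * m[2, ])) > 1 - 1e-8)
    return("stain rows must be linearly independent")
  TRUE
})

#' Construct a StainMatrix
#'
#' @param coefficients numeric 2 x 3 matrix; row 1 hematoxylin, row 2 eosin,
#'   columns R, G, B absorbance.
#' @param normalize if `TRUE` (default) rows are rescaled to unit norm.
#' @return A [StainMatrix-class] object.
#' @examples
#' StainMatrix(rbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11)))
#' @export
StainMatrix <- function(coefficients, normalize = TRUE) {
  m <- as.matrix(coefficients)
  if (normalize) {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm <= 0)) stop("stain rows must be non-zero")
    m <- m / nrm
  }
  m[m < 0 & m > -1e-9] <- 0
  dimnames(m) <- list(c("hematoxylin", "eosin"), c("R", "G", "B"))
  new("StainMatrix", coefficients = m)
}

#' @describeIn StainMatrix accessor for the 2 x 3 coefficient matrix.
#' @param object a `StainMatrix`.
#' @export
setGeneric("stainCoefficients", function(object)
  standardGeneric("stainCoefficients"))

#' @rdname StainMatrix
#' @export
setMethod("stainCoefficients", "StainMatrix", function(object)
  object@coefficients)

setMethod("show", "StainMatrix", function(object) {
  cat("StainMatrix (unit-norm absorbance rows)\n")
  print(round(object@coefficients, 4))
})

#' Canonical H&E stain matrix
#'
#' The classical color-deconvolution reference vectors,
#' H = (0.65, 0.70, 0.29), E = (0.07, 0.99, 0.11), unit-normalized.
#'
#' @return A [StainMatrix-class].
#' @export
canonicalStains <- function() {
  StainMatrix(rbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11)))
}

#' NormalizationTemplate: frozen color frame for stain normalization
#'
#' Holds the template image's estimated stain matrix, a robust per-stain
#' concentration scale (99th percentile of each concentration channel), and
#' the background intensity, as extracted by [fitTemplate()].
#'
#' @slot stain a [StainMatrix-class].
#' @slot maxConc numeric length-2 positive vector, robust concentration
#'   scale for (hematoxylin, eosin).
#' @slot background positive scalar background intensity.
#' @export
setClass("NormalizationTemplate",
         representation(stain = "StainMatrix", maxConc = "numeric",
                        background = "numeric"))

setValidity("NormalizationTemplate", function(object) {
  if (length(object@maxConc) != 2 || any(!is.finite(object@maxConc)) ||
      any(object@maxConc <= 0))
    return("maxConc must be two positive finite values")
  if (length(object@background) != 1 || object@background <= 0)
    return("background must be a positive scalar")
  TRUE
})

setMethod("show", "NormalizationTemplate", function(object) {
  cat("NormalizationTemplate\n  background:", object@background,
      "\n  maxConc (H, E):", round(object@maxConc, 3), "\n")
  print(round(object@stain@coefficients, 4))
})

#' CenterProfile: acquisition appearance of one (synthetic) center
#'
#' Encodes the center-specific nuisance parameters whose variability the
#' pipeline must overcome: the stain matrix, an additive brightness offset,
#' multiplicative per-channel gains, and pixel noise.
#'
#' @slot centerId character identifier.
#' @slot stain a [StainMatrix-class].
#' @slot brightnessOffset scalar added to all channels after rendering.
#' @slot channelGain positive length-3 multiplicative gain (R, G, B).
#' @slot noiseSd non-negative Gaussian pixel-noise standard deviation.
#' @export
setClass("CenterProfile",
         representation(centerId = "character", stain = "StainMatrix",
                        brightnessOffset = "numeric", channelGain = "numeric",
                        noiseSd = "numeric"))

setValidity("CenterProfile", function(object) {
  if (length(object@channelGain) != 3 || any(object@channelGain <= 0))
    return("channelGain must be three positive scalars")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  TRUE
})

setMethod("show", "CenterProfile", function(object) {
  cat("CenterProfile", object@centerId, "\n  gain:",
      round(object@channelGain, 3), " offset:",
      round(object@brightnessOffset, 2), " noiseSd:", object@noiseSd, "\n")
})

#' DannModel: two-head convolutional classifier with gradient reversal
#'
#' Wraps the shared convolutional trunk (theta_f), the task head (theta_y)
#' and, when `adversarial`, the domain head (theta_d) reached through a
#' gradient-reversal node. Built by [buildModel()] and trained in place by
#' [trainModel()].
#'
#' @slot trunk list of shared feature-extractor layers.
#' @slot taskHead list of task-branch layers (first dense layer is the
#'   feature embedding exported by [exportEmbeddings()]).
#' @slot domainHead list of domain-branch layers (empty when not adversarial).
#' @slot spec the architecture specification list.
#' @slot nDomains integer number of domain outputs.
#' @slot adversarial logical flag.
#' @slot trained logical flag.
#' @slot history data.frame of per-iteration losses and lambda schedule.
#' @export
setClass("DannModel",
         representation(trunk = "list", taskHead = "list",
                        domainHead = "list", spec = "list",
                        nDomains = "integer", adversarial = "logical",
                        trained = "logical", history = "data.frame"))

setMethod("show", "DannModel", function(object) {
  cat(if (object@adversarial) "DannModel (adversarial, "
      else "DannModel (task-only, ",
      object@nDomains, " domains)\n", sep = "")
  cat("  trunk layers:", length(object@trunk),
      " task head:", length(object@taskHead),
      " domain head:", length(object@domainHead), "\n")
  cat("  trained:", object@trained,
      if (nrow(object@history)) paste0(" (", nrow(object@history),
                                       " iterations)") else "", "\n")
})
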