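# Random channel-wise scale-and-shift color augmentation:
# I'_c <- a_c * I_c + b_c, applied in RGB, HSV or HED space at training
# time with fresh parameters per presentation.

#' Color augmentation configuration
#'
#' @param aRange range of the per-channel multiplicative factor a_c;
#'   `aRange[1]` must be positive.
#' @param bRange range of the per-channel additive shift b_c, expressed on
#'   the 0-255 intensity scale (rescaled internally for unit-scale spaces).
#' @param space `"RGB"` (default), `"HSV"` or `"HED"`.
#' @param perImage if `TRUE` (default) fresh parameters are drawn per image
#'   presentation; if `FALSE` one draw is shared across a batch.
#' @return validated list of class `AugmentationConfig`.
#' @export
augmentationConfig <- function(aRange = c(0.9, 1.1), bRange = c(-10, 10),
                               space = c("RGB", "HSV", "HED"),
                               perImage = TRUE) {
  space <- match.arg(space)
  if (aRange[1] > aRange[2] || bRange[1] > bRange[2])
    stop("ranges must satisfy min <= max")
  if (aRange[1] <= 0) stop("a_min must be positive")
  structure(list(aRange = aRange, bRange = bRange, space = space,
                 perImage = perImage), class = "AugmentationConfig")
}

#' Draw augmentation parameters
#'
#' a and b are drawn independently and uniformly per channel from the
#' configured ranges (uses the caller's RNG stream).
#'
#' @param config an [augmentationConfig()].
#' @return list with `a`, `b` (length-3) and `space`.
#' @export
sampleAugParams <- function(config) {
  stopifnot(inherits(config, "AugmentationConfig"))
  list(a = runif(3, config$aRange[1], config$aRange[2]),
       b = runif(3, config$bRange[1], config$bRange[2]),
       space = config$space)
}

# canonical H-E-DAB absorbance rows (unit-normalized), fixed deconvolution
hedMatrix <- function() {
  m <- rbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11), c(0.27, 0.57, 0.78))
  m / sqrt(rowSums(m^2))
}

#' Apply channel-wise affine color augmentation
#'
#' Per channel c of the configured space, x <- a_c * x + b_c, then clipped
#' back to the valid range. With identity parameters (a = 1, b = 0) the
#' operation is bit-exact identity in RGB space. In HSV and HED spaces the
#' shift b is rescaled by 1/255 to the unit channel scale; HED uses the
#' canonical fixed H-E-DAB deconvolution matrix, independent of any
#' per-image stain estimate.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param params a draw from [sampleAugParams()].
#' @return augmented H x W x 3 array in \[0, 255\].
#' @export
applyColorAugmentation <- function(img, params) {
  assertRGBImage(img)
  d <- dim(img)
  a <- params$a; b <- params$b
  if (params$space == "RGB") {
    if (all(a == 1) && all(b == 0)) return(img)
    out <- sweep(sweep(img, 3, a, `*`), 3, b, `+`)
    return(array(round(clip255(out)), d))
  }
  if (params$space == "HSV") {
    m <- t(matrix(img, ncol = 3))          # 3 x N, rows R,G,B
    hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
    hsv <- pmin(pmax(hsv * a + b / 255, 0), 1)
    out <- hsv2rgbMatrix(hsv)              # 3 x N in [0, 1]
    return(array(round(clip255(t(out) * 255)), d))
  }
  # HED: affine map on fixed-deconvolution stain channels in OD space
  M <- hedMatrix()
  od <- matrix(rgbToOD(img), ncol = 3)
  hed <- od %*% solve(M)
  hed <- sweep(sweep(hed, 2, a, `*`), 2, b / 255, `+`)
  od2 <- pmax(hed %*% M, 0)
  odToRGB(array(od2, d))
}

# vectorized HSV -> RGB ([0,1] channels)
hsv2rgbMatrix <- function(hsv) {
  h <- hsv[1, ] * 6; s <- hsv[2, ]; v <- hsv[3, ]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); tt <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, tt, v)))))
  g <- ifelse(i == 0, tt, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, tt,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}
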