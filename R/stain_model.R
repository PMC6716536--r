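# Beer-Lambert color physics: conversions between 8-bit RGB intensity and
# optical density (absorbance), and rendering from stain + concentration.
# Convention: natural logarithm; background intensity I0 defaults to 255.

assertRGBImage <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("an RGB image must be an H x W x 3 array")
  if (min(img) < 0 || max(img) > 255)
    stop("RGB intensities must lie in [0, 255]")
  invisible(img)
}

#' Convert an RGB image to optical density
#'
#' Inverts the Beer-Lambert transmission model I_c = I0 * exp(-OD_c):
#' OD_c = -ln(I_c / I0). Raw intensity 0 is clamped to 1 before the
#' logarithm so absorbance stays bounded; intensities above the background
#' are clamped to the background so absorbance is non-negative.
#'
#' @param img H x W x 3 array of intensities in \[0, 255\].
#' @param background background (white) intensity I0, > 0; default 255.
#' @return H x W x 3 array of non-negative absorbances.
#' @examples
#' od <- rgbToOD(array(94, c(2, 2, 3)))
#' stopifnot(abs(od[1] - (-log(94 / 255))) < 1e-12)
#' @export
rgbToOD <- function(img, background = 255) {
  if (length(background) != 1 || !is.finite(background) || background <= 0)
    stop("background intensity must be a positive scalar")
  assertRGBImage(img)
  od <- -log(pmin(pmax(img, 1), background) / background)
  array(od, dim(img))
}

#' Convert optical density to an RGB image
#'
#' Applies I_c = I0 * exp(-OD_c), rounds to integer levels and clips to
#' \[0, 255\].
#'
#' @param od H x W x 3 array of non-negative absorbances.
#' @param background background intensity I0; default 255.
#' @return H x W x 3 array of integer intensities in \[0, 255\].
#' @export
odToRGB <- function(od, background = 255) {
  if (length(background) != 1 || !is.finite(background) || background <= 0)
    stop("background intensity must be a positive scalar")
  if (!is.array(od) || length(dim(od)) != 3 || dim(od)[3] != 3)
    stop("od must be an H x W x 3 array")
  if (min(od) < -1e-9) stop("absorbance must be non-negative")
  img <- round(background * exp(-pmax(od, 0)))
  array(pmin(pmax(img, 0), 255), dim(od))
}

#' Render an RGB patch from a stain matrix and a concentration map
#'
#' Per pixel, OD = C . S (length-2 concentration vector times the 2 x 3
#' stain matrix), then the Beer-Lambert transmission I_c = I0 exp(-OD_c).
#'
#' @param stain a [StainMatrix-class].
#' @param conc H x W x 2 array of non-negative concentrations
#'   (hematoxylin, eosin).
#' @param background background intensity I0; default 255.
#' @return H x W x 3 integer RGB array.
#' @examples
#' conc <- array(0, c(4, 4, 2)); conc[, , 1] <- 1
#' img <- renderPatch(canonicalStains(), conc)
#' @export
renderPatch <- function(stain, conc, background = 255) {
  stopifnot(is(stain, "StainMatrix"))
  if (!is.array(conc) || length(dim(conc)) != 3 || dim(conc)[3] != 2)
    stop("conc must be an H x W x 2 array")
  if (min(conc) < 0) stop("concentrations must be non-negative")
  d <- dim(conc)
  od <- matrix(conc, ncol = 2) %*% stain@coefficients
  odToRGB(array(od, c(d[1], d[2], 3)), background)
}

#' Read / write 8-bit RGB patches (PNG or TIFF)
#'
#' Thin wrappers mapping between files and the package's H x W x 3
#' \[0, 255\] array convention. The format is taken from the file extension.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return `readPatch` returns an H x W x 3 array in \[0, 255\].
#' @export
readPatch <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext))
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  out <- round(x[, , 1:3, drop = FALSE] * 255)
  array(as.integer(out), dim(out))
}

#' @rdname readPatch
#' @param img H x W x 3 array in \[0, 255\].
#' @export
writePatch <- function(img, path) {
  assertRGBImage(img)
  ext <- tolower(tools::file_ext(path))
  x <- img / 255
  switch(ext,
         png = png::writePNG(x, path),
         tif = ,
         tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
         stop("unsupported image format: ", ext))
  invisible(path)
}
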