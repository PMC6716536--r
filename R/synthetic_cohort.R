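# Synthetic multi-center H&E-like patch cohort. Class signal lives in
# nuclear morphology (blob size/density carried by the hematoxylin
# concentration channel); center identity lives exclusively in color
# (per-center stain matrix, brightness offset, channel gains, pixel noise),
# so color carries domain but not class.

#' Configuration of a synthetic multi-center cohort
#'
#' Defaults encode the study conditions: 3 training centers shared by the
#' train / validation / internal-test partitions and 1 external center with
#' stain, gain and brightness parameters outside the training centers'
#' range; 64 x 64 patches; a 1:4 positive:negative class ratio.
#'
#' Class morphology: negatives carry more and smaller nucleus-like blobs,
#' positives fewer and larger ones, with overlapping count/size ranges
#' (realistic task difficulty) and near-matched expected total hematoxylin
#' mass so mean color is nearly class-blind while spatial structure is
#' class-informative.
#'
#' @param nCentersTrain number of training-side centers (serve train,
#'   validation and internal test).
#' @param nCentersExternal number of external-test centers.
#' @param nPatches named vector: patches per center for each partition.
#' @param patchSize patch edge length in pixels (even).
#' @param classRatio positive-class fraction in every partition.
#' @param blobCount0,blobCount1 integer count ranges for negative / positive
#'   patches.
#' @param blobRadius0,blobRadius1 blob radius ranges (pixels).
#' @param blobEcc maximal axis-ratio eccentricity of the elliptical blobs.
#' @param blobAmp amplitude range of blob hematoxylin concentration.
#' @param withinShiftDeg maximal angular stain perturbation (degrees) of a
#'   training center from the canonical H&E vectors.
#' @param externalShiftDeg angular stain perturbation of external centers;
#'   must exceed `withinShiftDeg`.
#' @param brightnessRange additive brightness-offset range of training
#'   centers (intensity levels).
#' @param externalBrightnessMag magnitude range of external centers'
#'   brightness offset (sign random); lies outside `brightnessRange`.
#' @param gainRange multiplicative channel-gain range of training centers.
#' @param externalGainMag magnitude range of external centers' gain
#'   deviation from 1 (sign random per channel); outside `gainRange`.
#' @param noiseSd Gaussian pixel-noise standard deviation (levels).
#' @param background background intensity I0.
#' @param seed integer seed; the cohort is a pure function of this config.
#' @return A validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nCentersTrain = 3L, nCentersExternal = 1L,
                         nPatches = c(train = 400L, validation = 60L,
                                      internal_test = 120L,
                                      external_test = 640L),
                         patchSize = 64L, classRatio = 0.2,
                         blobCount0 = c(9L, 16L), blobCount1 = c(5L, 9L),
                         blobRadius0 = c(1.8, 3.2), blobRadius1 = c(2.6, 4.4),
                         blobEcc = 1.6, blobAmp = c(0.8, 1.4),
                         withinShiftDeg = 4, externalShiftDeg = 32,
                         brightnessRange = c(-10, 10),
                         externalBrightnessMag = c(25, 40),
                         gainRange = c(0.92, 1.08),
                         externalGainMag = c(0.20, 0.35),
                         noiseSd = 3, background = 255, seed = 1L) {
  cfg <- list(nCentersTrain = as.integer(nCentersTrain),
              nCentersExternal = as.integer(nCentersExternal),
              nPatches = nPatches, patchSize = as.integer(patchSize),
              classRatio = classRatio, blobCount0 = blobCount0,
              blobCount1 = blobCount1, blobRadius0 = blobRadius0,
              blobRadius1 = blobRadius1, blobEcc = blobEcc,
              blobAmp = blobAmp, withinShiftDeg = withinShiftDeg,
              externalShiftDeg = externalShiftDeg,
              brightnessRange = brightnessRange,
              externalBrightnessMag = externalBrightnessMag,
              gainRange = gainRange, externalGainMag = externalGainMag,
              noiseSd = noiseSd, background = background,
              seed = as.integer(seed))
  parts <- c("train", "validation", "internal_test", "external_test")
  if (!all(parts %in% names(cfg$nPatches)))
    stop("nPatches must name the four partitions: ",
         paste(parts, collapse = ", "))
  if (cfg$nCentersTrain < 1L || cfg$nCentersExternal < 1L)
    stop("at least one center is required per partition side")
  if (cfg$classRatio <= 0 || cfg$classRatio >= 1)
    stop("classRatio must lie strictly in (0, 1)")
  if (cfg$externalShiftDeg <= cfg$withinShiftDeg)
    stop("externalShiftDeg must exceed withinShiftDeg")
  if (cfg$patchSize < 16L || cfg$patchSize %% 2L != 0L)
    stop("patchSize must be an even integer >= 16")
  class(cfg) <- "CohortConfig"
  cfg
}

#' Generate center appearance profiles
#'
#' Training centers perturb the canonical H&E stain vectors by random small
#' angles (up to `withinShiftDeg`) and draw gains / brightness from the
#' training ranges; external centers rotate the stain vectors by exactly
#' `externalShiftDeg` and draw gains / brightness outside the training
#' ranges. Rotation directions are rejection-sampled so each rotated row
#' stays closer to its own canonical stain identity than to the other's
#' (eosin remains eosin-like) and the rows stay well separated.
#' Deterministic given `config$seed`.
#'
#' @param config a [cohortConfig()].
#' @return list of [CenterProfile-class]; external centers named `"EXT*"`.
#' @export
makeCenters <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  base <- stainCoefficients(canonicalStains())
  # rotate the H and E rows by the requested angles while keeping the pair
  # physically identifiable: each rotated row stays closer to its own
  # canonical identity than to the other stain's (eosin remains
  # eosin-like), and the rows stay well separated
  rotatePair <- function(degH, degE) {
    for (t in seq_len(200)) {
      H2 <- rotateStainVector(base[1, ], degH)
      E2 <- rotateStainVector(base[2, ], degE)
      if (angleDeg(H2, base[1, ]) < angleDeg(H2, base[2, ]) - 5 &&
          angleDeg(E2, base[2, ]) < angleDeg(E2, base[1, ]) - 5 &&
          angleDeg(H2, E2) >= 15) return(rbind(H2, E2))
    }
    stop("could not draw an identifiable stain pair at shift ", degH)
  }
  withSeed(config$seed, {
    centers <- vector("list", config$nCentersTrain + config$nCentersExternal)
    for (i in seq_len(config$nCentersTrain)) {
      st <- StainMatrix(rotatePair(runif(1, 0, config$withinShiftDeg),
                                   runif(1, 0, config$withinShiftDeg)))
      centers[[i]] <- new("CenterProfile", centerId = paste0("C", i),
                          stain = st,
                          brightnessOffset = runif(1,
                            config$brightnessRange[1],
                            config$brightnessRange[2]),
                          channelGain = runif(3, config$gainRange[1],
                                              config$gainRange[2]),
                          noiseSd = config$noiseSd)
    }
    for (j in seq_len(config$nCentersExternal)) {
      st <- StainMatrix(rotatePair(config$externalShiftDeg,
                                   config$externalShiftDeg))
      gain <- 1 + sample(c(-1, 1), 3, replace = TRUE) *
        runif(3, config$externalGainMag[1], config$externalGainMag[2])
      off <- sample(c(-1, 1), 1) * runif(1, config$externalBrightnessMag[1],
                                         config$externalBrightnessMag[2])
      centers[[config$nCentersTrain + j]] <-
        new("CenterProfile", centerId = paste0("EXT", j), stain = st,
            brightnessOffset = off, channelGain = gain,
            noiseSd = config$noiseSd)
    }
    centers
  })
}

# Additive anti-aliased elliptical Gaussian blob field.
blobField <- function(size, counts, radii, ecc, amp) {
  n <- if (counts[1] >= counts[2]) counts[1] else
    sample(counts[1]:counts[2], 1)
  f <- matrix(0, size, size)
  if (n == 0) return(f)
  X <- matrix(seq_len(size), size, size, byrow = TRUE)
  Y <- matrix(seq_len(size), size, size)
  for (b in seq_len(n)) {
    cx <- runif(1, 1, size); cy <- runif(1, 1, size)
    r <- runif(1, radii[1], radii[2])
    s <- runif(1, 1, ecc)
    th <- runif(1, 0, pi)
    A <- runif(1, amp[1], amp[2])
    dx <- X - cx; dy <- Y - cy
    xr <- cos(th) * dx + sin(th) * dy
    yr <- -sin(th) * dx + cos(th) * dy
    q <- (xr / (r * s))^2 + (yr / (r / s))^2
    f <- f + A * exp(-1.5 * q)
  }
  f
}

#' Generate one labeled synthetic patch for a center
#'
#' Builds a two-channel concentration map (smooth eosin stroma texture plus
#' class-dependent hematoxylin blobs, with eosin attenuated inside blobs
#' because nuclei displace cytoplasm), renders it through the center's stain
#' matrix, then applies the center's channel gains, brightness offset and
#' Gaussian pixel noise. Uses the caller's RNG stream.
#'
#' @param center a [CenterProfile-class].
#' @param taskLabel 0 or 1.
#' @param config a [cohortConfig()].
#' @param returnConc also return the concentration map.
#' @return list with `image` (H x W x 3 integer array), `taskLabel`,
#'   `domainLabel`, `x`, `y` and optionally `conc`.
#' @export
makePatch <- function(center, taskLabel, config, returnConc = FALSE) {
  size <- config$patchSize
  eos <- upsampleGrid(matrix(runif(49, 0.18, 0.42), 7, 7), size)
  haze <- upsampleGrid(matrix(runif(36, 0, 0.03), 6, 6), size)
  if (taskLabel == 1)
    blobs <- blobField(size, config$blobCount1, config$blobRadius1,
                       config$blobEcc, config$blobAmp)
  else
    blobs <- blobField(size, config$blobCount0, config$blobRadius0,
                       config$blobEcc, config$blobAmp)
  cH <- blobs + haze
  cE <- eos * exp(-2 * cH)
  conc <- array(c(cH, cE), c(size, size, 2))
  img <- renderPatch(center@stain, conc, config$background)
  img <- sweep(img, 3, center@channelGain, `*`) + center@brightnessOffset
  if (center@noiseSd > 0)
    img <- img + rnorm(length(img), sd = center@noiseSd)
  img <- array(as.integer(round(clip255(img))), dim(img))
  out <- list(image = img, x = 0L, y = 0L, taskLabel = as.integer(taskLabel),
              domainLabel = center@centerId, partition = NA_character_)
  if (returnConc) out$conc <- conc
  out
}

#' Generate a full multi-center cohort with manifest
#'
#' Populates the four partitions with the configured per-center counts and
#' class ratio: train / validation / internal test share the training
#' centers; external test uses the disjoint external centers. The whole
#' cohort is a pure function of the config (including its seed).
#'
#' @param config a [cohortConfig()].
#' @param dir optional directory; when given, patches are written as PNG
#'   files and a `manifest.csv` (path, x, y, task_label, domain_label,
#'   partition) is written alongside.
#' @return list of class `Cohort`: `images` (list of H x W x 3 integer
#'   arrays), `manifest` (data.frame with columns path, x, y, task_label,
#'   domain_label, partition), `centers`, `config`.
#' @export
makeCohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "CohortConfig"))
  centers <- makeCenters(config)
  isExt <- grepl("^EXT", vapply(centers, function(p) p@centerId, ""))
  images <- list(); rows <- list(); k <- 0L
  withSeed(config$seed + 1L, {
    for (part in c("train", "validation", "internal_test", "external_test")) {
      useCenters <- centers[if (part == "external_test") isExt else !isExt]
      n <- as.integer(config$nPatches[[part]])
      nPos <- as.integer(round(config$classRatio * n))
      labels <- c(rep(1L, nPos), rep(0L, n - nPos))
      for (ct in useCenters) {
        for (lab in labels) {
          k <- k + 1L
          rec <- makePatch(ct, lab, config)
          images[[k]] <- rec$image
          rows[[k]] <- data.frame(path = NA_character_, x = 0L, y = 0L,
                                  task_label = lab,
                                  domain_label = ct@centerId,
                                  partition = part,
                                  stringsAsFactors = FALSE)
        }
      }
    }
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- sprintf("%s/%s_%s_%05d.png", dir, manifest$partition,
                     manifest$domain_label, seq_len(nrow(manifest)))
    for (i in seq_along(images)) writePatch(images[[i]], paths[i])
    manifest$path <- paths
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(images = images, manifest = manifest, centers = centers,
                 config = config), class = "Cohort")
}

#' Concentration phantom for stain-estimator validation
#'
#' A concentration map containing near-pure hematoxylin bands, near-pure
#' eosin bands and mixed pixels, spanning the full angular cone between the
#' two stain vectors. Rendering it through a known stain matrix gives an
#' image from which Macenko-type estimation should recover the generating
#' rows.
#'
#' @param size patch edge length.
#' @return H x W x 2 non-negative concentration array (uses the caller's
#'   RNG stream).
#' @export
deconvolutionPhantom <- function(size = 64) {
  third <- floor(size / 3)
  cH <- matrix(0, size, size); cE <- matrix(0, size, size)
  cH[seq_len(third), ] <- runif(third * size, 0.3, 1.6)
  cE[(third + 1):(2 * third), ] <- runif(third * size, 0.3, 1.4)
  mixRows <- (2 * third + 1):size
  cH[mixRows, ] <- runif(length(mixRows) * size, 0, 1.2)
  cE[mixRows, ] <- runif(length(mixRows) * size, 0, 1.0)
  array(c(cH, cE), c(size, size, 2))
}
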