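test_that("brightness standardization maps mid-gray to white and is idempotent", {
  g <- array(128, c(8, 8, 3))
  expect_true(all(standardizeBrightness(g) == 255))
  set.seed(14)
  conc <- phantomWithBackground(32)
  img <- renderPatch(canonicalStains(), conc)
  once <- standardizeBrightness(img)
  twice <- standardizeBrightness(once)
  expect_lte(max(abs(twice - once)), 1)
  # an image whose 95th-percentile lightness is already maximal is untouched
  bright <- img; bright[1:10, , ] <- 255
  expect_lte(max(abs(standardizeBrightness(bright) - bright)), 1)
})

test_that("Macenko estimation recovers generating stain matrices", {
  set.seed(40)
  errs <- vapply(1:20, function(i) {
    S <- randomStainMatrix()
    img <- renderPatch(S, deconvolutionPhantom(48))
    stainAngleError(estimateStainMatrix(img), S)
  }, 0)
  expect_lt(median(errs), 2)
})

test_that("estimation survives 1% multiplicative pixel noise within 5 degrees", {
  set.seed(41)
  errs <- vapply(1:20, function(i) {
    S <- randomStainMatrix()
    img <- renderPatch(S, deconvolutionPhantom(48))
    noisy <- pmin(pmax(round(img * (1 + rnorm(length(img), sd = 0.01))), 0),
                  255)
    stainAngleError(estimateStainMatrix(noisy), S)
  }, 0)
  expect_lt(median(errs), 5)
})

test_that("estimation is permutation-invariant and rejects degenerate input", {
  set.seed(42)
  img <- renderPatch(canonicalStains(), deconvolutionPhantom(32))
  est <- estimateStainMatrix(img)
  perm <- sample(32 * 32)
  permImg <- array(apply(img, 3, function(ch) ch[perm]), c(32, 32, 3))
  expect_equal(stainCoefficients(estimateStainMatrix(permImg)),
               stainCoefficients(est), tolerance = 1e-9)
  # pure single-stain image: OD collinear, plane undefined
  single <- array(0, c(16, 16, 2)); single[, , 1] <- runif(256, 0.5, 1.5)
  expect_error(estimateStainMatrix(renderPatch(canonicalStains(), single)),
               "collinear|degenerate")
  expect_error(estimateStainMatrix(array(255, c(16, 16, 3))),
               "too few tissue pixels")
})

test_that("canonical rows are labeled by red absorbance (H first)", {
  set.seed(43)
  img <- renderPatch(canonicalStains(), deconvolutionPhantom(48))
  est <- stainCoefficients(estimateStainMatrix(img))
  truth <- stainCoefficients(canonicalStains())
  expect_lt(angleDeg(est[1, ], truth[1, ]), 3)  # hematoxylin row
  expect_lt(angleDeg(est[2, ], truth[2, ]), 3)  # eosin row
})

test_that("concentration estimation inverts rendering and clips negatives", {
  S <- canonicalStains()
  uniform <- array(rep(c(1.3, 0.4), each = 24 * 24), c(24, 24, 2))
  conc <- estimateConcentrations(renderPatch(S, uniform), S)
  expect_lt(max(abs(conc - uniform)), 1e-2)
  bg <- estimateConcentrations(array(255, c(4, 4, 3)), S)
  expect_true(all(bg == 0))
  set.seed(44)
  noisy <- array(sample(0:255, 10 * 10 * 3, replace = TRUE), c(10, 10, 3))
  expect_true(all(estimateConcentrations(noisy, S) >= 0))
})

test_that("fitTemplate is deterministic with positive robust scales", {
  set.seed(45)
  img <- renderPatch(canonicalStains(), phantomWithBackground(48))
  t1 <- fitTemplate(img); t2 <- fitTemplate(img)
  expect_equal(stainCoefficients(t1@stain), stainCoefficients(t2@stain))
  expect_identical(t1@maxConc, t2@maxConc)
  expect_true(all(t1@maxConc > 0))
  # template of a center patch reproduces that center's stain rows
  cfg <- cohortConfig()
  ct <- makeCenters(cfg)[[2]]
  imgC <- renderPatch(ct@stain, phantomWithBackground(64))
  expect_lt(stainAngleError(fitTemplate(imgC)@stain, ct@stain), 5)
})

test_that("normalization is a fixed point on the template and idempotent", {
  set.seed(46)
  conc <- phantomWithBackground(64)
  img <- renderPatch(canonicalStains(), conc)
  tpl <- fitTemplate(img)
  n1 <- normalizeStains(img, tpl)
  expect_lte(mean(abs(n1 - img)), 2)
  n2 <- normalizeStains(n1, tpl)
  expect_lte(mean(abs(n2 - n1)), 2)
  expect_true(all(n1 >= 0 & n1 <= 255))
})

test_that("patches sharing concentrations converge under normalization", {
  cfg <- cohortConfig()
  centers <- makeCenters(cfg)
  set.seed(47)
  conc <- phantomWithBackground(64)
  tpl <- fitTemplate(renderPatch(centers[[2]]@stain, conc))
  imgA <- renderPatch(centers[[1]]@stain, conc)
  imgB <- renderPatch(centers[[4]]@stain, conc)  # external center
  nA <- normalizeStains(imgA, tpl)
  nB <- normalizeStains(imgB, tpl)
  expect_lte(mean(abs(nA - nB)), 3)
})

test_that("normalization shrinks between-center color variance on a cohort", {
  cfg <- cohortConfig(nPatches = c(train = 24L, validation = 4L,
                                   internal_test = 6L, external_test = 8L),
                      seed = 19)
  coh <- makeCohort(cfg)
  tr <- which(coh$manifest$partition == "train")
  dom <- coh$manifest$domain_label[tr]
  betweenVar <- function(imgs) {
    m <- t(vapply(imgs, function(im) apply(im, 3, mean), numeric(3)))
    gm <- colMeans(m)
    sum(vapply(split(seq_len(nrow(m)), dom), function(ix)
      length(ix) * sum((colMeans(m[ix, , drop = FALSE]) - gm)^2), 0)) / nrow(m)
  }
  v0 <- betweenVar(coh$images[tr])
  tpl <- fitTemplate(coh$images[[tr[1]]])
  v1 <- betweenVar(lapply(coh$images[tr], normalizeStains, template = tpl))
  expect_lte(v1 / v0, 0.25)
})

test_that("templates survive a JSON round trip", {
  set.seed(48)
  tpl <- fitTemplate(renderPatch(canonicalStains(), phantomWithBackground(32)))
  path <- tempfile(fileext = ".json")
  writeTemplate(tpl, path)
  back <- readTemplate(path)
  expect_equal(stainCoefficients(back@stain), stainCoefficients(tpl@stain),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back@maxConc, tpl@maxConc, tolerance = 1e-12)
  unlink(path)
})

test_that("normalization failures carry the source identifier", {
  tpl <- new("NormalizationTemplate", stain = canonicalStains(),
             maxConc = c(1, 1), background = 255)
  blank <- array(255, c(16, 16, 3))
  expect_error(normalizeStains(blank, tpl, sourceId = "slide-07"),
               "slide-07")
})
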