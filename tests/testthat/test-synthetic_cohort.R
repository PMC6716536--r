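test_that("center generation is deterministic and respects the shift contract", {
  cfg <- cohortConfig(seed = 7)
  c1 <- makeCenters(cfg)
  c2 <- makeCenters(cfg)
  expect_equal(lapply(c1, function(p) stainCoefficients(p@stain)),
               lapply(c2, function(p) stainCoefficients(p@stain)))
  canon <- stainCoefficients(canonicalStains())
  isExt <- grepl("^EXT", vapply(c1, function(p) p@centerId, ""))
  # every external stain row is at least external - within degrees from
  # every training row of the same stain
  for (ext in c1[isExt]) for (tr in c1[!isExt]) for (r in 1:2) {
    expect_gte(angleDeg(stainCoefficients(ext@stain)[r, ],
                        stainCoefficients(tr@stain)[r, ]),
               cfg$externalShiftDeg - cfg$withinShiftDeg - 1e-6)
  }
  # zero external shift keeps external rows within the training range
  cfg0 <- cohortConfig(withinShiftDeg = 4, externalShiftDeg = 4.0001, seed = 7)
  for (ext in makeCenters(cfg0)[4]) for (r in 1:2)
    expect_lte(angleDeg(stainCoefficients(ext@stain)[r, ], canon[r, ]), 4.1)
})

test_that("config invariants are enforced", {
  expect_error(cohortConfig(externalShiftDeg = 3, withinShiftDeg = 4),
               "exceed")
  expect_error(cohortConfig(classRatio = 0), "strictly")
  expect_error(cohortConfig(nCentersTrain = 0), "at least one center")
})

test_that("patch generation is a pure function of the RNG state", {
  cfg <- cohortConfig(patchSize = 32L)
  ct <- makeCenters(cfg)[[1]]
  p1 <- withr::with_seed(5, makePatch(ct, 1L, cfg))
  p2 <- withr::with_seed(5, makePatch(ct, 1L, cfg))
  expect_identical(p1$image, p2$image)
  expect_identical(p1$taskLabel, 1L)
  expect_identical(p1$domainLabel, "C1")
})

test_that("positive patches carry more hematoxylin on average", {
  cfg <- cohortConfig(patchSize = 32L)
  ct <- makeCenters(cfg)[[1]]
  set.seed(61)
  m0 <- replicate(100, mean(makePatch(ct, 0L, cfg, returnConc = TRUE)$conc[, , 1]))
  m1 <- replicate(100, mean(makePatch(ct, 1L, cfg, returnConc = TRUE)$conc[, , 1]))
  expect_gt(mean(m1), mean(m0))
})

test_that("cohort bookkeeping: counts, ratio, partitions, determinism", {
  cfg <- cohortConfig(nPatches = c(train = 20L, validation = 8L,
                                   internal_test = 10L, external_test = 12L),
                      patchSize = 16L, seed = 3)
  coh <- makeCohort(cfg)
  man <- coh$manifest
  expect_identical(nrow(man), 3L * (20L + 8L + 10L) + 12L)
  expect_identical(length(coh$images), nrow(man))
  for (p in unique(man$partition)) {
    sub <- man[man$partition == p, ]
    expect_lte(abs(mean(sub$task_label) - 0.2),
               0.5 / min(table(sub$domain_label)))
  }
  # external domains disjoint from training-side domains
  extDoms <- unique(man$domain_label[man$partition == "external_test"])
  intDoms <- unique(man$domain_label[man$partition != "external_test"])
  expect_length(intersect(extDoms, intDoms), 0)
  # full reproducibility from the config
  coh2 <- makeCohort(cfg)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$images[[37]], coh2$images[[37]])
})

test_that("task label is independent of center within partitions", {
  coh <- smallCohort(seed = 23)
  man <- coh$manifest[coh$manifest$partition != "external_test", ]
  tab <- table(man$domain_label, man$task_label)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("mean color carries the center but not the class", {
  cfg <- cohortConfig(nPatches = c(train = 100L, validation = 4L,
                                   internal_test = 6L, external_test = 8L),
                      patchSize = 32L, seed = 29)
  coh <- makeCohort(cfg)
  tr <- which(coh$manifest$partition == "train")
  feats <- t(vapply(coh$images[tr], function(im) apply(im, 3, mean),
                    numeric(3)))
  dom <- factor(coh$manifest$domain_label[tr])
  fitD <- nnet::multinom(dom ~ ., data.frame(dom, feats), trace = FALSE)
  expect_gte(mean(predict(fitD) == dom), 0.9)
  # class probe within a single center: held-out, class-balanced accuracy
  # (chance = 0.5; the raw 1:4 prior would let a majority vote score 0.8)
  one <- tr[coh$manifest$domain_label[tr] == "C1"]
  y <- coh$manifest$task_label[one]
  pos <- which(y == 1)
  neg <- withr::with_seed(2, sample(which(y == 0), length(pos)))
  sel <- c(pos, neg); yb <- y[sel]
  X <- t(vapply(coh$images[one[sel]], function(im) apply(im, 3, mean),
                numeric(3)))
  half <- withr::with_seed(1, sample(length(sel), length(sel) %/% 2))
  dfC <- data.frame(y = yb, X)
  fitC <- suppressWarnings(glm(y ~ ., dfC, family = binomial, subset = half))
  predC <- predict(fitC, newdata = dfC[-half, ], type = "response")
  expect_lte(mean((predC > 0.5) == yb[-half]), 0.6)
})

test_that("Macenko estimation recovers a noiseless center's stain rows", {
  cfg <- cohortConfig(noiseSd = 0, patchSize = 64L, seed = 31)
  ct <- makeCenters(cfg)[[1]]
  set.seed(31)
  p <- makePatch(ct, 1L, cfg)
  expect_lt(stainAngleError(estimateStainMatrix(p$image), ct@stain), 5)
})

test_that("cohorts can be written to disk with a manifest", {
  dir <- tempfile("cohort_")
  cfg <- cohortConfig(nPatches = c(train = 4L, validation = 2L,
                                   internal_test = 2L, external_test = 2L),
                      patchSize = 16L, seed = 13)
  coh <- makeCohort(cfg, dir = dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), nrow(coh$manifest))
  expect_true(all(file.exists(man$path)))
  expect_identical(readPatch(man$path[1]), coh$images[[1]], )
  unlink(dir, recursive = TRUE)
})
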