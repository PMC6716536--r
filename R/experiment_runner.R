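# Orchestration of the strategy grid (color augmentation x stain
# normalization x domain-adversarial training) across seeds on a cohort,
# mirroring the multi-column internal/external comparison design at desk
# scale.

#' Define an experiment plan over the strategy grid
#'
#' @param cohort a `Cohort` from [makeCohort()].
#' @param combinations data.frame with logical columns `ca` (color
#'   augmentation), `sn` (stain normalization), `dann` (adversarial
#'   training), one row per method combination; defaults to baseline +
#'   each single strategy. [fullGrid()] gives all combinations reported in
#'   multi-strategy comparisons.
#' @param seeds integer vector of model-initialization seeds, default 4.
#' @param train a [trainConfig()].
#' @param aug an [augmentationConfig()] used when `ca` is set.
#' @param spec an [architectureSpec()]; defaults to the cohort patch size.
#' @param templateIndex index (into the cohort's train partition) of the
#'   normalization template image used when `sn` is set.
#' @param externalDomainsForDann when `TRUE` (default), adversarial runs
#'   also feed the external-partition images as domain-only (n') samples:
#'   their center labels join the domain head's classes but their task
#'   labels are never touched, so the trunk learns invariance that covers
#'   the shifted center (the semi-supervised adaptation mode of the DANN
#'   objective). Baselines never see these images.
#' @param outputDir run directory; `configs/`, `predictions/` and
#'   `results/` are created beneath it.
#' @return validated list of class `ExperimentPlan`.
#' @export
experimentPlan <- function(cohort,
                           combinations = data.frame(
                             ca = c(FALSE, TRUE, FALSE, FALSE),
                             sn = c(FALSE, FALSE, TRUE, FALSE),
                             dann = c(FALSE, FALSE, FALSE, TRUE)),
                           seeds = 1:4, train = trainConfig(),
                           aug = augmentationConfig(),
                           spec = NULL, templateIndex = 1L,
                           externalDomainsForDann = TRUE,
                           outputDir = tempfile("stainshift_run_")) {
  stopifnot(inherits(cohort, "Cohort"))
  stopifnot(all(c("ca", "sn", "dann") %in% names(combinations)))
  if (anyDuplicated(combinations)) stop("combinations must be unique")
  if (is.null(spec)) {
    ps <- cohort$config$patchSize
    spec <- architectureSpec(inputSize = c(ps, ps, 3L))
  }
  structure(list(cohort = cohort, combinations = combinations,
                 seeds = as.integer(seeds), train = train, aug = aug,
                 spec = spec, templateIndex = as.integer(templateIndex),
                 externalDomainsForDann = isTRUE(externalDomainsForDann),
                 outputDir = outputDir), class = "ExperimentPlan")
}

#' @rdname experimentPlan
#' @return `fullGrid()`: the 8-row data.frame of all strategy combinations
#'   (baseline, the three single strategies, the pairs, and all three
#'   together).
#' @export
fullGrid <- function() {
  g <- expand.grid(ca = c(FALSE, TRUE), sn = c(FALSE, TRUE),
                   dann = c(FALSE, TRUE))
  g[order(g$ca + g$sn + g$dann), ]
}

methodTag <- function(row) {
  tags <- c("CA", "SN", "DANN")[c(row$ca, row$sn, row$dann)]
  if (length(tags) == 0) "baseline" else paste(tags, collapse = "+")
}

#' Run an experiment plan
#'
#' For each method combination and seed: optionally stain-normalize all
#' partitions offline against the plan's template image, build the model
#' (adversarial when the `dann` flag is set), train with optional online
#' color augmentation, and evaluate F1 and AUC on the internal and external
#' test partitions. Per-seed raw predictions, frozen configs and the
#' aggregated results table are written beneath `outputDir`. Failures in a
#' cell are recorded and remaining cells continue.
#'
#' @param plan an [experimentPlan()].
#' @param verbose print per-cell progress.
#' @return list with `runs` (per-seed tidy data.frame), `results`
#'   (aggregated mean/sd via [aggregateResults()]), `table` (formatted
#'   character matrix), `errors` (per-cell failure messages), `outputDir`.
#' @export
runExperiment <- function(plan, verbose = FALSE) {
  stopifnot(inherits(plan, "ExperimentPlan"))
  cohort <- plan$cohort
  man <- cohort$manifest
  for (d in c("configs", "predictions", "results"))
    dir.create(file.path(plan$outputDir, d), recursive = TRUE,
               showWarnings = FALSE)
  trainIdx <- which(man$partition == "train")
  valIdx <- which(man$partition == "validation")
  evalParts <- c(internal = "internal_test", external = "external_test")
  needSN <- any(plan$combinations$sn)
  normCache <- NULL
  template <- NULL
  if (needSN) {
    template <- fitTemplate(cohort$images[[trainIdx[plan$templateIndex]]])
    writeTemplate(template, file.path(plan$outputDir, "configs",
                                      "template.json"))
  }
  runs <- list(); errors <- list(); k <- 0L
  for (ci in seq_len(nrow(plan$combinations))) {
    comb <- plan$combinations[ci, ]
    tag <- methodTag(comb)
    if (comb$sn && is.null(normCache)) {
      normCache <- lapply(seq_along(cohort$images), function(i)
        tryCatch(normalizeStains(cohort$images[[i]], template,
                                 sourceId = i),
                 error = function(e) cohort$images[[i]]))
    }
    images <- if (comb$sn) normCache else cohort$images
    extIdx <- which(man$partition == "external_test")
    useExt <- isTRUE(comb$dann) && plan$externalDomainsForDann
    trainDomains <- unique(man$domain_label[trainIdx])
    nDomains <- length(trainDomains) +
      if (useExt) length(unique(man$domain_label[extIdx])) else 0L
    for (sd_i in seq_along(plan$seeds)) {
      seed <- plan$seeds[sd_i]
      k <- k + 1L
      cell <- sprintf("%s_seed%d", tag, seed)
      if (verbose) message("running ", cell)
      res <- tryCatch({
        model <- buildModel(plan$spec, nDomains = nDomains,
                            adversarial = isTRUE(comb$dann), seed = seed)
        cfg <- plan$train
        cfg$seed <- seed
        if (cfg$batchSize %% nDomains != 0L)  # keep domain-balanced quota
          cfg$batchSize <- nDomains * (cfg$batchSize %/% nDomains + 1L)
        model <- trainModel(model, images[trainIdx],
                            man$task_label[trainIdx],
                            man$domain_label[trainIdx], cfg,
                            augConfig = if (isTRUE(comb$ca)) plan$aug,
                            valImages = images[valIdx],
                            valLabels = man$task_label[valIdx],
                            domainOnlyImages =
                              if (useExt) images[extIdx],
                            domainOnlyDomains =
                              if (useExt) man$domain_label[extIdx])
        pv <- predictProb(model, images[valIdx])
        threshold <- optimalThreshold(man$task_label[valIdx], pv)
        jsonlite::write_json(
          list(method = tag, seed = seed, flags = as.list(comb),
               train = unclass(cfg),
               lambdaSchedule = model@history$lambda),
          file.path(plan$outputDir, "configs", paste0(cell, ".json")),
          auto_unbox = TRUE, digits = NA)
        out <- list()
        for (pn in names(evalParts)) {
          idx <- which(man$partition == evalParts[[pn]])
          probs <- predictProb(model, images[idx])
          pred <- data.frame(id = idx, prob = probs,
                             task_label = man$task_label[idx],
                             domain_label = man$domain_label[idx],
                             partition = evalParts[[pn]], method = tag,
                             seed = seed)
          write.csv(pred, file.path(plan$outputDir, "predictions",
                                    sprintf("%s_%s.csv", cell, pn)),
                    row.names = FALSE)
          out[[pn]] <- data.frame(
            method = tag, seed = seed, partition = evalParts[[pn]],
            f1 = f1Score(man$task_label[idx], probs, threshold),
            auc = aucScore(man$task_label[idx], probs),
            threshold = threshold)
        }
        do.call(rbind, out)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[cell]] <- conditionMessage(res)
        if (verbose) message("  failed: ", conditionMessage(res))
      } else runs[[cell]] <- res
    }
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  results <- aggregateResults(runs)
  write.csv(runs, file.path(plan$outputDir, "results", "per_seed.csv"),
            row.names = FALSE)
  write.csv(results, file.path(plan$outputDir, "results", "aggregate.csv"),
            row.names = FALSE)
  tab <- formatResultsTable(results)
  write.csv(tab, file.path(plan$outputDir, "results", "table.csv"))
  list(runs = runs, results = results, table = tab, errors = errors,
       outputDir = plan$outputDir)
}
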