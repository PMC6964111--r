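# Experiment orchestration: simulate/load cohorts -> per-site k-fold split
# -> fit/train per fold on training subjects -> harmonize held-out subjects
# towards the reference -> fold-averaged evaluation. Every held-out subject
# is transformed by a model that never saw it; reference statistics used in
# evaluation come from training subjects only.

#' RunConfig: one reproducible harmonization experiment
#'
#' @slot method one of dualgan, global_scaling, voxel_scaling, combat.
#' @slot referenceSite site label every other site is mapped onto.
#' @slot k number of cross-validation folds.
#' @slot seed integer master seed.
#' @slot outputDir output directory ("" = do not write files).
#' @slot genConfig,discConfig,trainConfig dual-GAN settings (ignored by the
#'   conventional methods).
#' @slot groupTest logical; run voxel-wise group tests on the assembled
#'   harmonized cohort.
#' @slot nPermutations permutations for the group test.
#' @exportClass RunConfig
setClass("RunConfig", representation(
  method = "character", referenceSite = "character", k = "integer",
  seed = "integer", outputDir = "character", genConfig = "GeneratorConfig",
  discConfig = "DiscriminatorConfig", trainConfig = "TrainConfig",
  groupTest = "logical", nPermutations = "integer"
))

#' Build a run configuration
#'
#' @param method harmonization method.
#' @param referenceSite reference site label.
#' @param k folds (default 6).
#' @param seed master seed.
#' @param outputDir where to write reports ("" keeps everything in memory).
#' @param genConfig,discConfig,trainConfig dual-GAN settings.
#' @param groupTest run voxel-wise group tests (permutation max-stat).
#' @param nPermutations permutations for the group test.
#' @return a \linkS4class{RunConfig}.
#' @export
runConfig <- function(method = c("dualgan", "global_scaling", "voxel_scaling",
                                 "combat"),
                      referenceSite, k = 6L, seed = 1L, outputDir = "",
                      genConfig = generatorConfig(),
                      discConfig = discriminatorConfig(genConfig@kernelStyle),
                      trainConfig = dtigan::trainConfig(),
                      groupTest = FALSE, nPermutations = 500L) {
  method <- match.arg(method)
  new("RunConfig", method = method, referenceSite = referenceSite,
      k = as.integer(k), seed = as.integer(seed), outputDir = outputDir,
      genConfig = genConfig, discConfig = discConfig,
      trainConfig = trainConfig, groupTest = groupTest,
      nPermutations = as.integer(nPermutations))
}

#' Subset a cohort by subject ids
#' @param dataset a \linkS4class{SiteDataset}.
#' @param ids subject ids to keep.
#' @return a \linkS4class{SiteDataset} with the selected volumes.
#' @export
datasetSubset <- function(dataset, ids) {
  keep <- subjectIds(dataset) %in% ids
  if (!any(keep)) stop("subset selects no subjects")
  new("SiteDataset", site = dataset@site, volumes = dataset@volumes[keep],
      mask = dataset@mask)
}

fitFoldModel <- function(method, trainTarget, trainRef, mask, cfg, foldSeed) {
  switch(method,
    global_scaling = fitGlobalScaling(trainTarget, trainRef, mask),
    voxel_scaling = fitVoxelScaling(trainTarget, trainRef, mask),
    combat = fitCombat(list(trainRef, trainTarget), mask,
                       empiricalBayes = TRUE,
                       referenceSite = trainRef@site),
    dualgan = {
      tc <- cfg@trainConfig
      tc@seed <- foldSeed
      trainDualGAN(trainTarget, trainRef, cfg@genConfig, cfg@discConfig, tc)
    },
    stop("unknown method ", method))
}

applyFoldModel <- function(method, model, dataset) {
  if (method == "dualgan") harmonizeDataset(model, dataset, "AtoB")
  else applyHarmonizationToDataset(model, dataset)
}

#' Run a full harmonization experiment
#'
#' For each fold: fit the chosen method on training subjects of all sites,
#' harmonize the fold's held-out non-reference subjects towards the
#' reference, and evaluate their RMSE against the reference training group
#' mean. Assembled over folds this yields one harmonized cohort in which
#' every subject was transformed by a model that held it out. With more than
#' two sites, each non-reference site is trained pairwise against the
#' reference.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param datasets list of \linkS4class{SiteDataset}s (>= 2 sites, one being
#'   the reference).
#' @return list with elements \code{before} / \code{after}
#'   (\linkS4class{ErrorReport}s for the pooled non-reference cohort against
#'   the reference), \code{perFold} (per-fold reports), \code{harmonized}
#'   (assembled harmonized datasets by site), \code{models}, \code{split},
#'   and optionally \code{groupTestBefore} / \code{groupTestAfter}.
#' @export
runExperiment <- function(config, datasets) {
  stopifnot(is(config, "RunConfig"))
  if (is(datasets, "SiteDataset")) datasets <- list(datasets)
  sites <- vapply(datasets, siteLabel, "")
  names(datasets) <- sites
  if (!config@referenceSite %in% sites)
    stop("referenceSite '", config@referenceSite,
         "' is not among the supplied sites: ", paste(sites, collapse = ", "))
  if (length(sites) < 2) stop("need at least 2 sites")
  mask <- datasetMask(datasets[[1]])
  for (d in datasets) checkGeometry(datasetMask(d), mask, "site masks")

  reference <- datasets[[config@referenceSite]]
  targets <- datasets[setdiff(sites, config@referenceSite)]
  split <- kfoldSplit(datasets, config@k, seed = config@seed)
  assign_ <- foldAssignments(split)
  foldSeeds <- withSeed(config@seed, sample.int(2^30, config@k))

  perFold <- list()
  models <- list()
  harmonizedVols <- setNames(vector("list", length(targets)), names(targets))

  for (f in seq_len(config@k)) {
    heldOf <- function(s) assign_$subject_id[assign_$fold == f & assign_$site == s]
    trainOf <- function(s) assign_$subject_id[assign_$fold != f & assign_$site == s]
    trainRef <- datasetSubset(reference, trainOf(config@referenceSite))
    for (ts in names(targets)) {
      tgt <- targets[[ts]]
      stopifnot(!length(intersect(heldOf(ts), trainOf(ts))))   # leakage guard
      trainTgt <- datasetSubset(tgt, trainOf(ts))
      heldTgt <- datasetSubset(tgt, heldOf(ts))
      model <- fitFoldModel(config@method, trainTgt, trainRef, mask, config,
                            foldSeeds[f])
      models[[paste0("fold", f, "_", ts)]] <- model
      harm <- applyFoldModel(config@method, model, heldTgt)
      harmonizedVols[[ts]] <- c(harmonizedVols[[ts]], volumes(harm))
      perFold[[paste0("fold", f, "_", ts)]] <-
        errorReport(harm, trainRef, mask,
                    method = config@method, foldAveraged = FALSE)
    }
  }

  harmonized <- lapply(names(targets), function(ts)
    new("SiteDataset", site = reference@site, volumes = harmonizedVols[[ts]],
        mask = mask))
  names(harmonized) <- names(targets)

  pooledTargetBefore <- new("SiteDataset", site = "pooled_targets",
                            volumes = unlist(lapply(targets, volumes)),
                            mask = mask)
  pooledTargetAfter <- new("SiteDataset", site = "pooled_targets_harmonized",
                           volumes = unlist(lapply(harmonized, volumes)),
                           mask = mask)
  before <- errorReport(pooledTargetBefore, reference, mask,
                        method = "none", foldAveraged = FALSE)
  avgMap <- Reduce(`+`, lapply(perFold, absErrorMap)) / length(perFold)
  afterTab <- do.call(rbind, lapply(perFold, perSubjectRmse))
  rownames(afterTab) <- NULL
  q <- quantile(afterTab$rmse, c(0.25, 0.5, 0.75))
  after <- new("ErrorReport", absErrorMap = avgMap, perSubjectRmse = afterTab,
               summary = c(q1 = unname(q[1]), median = unname(q[2]),
                           q3 = unname(q[3])),
               method = config@method, foldAveraged = TRUE)

  out <- list(before = before, after = after, perFold = perFold,
              harmonized = harmonized, models = models, split = split)

  if (config@groupTest) {
    out$groupTestBefore <- voxelwiseGroupTest(
      targets[[1]], reference, mask, "permutation_maxstat",
      nPermutations = config@nPermutations, seed = config@seed)
    out$groupTestAfter <- voxelwiseGroupTest(
      harmonized[[1]], reference, mask, "permutation_maxstat",
      nPermutations = config@nPermutations, seed = config@seed)
  }

  if (nzchar(config@outputDir)) writeExperiment(config, out)
  out
}

writeExperiment <- function(config, out) {
  dir <- config@outputDir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(method = config@method, referenceSite = config@referenceSite,
         k = config@k, seed = config@seed,
         lambdaRecon = config@trainConfig@lambdaRecon,
         lambdaGp = config@trainConfig@lambdaGp,
         epochs = config@trainConfig@epochs,
         learningRate = config@trainConfig@learningRate,
         batchSize = config@trainConfig@batchSize,
         criticSteps = config@trainConfig@criticSteps),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  writeFoldSplit(out$split, file.path(dir, "folds.csv"))
  write.csv(out$after@perSubjectRmse, file.path(dir, "rmse_after.csv"),
            row.names = FALSE)
  write.csv(out$before@perSubjectRmse, file.path(dir, "rmse_before.csv"),
            row.names = FALSE)
  write.csv(data.frame(stat = names(out$after@summary),
                       before = out$before@summary[names(out$after@summary)],
                       after = out$after@summary),
            file.path(dir, "rmse_summary.csv"), row.names = FALSE)
  RNifti::writeNifti(RNifti::asNifti(out$after@absErrorMap),
                     file.path(dir, "abs_error_after.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(out$before@absErrorMap),
                     file.path(dir, "abs_error_before.nii.gz"))
  if (!is.null(out$groupTestAfter)) {
    RNifti::writeNifti(RNifti::asNifti(significanceMask(out$groupTestAfter)),
                       file.path(dir, "sig_after.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(significanceMask(out$groupTestBefore)),
                       file.path(dir, "sig_before.nii.gz"))
  }
  invisible(dir)
}
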