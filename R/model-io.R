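# Persistence of fitted harmonization models: parameter maps as NIfTI plus
# key-value text sidecars. Dual-GAN models round-trip through R's native
# serialization (weights are plain numeric arrays).

writeKeyValues <- function(kv, path) {
  writeLines(paste0(names(kv), "=", vapply(kv, function(v)
    paste(format(v, digits = 17), collapse = ","), "")), path)
  invisible(path)
}

readKeyValues <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  setNames(lapply(kv, function(x) strsplit(x[2], ",", fixed = TRUE)[[1]]),
           vapply(kv, `[`, "", 1))
}

maskedToArray <- function(values, maskIdx, dims) {
  a <- array(0, dims)
  a[maskIdx] <- values
  a
}

#' Serialize a fitted scaling model to NIfTI + sidecar
#'
#' Writes the factor map (voxel mode) or the scalar factor (sidecar), the
#' mask, and a key-value sidecar (mode, sites, degenerate voxels).
#'
#' @param model a \linkS4class{ScalingModel}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeScalingModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(model@mask), file.path(dir, "mask.nii.gz"))
  if (model@mode == "voxel")
    RNifti::writeNifti(RNifti::asNifti(model@factorMap),
                       file.path(dir, "factor.nii.gz"))
  writeKeyValues(list(
    model = "scaling", mode = model@mode,
    factor_global = model@factorGlobal,
    reference_site = model@referenceSite, target_site = model@targetSite,
    degenerate_voxels = if (length(model@degenerateVoxels))
      model@degenerateVoxels else ""
  ), file.path(dir, "model.txt"))
  invisible(dir)
}

#' @rdname writeScalingModel
#' @return \code{readScalingModel}: the restored \linkS4class{ScalingModel}.
#' @export
readScalingModel <- function(dir) {
  kv <- readKeyValues(file.path(dir, "model.txt"))
  stopifnot(kv$model == "scaling")
  readArr <- function(f) {
    a <- as.array(RNifti::readNifti(file.path(dir, f)))
    array(as.numeric(a), dim(a))
  }
  mask <- readArr("mask.nii.gz")
  fmap <- if (kv$mode == "voxel") readArr("factor.nii.gz")
          else array(1, dim(mask))
  degen <- kv$degenerate_voxels
  degen <- if (identical(degen, "")) integer() else as.integer(degen)
  new("ScalingModel", mode = as.character(kv$mode),
      factorGlobal = as.numeric(kv$factor_global), factorMap = fmap,
      mask = mask, referenceSite = as.character(kv$reference_site),
      targetSite = as.character(kv$target_site), degenerateVoxels = degen)
}

#' Serialize a fitted ComBat model to NIfTI + sidecar
#'
#' Writes the per-voxel baseline, covariate-coefficient, residual-scale and
#' per-site batch-parameter maps as NIfTI volumes plus a key-value sidecar
#' (sites, reference, covariate centering, empirical-Bayes flag).
#'
#' @param model a \linkS4class{CombatModel}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeCombatModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- dim(model@mask)
  wr <- function(v, f) RNifti::writeNifti(
    RNifti::asNifti(maskedToArray(v, model@maskIdx, dims)), file.path(dir, f))
  RNifti::writeNifti(RNifti::asNifti(model@mask), file.path(dir, "mask.nii.gz"))
  wr(model@alpha, "alpha.nii.gz")
  wr(model@sigma, "sigma.nii.gz")
  for (j in seq_len(ncol(model@beta)))
    wr(model@beta[, j], sprintf("beta_%d.nii.gz", j))
  for (i in seq_along(model@sites)) {
    wr(model@gammaZ[, i], sprintf("gamma_z_%s.nii.gz", model@sites[i]))
    wr(model@delta[, i], sprintf("delta_%s.nii.gz", model@sites[i]))
  }
  writeKeyValues(list(
    model = "combat", sites = model@sites,
    reference_site = model@referenceSite,
    cov_center = model@covCenter, n_beta = ncol(model@beta),
    empirical_bayes = model@empiricalBayes,
    degenerate_voxels = if (length(model@degenerateVoxels))
      model@degenerateVoxels else ""
  ), file.path(dir, "model.txt"))
  invisible(dir)
}

#' @rdname writeCombatModel
#' @return \code{readCombatModel}: the restored \linkS4class{CombatModel}.
#' @export
readCombatModel <- function(dir) {
  kv <- readKeyValues(file.path(dir, "model.txt"))
  stopifnot(kv$model == "combat")
  readArr <- function(f) {
    a <- as.array(RNifti::readNifti(file.path(dir, f)))
    array(as.numeric(a), dim(a))
  }
  mask <- readArr("mask.nii.gz")
  idx <- which(mask > 0)
  rd <- function(f) readArr(f)[idx]
  sites <- as.character(kv$sites)
  nBeta <- as.integer(kv$n_beta)
  beta <- sapply(seq_len(nBeta), function(j) rd(sprintf("beta_%d.nii.gz", j)))
  gammaZ <- sapply(sites, function(s) rd(sprintf("gamma_z_%s.nii.gz", s)))
  delta <- sapply(sites, function(s) rd(sprintf("delta_%s.nii.gz", s)))
  degen <- kv$degenerate_voxels
  degen <- if (identical(degen, "")) integer() else as.integer(degen)
  new("CombatModel", maskIdx = as.integer(idx), mask = mask, sites = sites,
      referenceSite = as.character(kv$reference_site),
      alpha = rd("alpha.nii.gz"),
      beta = matrix(beta, ncol = nBeta),
      covCenter = as.numeric(kv$cov_center), sigma = rd("sigma.nii.gz"),
      gammaZ = matrix(gammaZ, ncol = length(sites)),
      delta = matrix(delta, ncol = length(sites)),
      empiricalBayes = as.logical(kv$empirical_bayes),
      degenerateVoxels = degen)
}

#' Persist / restore a trained dual-GAN model
#'
#' The model directory holds the network weights (R serialization of the
#' plain numeric weight arrays), the loss history as CSV, and a key-value
#' text summary of the configuration. Round trips are lossless.
#'
#' @param model a \linkS4class{HarmonizationModel}.
#' @param dir output directory.
#' @return the directory, invisibly; \code{loadDualGANModel} returns the
#'   restored model.
#' @export
saveDualGANModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  write.csv(model@lossHistory, file.path(dir, "loss_history.csv"),
            row.names = FALSE)
  writeKeyValues(list(
    model = "dualgan", site_a = model@siteA, site_b = model@siteB,
    metric = model@metricName, kernel_style = model@genConfig@kernelStyle,
    orientation = model@genConfig@orientation,
    depth = model@genConfig@depth,
    base_channels = model@genConfig@baseChannels,
    lambda_recon = model@trainConfig@lambdaRecon,
    lambda_gp = model@trainConfig@lambdaGp,
    seed = model@trainConfig@seed,
    generator_updates = nrow(model@lossHistory)
  ), file.path(dir, "model.txt"))
  invisible(dir)
}

#' @rdname saveDualGANModel
#' @export
loadDualGANModel <- function(dir) {
  m <- readRDS(file.path(dir, "model.rds"))
  stopifnot(is(m, "HarmonizationModel"))
  m
}
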