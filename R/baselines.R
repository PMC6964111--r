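# Conventional harmonization comparators: global-wise scaling, voxel-wise
# scaling, and voxel-level ComBat (location/scale model with optional
# parametric empirical Bayes), all supporting fit-on-train / apply-on-test.

cohortMatrix <- function(dataset, maskIdx) {
  vapply(dataset@volumes, function(v) v@data[maskIdx],
         numeric(length(maskIdx)))
}

checkGeometry <- function(a, b, what = "datasets") {
  if (!identical(dim(a), dim(b)))
    stop("geometry mismatch between ", what, ": ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
}

#' Fit global-wise scaling
#'
#' The scaling factor is the ratio of the reference cohort's mean metric over
#' the mask (and all subjects) to the target cohort's; applying the model
#' multiplies every voxel of a target-site volume by this factor.
#'
#' @param target,reference \linkS4class{SiteDataset}s sharing geometry.
#' @param mask binary 3D analysis mask (default: the target's mask).
#' @return a \linkS4class{ScalingModel} with mode "global".
#' @export
fitGlobalScaling <- function(target, reference, mask = datasetMask(target)) {
  checkGeometry(datasetMask(target), datasetMask(reference))
  checkGeometry(datasetMask(target), mask, "mask and datasets")
  idx <- which(mask > 0)
  if (!length(idx)) stop("mask is empty")
  tMean <- mean(cohortMatrix(target, idx))
  rMean <- mean(cohortMatrix(reference, idx))
  if (tMean == 0) stop("target cohort mean over the mask is zero")
  new("ScalingModel", mode = "global", factorGlobal = rMean / tMean,
      factorMap = array(1, dim(mask)), mask = mask,
      referenceSite = reference@site, targetSite = target@site,
      degenerateVoxels = integer())
}

#' Fit voxel-wise scaling
#'
#' factor(v) = reference group mean at v / target group mean at v for masked
#' voxels, 1 elsewhere. Masked voxels whose target group mean is zero are
#' degenerate: their factor is 1 and they are listed in the model.
#'
#' @inheritParams fitGlobalScaling
#' @return a \linkS4class{ScalingModel} with mode "voxel".
#' @export
fitVoxelScaling <- function(target, reference, mask = datasetMask(target)) {
  checkGeometry(datasetMask(target), datasetMask(reference))
  checkGeometry(datasetMask(target), mask, "mask and datasets")
  idx <- which(mask > 0)
  if (!length(idx)) stop("mask is empty")
  tMean <- rowMeans(cohortMatrix(target, idx))
  rMean <- rowMeans(cohortMatrix(reference, idx))
  degen <- which(tMean == 0)
  f <- rep(1, length(idx))
  ok <- setdiff(seq_along(idx), degen)
  f[ok] <- rMean[ok] / tMean[ok]
  fmap <- array(1, dim(mask))
  fmap[idx] <- f
  new("ScalingModel", mode = "voxel", factorGlobal = 1, factorMap = fmap,
      mask = mask, referenceSite = reference@site, targetSite = target@site,
      degenerateVoxels = as.integer(degen))
}

combatDesign <- function(ages, sexes, covCenter = NULL) {
  X <- cbind(intercept = 1, age = ages, sexF = as.numeric(sexes == "female"))
  if (is.null(covCenter)) covCenter <- c(0, mean(X[, 2]), mean(X[, 3]))
  X[, 2] <- X[, 2] - covCenter[2]
  X[, 3] <- X[, 3] - covCenter[3]
  list(X = X, covCenter = covCenter)
}

#' Fit voxel-level ComBat
#'
#' Location/scale batch model at each masked voxel, anchored on the reference
#' site: the voxel baseline, covariate coefficients (age, sex) and residual
#' scale are fitted on the reference cohort by least squares; every other
#' site's standardized residuals yield its additive (gamma) and
#' multiplicative (delta) batch parameters, optionally shrunk towards
#' across-voxel parametric priors by iterative empirical Bayes (tolerance
#' 1e-4, at most 100 iterations). The reference site has gamma = 0, delta = 1
#' by construction, so harmonization maps every site onto the reference.
#'
#' @param datasets a \linkS4class{SiteDataset} or list of them (>= 3 subjects
#'   per site).
#' @param mask binary 3D analysis mask (default: first dataset's mask).
#' @param empiricalBayes logical; disable for exact-recovery analyses.
#' @param referenceSite label of the anchor site (default: first dataset).
#' @return a \linkS4class{CombatModel}.
#' @export
fitCombat <- function(datasets, mask = NULL, empiricalBayes = TRUE,
                      referenceSite = NULL) {
  if (is(datasets, "SiteDataset")) datasets <- list(datasets)
  sites <- vapply(datasets, function(d) d@site, "")
  if (anyDuplicated(sites)) stop("duplicate site labels")
  if (is.null(referenceSite)) referenceSite <- sites[1]
  if (!referenceSite %in% sites) stop("referenceSite '", referenceSite,
                                      "' not among fitted sites")
  if (is.null(mask)) mask <- datasetMask(datasets[[1]])
  for (d in datasets) checkGeometry(datasetMask(d), mask, "mask and datasets")
  ns <- vapply(datasets, nSubjects, 0L)
  if (any(ns < 3)) stop("every site needs >= 3 subjects for ComBat; got ",
                        paste(ns, collapse = ", "))
  idx <- which(mask > 0)
  if (!length(idx)) stop("mask is empty")

  Y <- do.call(cbind, lapply(datasets, cohortMatrix, maskIdx = idx))
  siteOf <- rep(sites, ns)
  ages <- unlist(lapply(datasets, function(d)
    vapply(d@volumes, function(v) v@ageWeeks, 0)))
  sexes <- unlist(lapply(datasets, function(d)
    vapply(d@volumes, function(v) v@sex, "")))
  des <- combatDesign(ages, sexes)
  X <- des$X

  refCols <- which(siteOf == referenceSite)
  Xr <- X[refCols, , drop = FALSE]
  qrX <- qr(Xr)
  if (qrX$rank < ncol(Xr))
    stop("rank-deficient covariate design on the reference site ",
         "(constant age or single-sex cohort); drop the collinear covariate")
  XtXinv <- chol2inv(chol(crossprod(Xr)))
  coef <- XtXinv %*% t(Xr) %*% t(Y[, refCols, drop = FALSE])  # p x V
  alpha <- coef[1, ]
  beta <- t(coef[-1, , drop = FALSE])                          # V x (p-1)
  fitRef <- t(Xr %*% coef)                                     # V x n_ref
  resid <- Y[, refCols, drop = FALSE] - fitRef
  dfRef <- length(refCols) - ncol(Xr)
  sigma2 <- rowSums(resid^2) / dfRef
  degen <- which(sigma2 < 1e-20)
  sigma <- sqrt(pmax(sigma2, 1e-20))

  pred <- alpha + beta %*% t(X[, -1, drop = FALSE])            # V x n
  Z <- (Y - pred) / sigma

  nSites <- length(sites)
  gammaZ <- matrix(0, length(idx), nSites)
  delta <- matrix(1, length(idx), nSites)
  for (i in seq_len(nSites)) {
    if (sites[i] == referenceSite) next                        # anchored
    cols <- which(siteOf == sites[i])
    Zi <- Z[, cols, drop = FALSE]
    ghat <- rowMeans(Zi)
    d2 <- apply(Zi, 1, var)
    if (empiricalBayes && length(idx) > 2) {
      gbar <- mean(ghat); t2 <- var(ghat)
      m <- mean(d2); s2 <- var(d2)
      if (t2 > 0 && s2 > 0) {
        aprior <- (2 * s2 + m^2) / s2
        bprior <- (m * s2 + m^3) / s2
        n_i <- length(cols)
        gstar <- ghat; dstar <- d2
        for (it in seq_len(100)) {
          gOld <- gstar; dOld <- dstar
          gstar <- (n_i * t2 * ghat + dstar * gbar) / (n_i * t2 + dstar)
          ss <- rowSums((Zi - gstar)^2)
          dstar <- (bprior + 0.5 * ss) / (n_i / 2 + aprior - 1)
          if (max(abs(gstar - gOld), abs(dstar - dOld)) < 1e-4) break
        }
        ghat <- gstar; d2 <- dstar
      }
    }
    gammaZ[, i] <- ghat
    delta[, i] <- sqrt(pmax(d2, 1e-20))
    degen <- union(degen, which(d2 < 1e-20))
  }
  new("CombatModel", maskIdx = as.integer(idx), mask = mask, sites = sites,
      referenceSite = referenceSite, alpha = alpha, beta = beta,
      covCenter = des$covCenter, sigma = sigma, gammaZ = gammaZ,
      delta = delta, empiricalBayes = empiricalBayes,
      degenerateVoxels = as.integer(degen))
}

#' Apply a fitted harmonization model to a volume
#'
#' Scaling models multiply by the fitted factor; ComBat removes the site's
#' additive batch term, rescales by its multiplicative term, and restores the
#' covariate-adjusted baseline. Out-of-mask voxels are untouched (global
#' scaling, which is defined image-wide, excepted). FA outputs are clipped to
#' [0, 1] and the clipped-voxel count is reported via a message.
#'
#' @param model a \linkS4class{ScalingModel} or \linkS4class{CombatModel}.
#' @param volume a \linkS4class{MetricVolume} with matching geometry.
#' @param ... unused.
#' @return the harmonized \linkS4class{MetricVolume}.
#' @export
setGeneric("applyHarmonization", function(model, volume, ...)
  standardGeneric("applyHarmonization"))

clipReport <- function(y, metric) {
  r <- metricRange(metric)
  n <- sum(y < r[1] | y > r[2])
  if (n > 0) message(n, " voxel(s) clipped to the ", metric, " range")
  pmin(pmax(y, r[1]), r[2])
}

#' @rdname applyHarmonization
setMethod("applyHarmonization", "ScalingModel", function(model, volume, ...) {
  checkGeometry(volume@data, model@mask, "model and volume")
  y <- if (model@mode == "global") volume@data * model@factorGlobal
       else volume@data * model@factorMap
  y <- clipReport(y, volume@metricName)
  initialize(volume, data = array(y, dim(volume@data)),
             site = model@referenceSite)
})

#' @rdname applyHarmonization
setMethod("applyHarmonization", "CombatModel", function(model, volume, ...) {
  checkGeometry(volume@data, model@mask, "model and volume")
  s <- match(volume@site, model@sites)
  if (is.na(s))
    stop("site '", volume@site, "' was not seen when fitting this ComBat model")
  des <- combatDesign(volume@ageWeeks, volume@sex, model@covCenter)
  x <- des$X[1, -1]
  y <- volume@data
  v <- y[model@maskIdx]
  pred <- model@alpha + as.numeric(model@beta %*% x)
  z <- (v - pred) / model@sigma
  zAdj <- (z - model@gammaZ[, s]) / model@delta[, s]
  out <- model@sigma * zAdj + pred
  if (length(model@degenerateVoxels))
    out[model@degenerateVoxels] <- v[model@degenerateVoxels]
  y[model@maskIdx] <- out
  y[model@maskIdx] <- clipReport(y[model@maskIdx], volume@metricName)
  initialize(volume, data = y, site = model@referenceSite)
})

#' Apply a fitted model to every volume of a dataset
#' @param model a fitted harmonization model.
#' @param dataset a \linkS4class{SiteDataset}.
#' @return a \linkS4class{SiteDataset} of harmonized volumes.
#' @export
applyHarmonizationToDataset <- function(model, dataset) {
  vols <- lapply(dataset@volumes, function(v) applyHarmonization(model, v))
  new("SiteDataset", site = vols[[1]]@site, volumes = vols,
      mask = dataset@mask)
}
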