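# Dual-GAN training: alternating critic updates (Wasserstein loss with
# gradient penalty, discriminators trained first) and generator updates
# (adversarial + lambda x L1 cycle reconstruction), with RMSProp and full
# seeded reproducibility on CPU.

# Pooled training slices for one site. Slices are kept subject-major in the
# order of the retained positions, so sample (subject s, position rank j)
# lives at index (s - 1) * nKept + j. Keeping the position labels allows
# position-matched batch sampling across sites: the cohorts are registered,
# so drawing the same slice positions from both sites removes anatomical
# variance from the critic's real-vs-fake signal and leaves the site effect.
slicePool <- function(dataset, orientation, minCoverage) {
  mask <- datasetMask(dataset)
  mStack <- extractSlices(mask, orientation)$slices
  nS <- dim(mStack)[3]
  coverage <- colMeans(matrix(mStack, ncol = nS))
  keep <- which(coverage >= minCoverage)
  if (!length(keep))
    stop("no slices with mask coverage >= ", minCoverage, " in orientation ",
         orientation)
  sl <- lapply(dataset@volumes, function(v)
    extractSlices(v@data, orientation)$slices[, , keep, drop = FALSE])
  pool <- array(unlist(sl), c(dim(sl[[1]])[1:2], 1L, length(keep) * length(sl)))
  list(arr = pool, nKept = length(keep), nSubjects = length(sl))
}

volumePool <- function(dataset) {
  d <- dim(datasetMask(dataset))
  pool <- array(unlist(lapply(dataset@volumes, function(v) v@data)),
                c(d, 1L, nSubjects(dataset)))
  list(arr = pool, nKept = 1L, nSubjects = nSubjects(dataset))
}

takeBatch <- function(pool, idx) {
  nd <- length(dim(pool$arr))
  args <- c(list(pool$arr), as.list(rep(TRUE, nd - 1L)), list(idx),
            list(drop = FALSE))
  do.call(`[`, args)
}

# position-matched batch: common slice positions, independent random
# subjects per site
matchedIdx <- function(poolA, poolB, B) {
  stopifnot(poolA$nKept == poolB$nKept)
  j <- sample.int(poolA$nKept, B, replace = TRUE)
  list(a = (sample.int(poolA$nSubjects, B, replace = TRUE) - 1L) * poolA$nKept + j,
       b = (sample.int(poolB$nSubjects, B, replace = TRUE) - 1L) * poolB$nKept + j)
}

scaleGrads <- function(layers, s) {
  lapply(layers, function(g) lapply(g, function(v) v * s))
}

criticUpdate <- function(D, G, poolSrc, poolTgt, cfg, state, prefix) {
  B <- cfg@batchSize
  ix <- matchedIdx(poolSrc, poolTgt, B)
  xb <- takeBatch(poolSrc, ix$a)
  real <- takeBatch(poolTgt, ix$b)
  fake <- unetForward(G, xb, training = TRUE)$y

  fwR <- discForward(D, real)
  fwF <- discForward(D, fake)
  d <- dim(fwR$map)
  seed <- 1 / (prod(d[-length(d)]) * d[length(d)])
  gR <- discBackward(D, fwR$cache, array(-seed, d))$layers
  gF <- discBackward(D, fwF$cache, array(+seed, dim(fwF$map)))$layers

  alpha <- runif(B)
  per <- prod(dim(real)) / B
  aFull <- array(rep(alpha, each = per), dim(real))
  gp <- discGradPenalty(D, aFull * real + (1 - aFull) * fake)

  grads <- addGradTrees(addGradTrees(gR, gF),
                        scaleGrads(gp$grads, cfg@lambdaGp))
  D <- applyGradsCritic(D, grads, state, prefix,
                        cfg@learningRate * cfg@criticLrMult)
  list(D = D,
       adv = mean(discScores(fwR$map)) - mean(discScores(fwF$map)),
       gp = gp$penalty)
}

#' Train the dual-GAN harmonization model
#'
#' Alternates \code{criticSteps} Wasserstein critic updates (for both
#' discriminators, with gradient penalty) with one joint update of both
#' generators (adversarial term plus lambda times the L1 cycle
#' reconstruction), using RMSProp, for the configured number of epochs. The
#' cohorts are unpaired. Training is fully reproducible from the seed
#' (single-threaded CPU). Non-finite losses abort with the update index.
#'
#' In 2D mode, training samples are all mask-covered slices of all subjects
#' (pooled) in the configured orientation; slices with mask coverage below
#' \code{backgroundSlicePolicy} are excluded.
#'
#' @param siteA,siteB \linkS4class{SiteDataset}s (site A is translated
#'   towards site B by \code{generatorAB}).
#' @param genConfig a \linkS4class{GeneratorConfig}.
#' @param discConfig a \linkS4class{DiscriminatorConfig} (kernel style must
#'   match).
#' @param config a \linkS4class{TrainConfig}.
#' @return a \linkS4class{HarmonizationModel}.
#' @export
trainDualGAN <- function(siteA, siteB, genConfig = generatorConfig(),
                         discConfig = discriminatorConfig(genConfig@kernelStyle),
                         config = trainConfig()) {
  stopifnot(is(siteA, "SiteDataset"), is(siteB, "SiteDataset"))
  if (!nSubjects(siteA) || !nSubjects(siteB)) stop("both sites must be non-empty")
  checkGeometry(datasetMask(siteA), datasetMask(siteB))
  if (genConfig@kernelStyle != discConfig@kernelStyle)
    stop("generator and discriminator kernel styles differ")
  metric <- metricName(siteA)

  withSeed(config@seed, {
    if (genConfig@kernelStyle == "2D") {
      poolA <- slicePool(siteA, genConfig@orientation,
                         config@backgroundSlicePolicy)
      poolB <- slicePool(siteB, genConfig@orientation,
                         config@backgroundSlicePolicy)
    } else {
      poolA <- volumePool(siteA)
      poolB <- volumePool(siteB)
    }
    sp <- spatialDims(poolA$arr)
    GA <- buildGenerator(genConfig, inputSize = sp,
                         seed = sample.int(2^30, 1))
    GB <- buildGenerator(genConfig, inputSize = sp,
                         seed = sample.int(2^30, 1))
    DA <- buildDiscriminator(discConfig, seed = sample.int(2^30, 1))
    DB <- buildDiscriminator(discConfig, seed = sample.int(2^30, 1))
    state <- rmspropInit()

    nA <- dim(poolA$arr)[length(dim(poolA$arr))]
    nB <- dim(poolB$arr)[length(dim(poolB$arr))]
    B <- config@batchSize
    stepsPerEpoch <- max(1L, min(nA, nB) %/% B)
    lam <- config@lambdaRecon
    hist <- list()
    genUpdates <- 0L

    for (epoch in seq_len(config@epochs)) {
      for (step in seq_len(stepsPerEpoch)) {
        if (genUpdates >= config@maxGeneratorUpdates) break
        # discriminators first
        advA <- gpA <- advB <- gpB <- NA_real_
        for (cs in seq_len(config@criticSteps)) {
          upA <- criticUpdate(DA, GA, poolA, poolB, config, state, "DA")
          DA <- upA$D
          upB <- criticUpdate(DB, GB, poolB, poolA, config, state, "DB")
          DB <- upB$D
          advA <- upA$adv; gpA <- upA$gp; advB <- upB$adv; gpB <- upB$gp
        }

        # one joint generator update (position-matched batches)
        ix <- matchedIdx(poolA, poolB, B)
        xb <- takeBatch(poolA, ix$a)
        yb <- takeBatch(poolB, ix$b)

        fwA  <- unetForward(GA, xb, training = TRUE); GA <- fwA$net
        fwAB <- unetForward(GB, fwA$y, training = TRUE); GB <- fwAB$net
        fwB  <- unetForward(GB, yb, training = TRUE); GB <- fwB$net
        fwBA <- unetForward(GA, fwB$y, training = TRUE); GA <- fwBA$net
        fA <- fwA$y; recA <- fwAB$y
        fB <- fwB$y; recB <- fwBA$y

        dFA <- discForward(DA, fA)
        dFB <- discForward(DB, fB)
        mdA <- dim(dFA$map); mdB <- dim(dFB$map)
        seedA <- 1 / prod(mdA); seedB <- 1 / prod(mdB)
        gAdvFA <- discBackward(DA, dFA$cache, array(-seedA, mdA))$gx
        gAdvFB <- discBackward(DB, dFB$cache, array(-seedB, mdB))$gx

        nEl <- length(xb)
        gRecA <- lam * sign(recA - xb) / nEl
        dim(gRecA) <- dim(recA)
        gRecB <- lam * sign(recB - yb) / nEl
        dim(gRecB) <- dim(recB)

        bAB <- unetBackward(GB, fwAB$cache, gRecA)   # through G_B at G_A(x)
        bBA <- unetBackward(GA, fwBA$cache, gRecB)   # through G_A at G_B(y)
        gFA <- gAdvFA + bAB$gx
        dim(gFA) <- dim(fA)
        gFB <- gAdvFB + bBA$gx
        dim(gFB) <- dim(fB)
        bA <- unetBackward(GA, fwA$cache, gFA)
        bB <- unetBackward(GB, fwB$cache, gFB)

        gGA <- addGradTrees(bA[c("enc", "dec")], bBA[c("enc", "dec")])
        gGB <- addGradTrees(bB[c("enc", "dec")], bAB[c("enc", "dec")])
        GA <- applyGradsUnet(GA, gGA, state, "GA", config@learningRate)
        GB <- applyGradsUnet(GB, gGB, state, "GB", config@learningRate)

        genUpdates <- genUpdates + 1L
        recon <- mean(abs(xb - recA)) + mean(abs(yb - recB))
        genAdv <- -mean(discScores(dFA$map)) - mean(discScores(dFB$map))
        row <- data.frame(iter = genUpdates, epoch = epoch,
                          advA = advA, gpA = gpA, advB = advB, gpB = gpB,
                          recon = recon, genAdv = genAdv,
                          genTotal = genAdv + lam * recon)
        if (!all(is.finite(unlist(row[-(1:2)]))))
          stop("non-finite loss at generator update ", genUpdates,
               "; training aborted")
        hist[[length(hist) + 1L]] <- row
      }
      if (genUpdates >= config@maxGeneratorUpdates) break
    }

    new("HarmonizationModel",
        generatorAB = unclass(GA), generatorBA = unclass(GB),
        discA = unclass(DA), discB = unclass(DB),
        genConfig = genConfig, discConfig = discConfig, trainConfig = config,
        lossHistory = do.call(rbind, hist),
        siteA = siteA@site, siteB = siteB@site,
        mask = datasetMask(siteA), metricName = metric)
  })
}

#' Harmonize a volume with a trained dual-GAN model
#'
#' 2D mode extracts slices in the model's orientation, translates each with
#' the appropriate generator, and restacks; 3D mode translates the whole
#' volume. Out-of-mask voxels are restored from the input and outputs are
#' clipped to the metric range. Covariates are preserved; the site label
#' becomes the target site.
#'
#' @param model a \linkS4class{HarmonizationModel}.
#' @param volume a \linkS4class{MetricVolume}.
#' @param direction "AtoB" (site A to site B, aliases "1to2") or "BtoA"
#'   ("2to1").
#' @return the harmonized \linkS4class{MetricVolume}.
#' @export
harmonize <- function(model, volume, direction = c("AtoB", "BtoA", "1to2", "2to1")) {
  direction <- match.arg(direction)
  direction <- c(AtoB = "AtoB", `1to2` = "AtoB",
                 BtoA = "BtoA", `2to1` = "BtoA")[direction]
  stopifnot(is(model, "HarmonizationModel"), is(volume, "MetricVolume"))
  checkGeometry(volume@data, model@mask, "model mask and volume")
  G <- if (direction == "AtoB") model@generatorAB else model@generatorBA
  targetSite <- if (direction == "AtoB") model@siteB else model@siteA

  if (model@genConfig@kernelStyle == "2D") {
    st <- extractSlices(volume@data, model@genConfig@orientation)
    d <- dim(st$slices)
    batch <- array(st$slices, c(d[1], d[2], 1L, d[3]))
    out <- unetForward(G, batch, training = FALSE)$y
    st$slices <- array(out, d)
    y <- restackSlices(st)
  } else {
    batch <- array(volume@data, c(dim(volume@data), 1L, 1L))
    y <- array(unetForward(G, batch, training = FALSE)$y, dim(volume@data))
  }
  y[model@mask == 0] <- volume@data[model@mask == 0]
  y <- clipToMetric(y, volume@metricName)
  initialize(volume, data = array(y, dim(volume@data)), site = targetSite)
}

#' Harmonize every volume of a dataset
#' @inheritParams harmonize
#' @param dataset a \linkS4class{SiteDataset}.
#' @return a \linkS4class{SiteDataset} of harmonized volumes.
#' @export
harmonizeDataset <- function(model, dataset, direction = "AtoB") {
  vols <- lapply(dataset@volumes, function(v) harmonize(model, v, direction))
  new("SiteDataset", site = vols[[1]]@site, volumes = vols,
      mask = dataset@mask)
}
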