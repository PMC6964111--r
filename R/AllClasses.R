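# Central S4 data containers. All voxel arrays use template-space index order
# (X, Y, Z); no world-space resampling is performed anywhere in the package —
# inputs are required to be pre-registered to a common template.

#' MetricVolume: one subject's 3D scalar metric map
#'
#' Holds a single subject's fractional anisotropy (FA, dimensionless) or mean
#' diffusivity (MD, mm^2/s) volume together with its geometry, site label and
#' covariates (postmenstrual age in weeks, sex).
#'
#' @slot data 3D numeric array of metric values.
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot subjectId character scalar.
#' @slot site character scalar site label.
#' @slot ageWeeks numeric scalar, postmenstrual age in weeks.
#' @slot sex "male" or "female".
#' @slot metricName "FA" or "MD".
#' @exportClass MetricVolume
setClass("MetricVolume", representation(
  data = "array", voxelSize = "numeric", subjectId = "character",
  site = "character", ageWeeks = "numeric", sex = "character",
  metricName = "character"
))

setValidity("MetricVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3D array")
  if (!all(is.finite(object@data))) msg <- c(msg, "data must be finite everywhere")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive reals")
  if (!object@sex %in% c("male", "female")) msg <- c(msg, "sex must be male or female")
  if (!object@metricName %in% c("FA", "MD")) msg <- c(msg, "metricName must be FA or MD")
  if (length(object@ageWeeks) != 1L || object@ageWeeks <= 0)
    msg <- c(msg, "ageWeeks must be a positive scalar")
  if (object@metricName %in% c("FA", "MD") && all(is.finite(object@data))) {
    r <- metricRange(object@metricName)
    if (min(object@data) < r[1] - 1e-9 || max(object@data) > r[2] + 1e-9)
      msg <- c(msg, sprintf("%s values must lie in [%g, %g]",
                            object@metricName, r[1], r[2]))
  }
  if (length(msg)) msg else TRUE
})

#' SiteDataset: one site's cohort of metric volumes
#'
#' @slot site character site label.
#' @slot volumes list of \linkS4class{MetricVolume}, all sharing one shape and
#'   metric.
#' @slot mask binary 3D array (white-matter analysis mask) shared by all
#'   volumes.
#' @exportClass SiteDataset
setClass("SiteDataset", representation(
  site = "character", volumes = "list", mask = "array"
))

setValidity("SiteDataset", function(object) {
  msg <- character()
  if (!length(object@volumes)) msg <- c(msg, "volumes must be non-empty")
  if (!all(vapply(object@volumes, is, TRUE, "MetricVolume")))
    msg <- c(msg, "volumes must all be MetricVolume objects")
  else {
    shp <- dim(object@volumes[[1]]@data)
    if (!all(vapply(object@volumes, function(v) identical(dim(v@data), shp), TRUE)))
      msg <- c(msg, "all volumes must share one shape")
    mets <- vapply(object@volumes, function(v) v@metricName, "")
    if (length(unique(mets)) != 1L) msg <- c(msg, "all volumes must share one metric")
    ids <- vapply(object@volumes, function(v) v@subjectId, "")
    if (anyDuplicated(ids)) msg <- c(msg, "subject ids must be unique")
    if (!identical(dim(object@mask), shp)) msg <- c(msg, "mask shape must match volumes")
  }
  if (!all(object@mask %in% c(0, 1))) msg <- c(msg, "mask must be binary")
  if (length(msg)) msg else TRUE
})

#' TemplateAtlas: synthetic template with white-matter mask and tract set
#'
#' Synthetic stand-in for a population FA template plus a set of tract
#' regions, used by the phantom generator. Tracts are elongated tube
#' structures with higher baseline FA than surrounding white matter, each with
#' an associated principal-axis direction.
#'
#' @slot baseMap 3D array of baseline FA values in [0, 1].
#' @slot wmMask binary 3D array.
#' @slot tractMasks named list of binary 3D arrays, each a subset of wmMask.
#' @slot tractAxes named list of unit 3-vectors (principal axis per tract).
#' @slot shape integer(3).
#' @exportClass TemplateAtlas
setClass("TemplateAtlas", representation(
  baseMap = "array", wmMask = "array", tractMasks = "list",
  tractAxes = "list", shape = "integer"
))

setValidity("TemplateAtlas", function(object) {
  msg <- character()
  shp <- object@shape
  if (!identical(dim(object@baseMap), shp)) msg <- c(msg, "baseMap shape mismatch")
  if (!identical(dim(object@wmMask), shp)) msg <- c(msg, "wmMask shape mismatch")
  inmask <- object@baseMap[object@wmMask > 0]
  if (length(inmask) && (min(inmask) <= 0 || max(inmask) >= 1))
    msg <- c(msg, "baseMap values inside wmMask must lie in (0, 1)")
  if (any(object@baseMap[object@wmMask == 0 & object@baseMap != 0] < 0))
    msg <- c(msg, "baseMap must be non-negative")
  for (nm in names(object@tractMasks)) {
    tm <- object@tractMasks[[nm]]
    if (!identical(dim(tm), shp)) msg <- c(msg, paste0("tract ", nm, " shape mismatch"))
    else if (any(tm > 0 & object@wmMask == 0))
      msg <- c(msg, paste0("tract ", nm, " must be a subset of wmMask"))
  }
  if (!identical(sort(names(object@tractMasks)), sort(names(object@tractAxes))))
    msg <- c(msg, "tractMasks and tractAxes must share names")
  if (length(msg)) msg else TRUE
})

#' CovariateModel: generative covariate-effect parameters for phantom cohorts
#'
#' @slot ageRange numeric(2) postmenstrual-age range (weeks), low < high.
#' @slot maleFraction fraction of males in [0, 1].
#' @slot betaAge FA change per week of age, applied within tract masks.
#' @slot betaSex additive FA offset for female subjects within tract masks
#'   (positive values give the conventional positive Cohen's d, female minus
#'   male).
#' @slot subjectSd between-subject FA standard deviation (constant offset per
#'   subject over white matter).
#' @slot noiseSd within-image voxel noise standard deviation.
#' @exportClass CovariateModel
setClass("CovariateModel", representation(
  ageRange = "numeric", maleFraction = "numeric", betaAge = "numeric",
  betaSex = "numeric", subjectSd = "numeric", noiseSd = "numeric"
))

setValidity("CovariateModel", function(object) {
  msg <- character()
  if (length(object@ageRange) != 2L || object@ageRange[1] >= object@ageRange[2])
    msg <- c(msg, "ageRange must be (low, high) with low < high")
  if (object@maleFraction < 0 || object@maleFraction > 1)
    msg <- c(msg, "maleFraction must lie in [0, 1]")
  if (object@subjectSd < 0 || object@noiseSd < 0)
    msg <- c(msg, "standard deviations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SiteEffectField: ground-truth synthetic site transformation
#'
#' Voxel-wise transformation x -> clip((g(v) x + a(v))^gamma + noise) applied
#' within tissue support, with spatially smooth gain g and offset a.
#'
#' @slot kind one of identity, multiplicative, additive, nonlinear, mixed.
#' @slot multField strictly positive 3D gain array g(v).
#' @slot addField 3D offset array a(v).
#' @slot gammaNl positive scalar exponent of the monotone power nonlinearity.
#' @slot noiseSdSite site-noise standard deviation (>= 0).
#' @slot smoothnessMm smoothing length of the random fields, mm.
#' @slot seed integer seed the fields were drawn with.
#' @exportClass SiteEffectField
setClass("SiteEffectField", representation(
  kind = "character", multField = "array", addField = "array",
  gammaNl = "numeric", noiseSdSite = "numeric", smoothnessMm = "numeric",
  seed = "integer"
))

setValidity("SiteEffectField", function(object) {
  msg <- character()
  if (any(object@multField <= 0)) msg <- c(msg, "multField must be > 0 everywhere")
  if (!sameShape(object@multField, object@addField))
    msg <- c(msg, "multField and addField must share shape")
  if (object@gammaNl <= 0) msg <- c(msg, "gammaNl must be positive")
  if (object@noiseSdSite < 0) msg <- c(msg, "noiseSdSite must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FoldSplit: per-site k-fold partition of subjects
#'
#' @slot k number of folds.
#' @slot assignments data.frame with columns subject_id, site, fold.
#' @exportClass FoldSplit
setClass("FoldSplit", representation(k = "integer", assignments = "data.frame"))

setValidity("FoldSplit", function(object) {
  msg <- character()
  a <- object@assignments
  if (!all(c("subject_id", "site", "fold") %in% names(a)))
    msg <- c(msg, "assignments needs columns subject_id, site, fold")
  else {
    if (anyDuplicated(paste(a$site, a$subject_id)))
      msg <- c(msg, "each subject must appear in exactly one fold")
    if (length(unique(a$fold)) > object@k) msg <- c(msg, "more folds than k")
    for (s in unique(a$site)) {
      sizes <- table(factor(a$fold[a$site == s], levels = seq_len(object@k)))
      if (diff(range(sizes)) > 1L)
        msg <- c(msg, paste0("fold sizes for site ", s, " differ by more than 1"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ScalingModel: global- or voxel-wise scaling harmonization
#'
#' Factors map the TARGET site onto the REFERENCE site: applying the model
#' multiplies a target-site volume by the (global or voxel-wise) factor.
#'
#' @slot mode "global" or "voxel".
#' @slot factorGlobal scalar factor (global mode; 1 in voxel mode).
#' @slot factorMap 3D factor array (voxel mode; 1 outside mask).
#' @slot mask binary 3D analysis mask.
#' @slot referenceSite,targetSite site labels.
#' @slot degenerateVoxels integer indices of masked voxels with zero target
#'   mean, passed through with factor 1.
#' @exportClass ScalingModel
setClass("ScalingModel", representation(
  mode = "character", factorGlobal = "numeric", factorMap = "array",
  mask = "array", referenceSite = "character", targetSite = "character",
  degenerateVoxels = "integer"
))

setValidity("ScalingModel", function(object) {
  msg <- character()
  if (!object@mode %in% c("global", "voxel")) msg <- c(msg, "mode must be global or voxel")
  if (object@mode == "global" &&
      (!is.finite(object@factorGlobal) || object@factorGlobal <= 0))
    msg <- c(msg, "global factor must be finite and > 0")
  if (object@mode == "voxel") {
    if (!all(is.finite(object@factorMap)) || any(object@factorMap <= 0))
      msg <- c(msg, "voxel factors must be finite and > 0")
    if (any(object@factorMap[object@mask == 0] != 1))
      msg <- c(msg, "voxel factor must be 1 outside the mask")
  }
  if (length(msg)) msg else TRUE
})

#' CombatModel: voxel-level location/scale (ComBat) harmonization model
#'
#' Reference-anchored parameterisation: the voxel-wise baseline alpha(v) and
#' covariate coefficients beta(v) (age, sex) and the residual scale sigma(v)
#' are fitted on the reference site, whose batch parameters are fixed at
#' gamma = 0, delta = 1; every other site's additive gamma_site(v) and
#' multiplicative delta_site(v) are estimated on standardized residuals,
#' optionally shrunk by parametric empirical Bayes.
#'
#' @slot maskIdx integer indices of masked voxels (into the 3D array).
#' @slot mask binary 3D array.
#' @slot sites character vector of fitted site labels.
#' @slot referenceSite the anchor site.
#' @slot alpha numeric(V) per-voxel baseline.
#' @slot beta V x p matrix of covariate coefficients.
#' @slot covCenter numeric(p) covariate centering values.
#' @slot sigma numeric(V) residual scale.
#' @slot gammaZ V x nsites matrix of standardized additive batch parameters.
#' @slot delta V x nsites matrix of multiplicative batch parameters (> 0).
#' @slot empiricalBayes logical flag.
#' @slot degenerateVoxels integer indices (into maskIdx) of voxels excluded
#'   from fitting (zero variance), passed through unchanged.
#' @exportClass CombatModel
setClass("CombatModel", representation(
  maskIdx = "integer", mask = "array", sites = "character",
  referenceSite = "character", alpha = "numeric", beta = "matrix",
  covCenter = "numeric", sigma = "numeric", gammaZ = "matrix",
  delta = "matrix", empiricalBayes = "logical", degenerateVoxels = "integer"
))

#' GeneratorConfig: U-Net generator architecture settings
#'
#' Encoder levels are strided convolutions (kernel 5, stride 2) each followed
#' by LeakyReLU and batch normalization; the decoder mirrors them with
#' transposed convolutions, encoder features concatenated in via skip
#' connections. The output head is a linear transposed convolution predicting
#' an additive residual correction to the input (zero-initialised, so the
#' generator starts as the identity); outputs are clipped to the metric range
#' at inference only.
#'
#' @slot kernelStyle "2D" or "3D".
#' @slot orientation axial, coronal or sagittal (2D only).
#' @slot kernelSize convolution kernel size per spatial dimension (5).
#' @slot stride stride per spatial dimension (2).
#' @slot depth number of encoder levels.
#' @slot baseChannels channels at the first level (doubling per level).
#' @slot leakySlope LeakyReLU negative slope.
#' @slot batchNorm logical; batch normalization in the generator.
#' @slot skipConnections logical; encoder-decoder concatenation.
#' @slot residualHead logical; output = input + predicted correction.
#' @exportClass GeneratorConfig
setClass("GeneratorConfig", representation(
  kernelStyle = "character", orientation = "character", kernelSize = "integer",
  stride = "integer", depth = "integer", baseChannels = "integer",
  leakySlope = "numeric", batchNorm = "logical", skipConnections = "logical",
  residualHead = "logical"
))

#' DiscriminatorConfig: Markovian (patch) discriminator settings
#'
#' A fully convolutional critic (convolution + LeakyReLU, no batch
#' normalization) whose per-output-unit receptive field must equal the target
#' patch size exactly: 30 x 30 in 2D, 30 x 30 x 8 in 3D. The overall score of
#' an image is the mean of the local score map. Building a plan whose analytic
#' receptive field differs from the target is an error.
#'
#' @slot kernelStyle "2D" or "3D".
#' @slot kernels integer matrix (layers x spatial dims) of kernel sizes.
#' @slot strides integer matrix (layers x spatial dims).
#' @slot channels integer vector of output channels per layer (last must be 1).
#' @slot targetField integer target receptive field per spatial dimension.
#' @slot leakySlope LeakyReLU negative slope.
#' @exportClass DiscriminatorConfig
setClass("DiscriminatorConfig", representation(
  kernelStyle = "character", kernels = "matrix", strides = "matrix",
  channels = "integer", targetField = "integer", leakySlope = "numeric"
))

#' TrainConfig: dual-GAN training settings
#'
#' Defaults follow the method's standard configuration (reconstruction
#' weight lambda = 20, gradient-penalty weight lambda_gp = 10, RMSProp,
#' 300 epochs); critic schedule, learning rate and batch size are declared
#' package defaults.
#'
#' @slot lambdaRecon reconstruction-loss weight (lambda, 20).
#' @slot lambdaGp gradient-penalty weight (lambda_gp, 10).
#' @slot epochs training epochs (300).
#' @slot learningRate RMSProp learning rate (generators).
#' @slot criticLrMult multiplier on the learning rate for the critics
#'   (two-time-scale updates keep the critics near-optimal between generator
#'   steps).
#' @slot batchSize mini-batch size.
#' @slot criticSteps discriminator updates per generator update.
#' @slot seed integer RNG seed.
#' @slot backgroundSlicePolicy minimum mask coverage fraction for a 2D slice
#'   to enter training batches.
#' @slot maxGeneratorUpdates hard cap on generator updates (Inf = epochs
#'   decide).
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  lambdaRecon = "numeric", lambdaGp = "numeric", epochs = "integer",
  learningRate = "numeric", criticLrMult = "numeric", batchSize = "integer",
  criticSteps = "integer", seed = "integer",
  backgroundSlicePolicy = "numeric", maxGeneratorUpdates = "numeric"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@lambdaRecon < 0) msg <- c(msg, "lambdaRecon must be >= 0")
  if (object@lambdaGp < 0) msg <- c(msg, "lambdaGp must be >= 0")
  if (object@epochs < 1 || object@batchSize < 1 || object@criticSteps < 1)
    msg <- c(msg, "epochs, batchSize and criticSteps must be positive")
  if (length(msg)) msg else TRUE
})

#' HarmonizationModel: trained dual-GAN quadruple
#'
#' Holds the two generators (A -> B and B -> A), the two Markovian critics,
#' their configurations, the white-matter mask used during training, and the
#' per-update loss history.
#'
#' @slot generatorAB,generatorBA generator networks (site A -> B, B -> A).
#' @slot discA critic judging the site-B domain; \code{discB} the site-A one.
#' @slot discB see discA.
#' @slot genConfig,discConfig,trainConfig configuration objects.
#' @slot lossHistory data.frame of per-generator-update loss terms.
#' @slot siteA,siteB site labels.
#' @slot mask binary 3D training mask.
#' @slot metricName metric the model was trained on.
#' @exportClass HarmonizationModel
setClass("HarmonizationModel", representation(
  generatorAB = "list", generatorBA = "list", discA = "list", discB = "list",
  genConfig = "GeneratorConfig", discConfig = "DiscriminatorConfig",
  trainConfig = "TrainConfig", lossHistory = "data.frame",
  siteA = "character", siteB = "character", mask = "array",
  metricName = "character"
))

#' EffectSizeResult: Cohen's d between two groups
#'
#' d = (M_f - M_m) / S_pooled with the (n - 1)-weighted pooled standard
#' deviation.
#'
#' @slot d standardized mean difference.
#' @slot meanF,meanM group means.
#' @slot sdF,sdM group standard deviations (n - 1 denominator).
#' @slot nF,nM group sizes.
#' @slot sdPooled pooled standard deviation.
#' @exportClass EffectSizeResult
setClass("EffectSizeResult", representation(
  d = "numeric", meanF = "numeric", meanM = "numeric", sdF = "numeric",
  sdM = "numeric", nF = "integer", nM = "integer", sdPooled = "numeric"
))

#' TractProfile: along-tract metric profile
#'
#' Metric values averaged on equally spaced bins along the tract axis,
#' ordered from the end with the smaller projected coordinate.
#'
#' @slot tract tract name.
#' @slot values numeric vector of per-level means.
#' @slot nLevels number of levels (100 by default).
#' @exportClass TractProfile
setClass("TractProfile", representation(
  tract = "character", values = "numeric", nLevels = "integer"
))

#' GroupTestResult: voxel-wise two-sample test with multiplicity control
#'
#' Simplified voxel-wise stand-in for skeleton-based group testing: per-voxel
#' two-sample comparison with either Benjamini-Hochberg FDR or max-statistic
#' permutation FWER control. Not a TBSS implementation (no skeleton
#' projection, no TFCE).
#'
#' @slot pMap 3D array of corrected p-values (1 outside mask).
#' @slot sigMask binary 3D array of significant voxels at alpha.
#' @slot directionMap 3D array: +1 where site B higher, -1 where site A
#'   higher, 0 elsewhere.
#' @slot method "mannwhitney_fdr" or "permutation_maxstat".
#' @slot alpha significance level.
#' @slot mask analysis mask.
#' @exportClass GroupTestResult
setClass("GroupTestResult", representation(
  pMap = "array", sigMask = "array", directionMap = "array",
  method = "character", alpha = "numeric", mask = "array"
))

#' ErrorReport: site-difference error summary for one harmonization method
#'
#' @slot absErrorMap 3D array |group mean A - group mean B| within the mask.
#' @slot perSubjectRmse data.frame (subject_id, rmse).
#' @slot summary named numeric: median and quartiles of per-subject RMSE.
#' @slot method method label.
#' @slot foldAveraged logical: whether quantities were averaged over folds.
#' @exportClass ErrorReport
setClass("ErrorReport", representation(
  absErrorMap = "array", perSubjectRmse = "data.frame", summary = "numeric",
  method = "character", foldAveraged = "logical"
))
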