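# Accessor generics and show methods. Slots are never accessed with @ by
# user code; these are the supported surface.

#' @name accessors
#' @title Accessors for dtigan data containers
#' @description Accessor functions for the S4 containers: voxel data,
#'   geometry, covariates, cohort manifests, masks, tract sets, fitted model
#'   components and training histories.
#' @param x an object of the documented class.
#' @return the slot value; see each method.
NULL

#' @rdname accessors
#' @export
setGeneric("metricData", function(x) standardGeneric("metricData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("siteLabel", function(x) standardGeneric("siteLabel"))
#' @rdname accessors
#' @export
setGeneric("ageWeeks", function(x) standardGeneric("ageWeeks"))
#' @rdname accessors
#' @export
setGeneric("subjectSex", function(x) standardGeneric("subjectSex"))
#' @rdname accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))
#' @rdname accessors
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))
#' @rdname accessors
#' @export
setGeneric("datasetMask", function(x) standardGeneric("datasetMask"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setGeneric("baseMap", function(x) standardGeneric("baseMap"))
#' @rdname accessors
#' @export
setGeneric("wmMask", function(x) standardGeneric("wmMask"))
#' @rdname accessors
#' @export
setGeneric("tractMasks", function(x) standardGeneric("tractMasks"))
#' @rdname accessors
#' @export
setGeneric("tractAxes", function(x) standardGeneric("tractAxes"))
#' @rdname accessors
#' @export
setGeneric("multField", function(x) standardGeneric("multField"))
#' @rdname accessors
#' @export
setGeneric("addField", function(x) standardGeneric("addField"))
#' @rdname accessors
#' @export
setGeneric("fieldKind", function(x) standardGeneric("fieldKind"))
#' @rdname accessors
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))
#' @rdname accessors
#' @export
setGeneric("scalingFactor", function(x) standardGeneric("scalingFactor"))
#' @rdname accessors
#' @export
setGeneric("degenerateVoxels", function(x) standardGeneric("degenerateVoxels"))
#' @rdname accessors
#' @export
setGeneric("combatGamma", function(x) standardGeneric("combatGamma"))
#' @rdname accessors
#' @export
setGeneric("combatDelta", function(x) standardGeneric("combatDelta"))
#' @rdname accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))
#' @rdname accessors
#' @export
setGeneric("effectSize", function(x) standardGeneric("effectSize"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("pMap", function(x) standardGeneric("pMap"))
#' @rdname accessors
#' @export
setGeneric("significanceMask", function(x) standardGeneric("significanceMask"))
#' @rdname accessors
#' @export
setGeneric("directionMap", function(x) standardGeneric("directionMap"))
#' @rdname accessors
#' @export
setGeneric("absErrorMap", function(x) standardGeneric("absErrorMap"))
#' @rdname accessors
#' @export
setGeneric("perSubjectRmse", function(x) standardGeneric("perSubjectRmse"))

#' @rdname accessors
setMethod("metricData", "MetricVolume", function(x) x@data)
#' @rdname accessors
setMethod("voxelSize", "MetricVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("subjectId", "MetricVolume", function(x) x@subjectId)
#' @rdname accessors
setMethod("siteLabel", "MetricVolume", function(x) x@site)
#' @rdname accessors
setMethod("ageWeeks", "MetricVolume", function(x) x@ageWeeks)
#' @rdname accessors
setMethod("subjectSex", "MetricVolume", function(x) x@sex)
#' @rdname accessors
setMethod("metricName", "MetricVolume", function(x) x@metricName)

#' @rdname accessors
setMethod("siteLabel", "SiteDataset", function(x) x@site)
#' @rdname accessors
setMethod("volumes", "SiteDataset", function(x) x@volumes)
#' @rdname accessors
setMethod("datasetMask", "SiteDataset", function(x) x@mask)
#' @rdname accessors
setMethod("nSubjects", "SiteDataset", function(x) length(x@volumes))
#' @rdname accessors
setMethod("subjectIds", "SiteDataset", function(x)
  vapply(x@volumes, function(v) v@subjectId, ""))
#' @rdname accessors
setMethod("metricName", "SiteDataset", function(x) x@volumes[[1]]@metricName)
#' @rdname accessors
setMethod("manifest", "SiteDataset", function(x) {
  data.frame(
    subject_id = subjectIds(x),
    site = x@site,
    age_weeks = vapply(x@volumes, function(v) v@ageWeeks, 0),
    sex = vapply(x@volumes, function(v) v@sex, ""),
    stringsAsFactors = FALSE
  )
})

#' @rdname accessors
setMethod("baseMap", "TemplateAtlas", function(x) x@baseMap)
#' @rdname accessors
setMethod("wmMask", "TemplateAtlas", function(x) x@wmMask)
#' @rdname accessors
setMethod("tractMasks", "TemplateAtlas", function(x) x@tractMasks)
#' @rdname accessors
setMethod("tractAxes", "TemplateAtlas", function(x) x@tractAxes)

#' @rdname accessors
setMethod("multField", "SiteEffectField", function(x) x@multField)
#' @rdname accessors
setMethod("addField", "SiteEffectField", function(x) x@addField)
#' @rdname accessors
setMethod("fieldKind", "SiteEffectField", function(x) x@kind)

#' @rdname accessors
setMethod("foldAssignments", "FoldSplit", function(x) x@assignments)

#' @rdname accessors
setMethod("scalingFactor", "ScalingModel", function(x)
  if (x@mode == "global") x@factorGlobal else x@factorMap)
#' @rdname accessors
setMethod("degenerateVoxels", "ScalingModel", function(x) x@degenerateVoxels)
#' @rdname accessors
setMethod("degenerateVoxels", "CombatModel", function(x) x@degenerateVoxels)

#' @rdname accessors
#' @param site site label whose batch parameters to return; default all.
setMethod("combatGamma", "CombatModel", function(x) {
  g <- x@gammaZ * x@sigma  # report in data units
  colnames(g) <- x@sites
  g
})
#' @rdname accessors
setMethod("combatDelta", "CombatModel", function(x) {
  d <- x@delta
  colnames(d) <- x@sites
  d
})

#' @rdname accessors
setMethod("lossHistory", "HarmonizationModel", function(x) x@lossHistory)

#' @rdname accessors
setMethod("effectSize", "EffectSizeResult", function(x) x@d)
#' @rdname accessors
setMethod("profileValues", "TractProfile", function(x) x@values)

#' @rdname accessors
setMethod("pMap", "GroupTestResult", function(x) x@pMap)
#' @rdname accessors
setMethod("significanceMask", "GroupTestResult", function(x) x@sigMask)
#' @rdname accessors
setMethod("directionMap", "GroupTestResult", function(x) x@directionMap)

#' @rdname accessors
setMethod("absErrorMap", "ErrorReport", function(x) x@absErrorMap)
#' @rdname accessors
setMethod("perSubjectRmse", "ErrorReport", function(x) x@perSubjectRmse)

setMethod("show", "MetricVolume", function(object) {
  cat(sprintf("MetricVolume '%s' (%s, site %s): %s, age %.2f wk, %s\n",
              object@subjectId, object@metricName, object@site,
              paste(dim(object@data), collapse = "x"),
              object@ageWeeks, object@sex))
})

setMethod("show", "SiteDataset", function(object) {
  cat(sprintf("SiteDataset '%s': %d %s volumes of %s, mask %d voxels\n",
              object@site, length(object@volumes),
              object@volumes[[1]]@metricName,
              paste(dim(object@mask), collapse = "x"),
              sum(object@mask)))
})

setMethod("show", "TemplateAtlas", function(object) {
  cat(sprintf("TemplateAtlas %s: %d tracts (%s), %d WM voxels\n",
              paste(object@shape, collapse = "x"),
              length(object@tractMasks),
              paste(names(object@tractMasks), collapse = ", "),
              sum(object@wmMask)))
})

setMethod("show", "SiteEffectField", function(object) {
  cat(sprintf(
    "SiteEffectField '%s': mean gain %.4f, mean offset %.4f, gamma %.3f, noise sd %.4f\n",
    object@kind, mean(object@multField), mean(object@addField),
    object@gammaNl, object@noiseSdSite))
})

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit: k = %d, %d subjects over %d site(s)\n",
              object@k, nrow(object@assignments),
              length(unique(object@assignments$site))))
})

setMethod("show", "ScalingModel", function(object) {
  cat(sprintf("ScalingModel (%s): %s -> %s", object@mode,
              object@targetSite, object@referenceSite))
  if (object@mode == "global") cat(sprintf(", factor %.4f", object@factorGlobal))
  cat(sprintf(", %d degenerate voxel(s)\n", length(object@degenerateVoxels)))
})

setMethod("show", "CombatModel", function(object) {
  cat(sprintf(
    "CombatModel: %d masked voxels, sites [%s] anchored on '%s', EB %s\n",
    length(object@maskIdx), paste(object@sites, collapse = ", "),
    object@referenceSite, if (object@empiricalBayes) "on" else "off"))
})

setMethod("show", "HarmonizationModel", function(object) {
  cat(sprintf(
    "HarmonizationModel (dual GAN, %s%s): %s <-> %s, %d generator updates\n",
    object@genConfig@kernelStyle,
    if (object@genConfig@kernelStyle == "2D")
      paste0(" ", object@genConfig@orientation) else "",
    object@siteA, object@siteB, nrow(object@lossHistory)))
})

setMethod("show", "EffectSizeResult", function(object) {
  cat(sprintf("Cohen's d = %.4f (F: n=%d, M=%.4f; M: n=%d, M=%.4f; S_pooled=%.4f)\n",
              object@d, object@nF, object@meanF, object@nM, object@meanM,
              object@sdPooled))
})

setMethod("show", "TractProfile", function(object) {
  cat(sprintf("TractProfile '%s': %d levels, mean %.4f\n",
              object@tract, object@nLevels, mean(object@values)))
})

setMethod("show", "GroupTestResult", function(object) {
  cat(sprintf("GroupTestResult (%s, alpha=%.3g): %d significant voxel(s)\n",
              object@method, object@alpha, sum(object@sigMask)))
})

setMethod("show", "ErrorReport", function(object) {
  cat(sprintf("ErrorReport [%s]%s: median RMSE %.5f (n=%d subjects)\n",
              object@method, if (object@foldAveraged) " (fold-averaged)" else "",
              object@summary[["median"]], nrow(object@perSubjectRmse)))
})
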