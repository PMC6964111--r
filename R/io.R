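# NIfTI volume and cohort I/O, manifest handling, cross-validation folds,
# and orientation-specific slice extraction/restacking.

#' Write a metric volume to NIfTI
#'
#' @param volume a \linkS4class{MetricVolume}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeMetricVolume <- function(volume, path) {
  stopifnot(is(volume, "MetricVolume"))
  im <- RNifti::asNifti(volume@data)
  RNifti::pixdim(im) <- volume@voxelSize
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a metric volume from NIfTI
#'
#' Geometry comes from the NIfTI header; covariates come from the manifest
#' row (fields subject_id, site, age_weeks, sex and optionally metric).
#' FA values marginally outside [0, 1] — typically registration interpolation
#' artifacts — are clipped with a warning; any |value| > 1.5 is rejected.
#'
#' @param path a readable 3D NIfTI file.
#' @param manifestRow one-row data.frame (or named list) of covariates.
#' @param metric "FA" or "MD" (default from manifestRow$metric, else FA).
#' @param outOfRange "clip" (default, warn) or "error".
#' @return a \linkS4class{MetricVolume}.
#' @export
readMetricVolume <- function(path, manifestRow, metric = NULL,
                             outOfRange = c("clip", "error")) {
  outOfRange <- match.arg(outOfRange)
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  im <- RNifti::readNifti(path)
  a <- as.array(im)
  a <- array(as.numeric(a), dim(a))      # strip the niftiImage class
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
  if (length(dim(a)) != 3L)
    stop("expected a 3D image, got ", length(dim(a)), " dimensions in ", path)
  need <- c("subject_id", "site", "age_weeks", "sex")
  missing <- setdiff(need, names(manifestRow))
  if (length(missing))
    stop("manifest row missing covariates: ", paste(missing, collapse = ", "))
  if (is.null(metric))
    metric <- if (!is.null(manifestRow[["metric"]])) manifestRow[["metric"]] else "FA"

  r <- metricRange(metric)
  if (metric == "FA" && any(abs(a) > 1.5))
    stop("FA values with |value| > 1.5 found in ", path,
         " (max ", max(abs(a)), "); refusing to clip")
  nOut <- sum(a < r[1] | a > r[2])
  if (nOut > 0) {
    if (outOfRange == "error")
      stop(nOut, " voxel(s) outside the ", metric, " range [",
           r[1], ", ", r[2], "] in ", path)
    warning(nOut, " ", metric, " voxel(s) outside [", r[1], ", ", r[2],
            "] clipped in ", path)
    a <- clipToMetric(a, metric)
  }
  vs <- RNifti::pixdim(im)[1:3]
  new("MetricVolume", data = a, voxelSize = as.numeric(vs),
      subjectId = as.character(manifestRow[["subject_id"]]),
      site = as.character(manifestRow[["site"]]),
      ageWeeks = as.numeric(manifestRow[["age_weeks"]]),
      sex = as.character(manifestRow[["sex"]]), metricName = metric)
}

#' Write a cohort as NIfTI volumes plus a CSV manifest
#'
#' @param dataset a \linkS4class{SiteDataset}.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame (columns subject_id, site, age_weeks, sex,
#'   path), invisibly; also written to \code{dir/manifest.csv}, with the mask
#'   at \code{dir/mask.nii.gz}.
#' @export
writeCohort <- function(dataset, dir) {
  stopifnot(is(dataset, "SiteDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset@volumes, function(v) {
    p <- file.path(dir, paste0(v@subjectId, ".nii.gz"))
    writeMetricVolume(v, p)
    data.frame(subject_id = v@subjectId, site = v@site,
               age_weeks = v@ageWeeks, sex = v@sex,
               metric = v@metricName, path = p, stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  maskIm <- RNifti::asNifti(dataset@mask)
  RNifti::pixdim(maskIm) <- dataset@volumes[[1]]@voxelSize
  RNifti::writeNifti(maskIm, file.path(dir, "mask.nii.gz"))
  invisible(man)
}

#' Read a cohort from a manifest
#'
#' Subject order and covariates follow the manifest rows.
#'
#' @param manifest path to a manifest CSV or a data.frame with columns
#'   subject_id, site, age_weeks, sex, path (optionally metric).
#' @param mask binary 3D array or path to a mask NIfTI.
#' @param site site label to select (default: the manifest's single site).
#' @return a \linkS4class{SiteDataset}.
#' @export
readCohort <- function(manifest, mask, site = NULL) {
  man <- if (is.character(manifest)) read.csv(manifest, stringsAsFactors = FALSE)
         else manifest
  if (!is.null(site)) man <- man[man$site == site, , drop = FALSE]
  if (!nrow(man)) stop("manifest contains no subjects",
                       if (!is.null(site)) paste0(" for site ", site))
  if (length(unique(man$site)) != 1L)
    stop("manifest holds multiple sites; pass `site` to select one")
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
  mask <- array(as.numeric(mask > 0.5), dim(mask))
  vols <- lapply(seq_len(nrow(man)), function(i)
    readMetricVolume(man$path[i], man[i, ]))
  new("SiteDataset", site = man$site[1], volumes = vols, mask = mask)
}

#' Write site-effect ground-truth parameters to a key-value sidecar
#' @param field a \linkS4class{SiteEffectField}.
#' @param dir output directory.
#' @return paths written, invisibly. Fields g and a go to NIfTI; scalars to
#'   \code{site_effect.txt}.
#' @export
writeSiteEffectSidecar <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gPath <- file.path(dir, "site_effect_mult.nii.gz")
  aPath <- file.path(dir, "site_effect_add.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(field@multField), gPath)
  RNifti::writeNifti(RNifti::asNifti(field@addField), aPath)
  txt <- file.path(dir, "site_effect.txt")
  writeLines(c(
    paste0("kind=", field@kind),
    paste0("gamma_nl=", format(field@gammaNl, digits = 17)),
    paste0("noise_sd_site=", format(field@noiseSdSite, digits = 17)),
    paste0("smoothness_mm=", format(field@smoothnessMm, digits = 17)),
    paste0("seed=", field@seed),
    paste0("mult_field=", basename(gPath)),
    paste0("add_field=", basename(aPath))
  ), txt)
  invisible(c(txt, gPath, aPath))
}

#' Split cohorts into k per-site folds
#'
#' Stratified by site: each site's subjects are partitioned into k folds of
#' sizes differing by at most one (seeded shuffle), so every fold holds
#' subjects of every site.
#'
#' @param datasets a \linkS4class{SiteDataset} or list of them.
#' @param k number of folds.
#' @param seed integer seed.
#' @return a \linkS4class{FoldSplit}.
#' @examples
#' tpl <- makeTemplate(c(32, 32, 8), 1, seed = 1)
#' co <- generateCohort(tpl, 12, covariateModel(), identityField(dim(wmMask(tpl))), seed = 1)
#' kfoldSplit(co, k = 6, seed = 1)
#' @export
kfoldSplit <- function(datasets, k, seed = 1) {
  if (is(datasets, "SiteDataset")) datasets <- list(datasets)
  k <- as.integer(k)
  rows <- withSeed(seed, lapply(datasets, function(d) {
    ids <- subjectIds(d)
    if (k > length(ids))
      stop("k = ", k, " exceeds the ", length(ids), " subjects of site ",
           d@site)
    ids <- sample(ids)
    data.frame(subject_id = ids, site = d@site,
               fold = rep_len(seq_len(k), length(ids)), stringsAsFactors = FALSE)
  }))
  new("FoldSplit", k = k, assignments = do.call(rbind, rows))
}

#' Persist / load fold assignments as CSV
#' @param split a \linkS4class{FoldSplit}.
#' @param path CSV path.
#' @return \code{writeFoldSplit}: the path invisibly; \code{readFoldSplit}:
#'   a \linkS4class{FoldSplit}.
#' @export
writeFoldSplit <- function(split, path) {
  write.csv(split@assignments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFoldSplit
#' @export
readFoldSplit <- function(path) {
  a <- read.csv(path, stringsAsFactors = FALSE)
  new("FoldSplit", k = max(a$fold), assignments = a)
}

orientationAxis <- function(orientation) {
  switch(orientation, axial = 3L, coronal = 2L, sagittal = 1L,
         stop("unknown orientation '", orientation,
              "'; expected axial, coronal or sagittal"))
}

#' Extract an ordered slice stack from a volume
#'
#' Axial yields Z slices of shape (X, Y); coronal Y slices of (X, Z);
#' sagittal X slices of (Y, Z). \code{restackSlices} inverts the operation
#' exactly.
#'
#' @param volume a \linkS4class{MetricVolume} or 3D array.
#' @param orientation axial, coronal or sagittal.
#' @return list with \code{slices} (3D array, slice index last),
#'   \code{orientation} and \code{shape} (original volume shape).
#' @export
extractSlices <- function(volume, orientation = c("axial", "coronal", "sagittal")) {
  orientation <- match.arg(orientation)
  a <- if (is(volume, "MetricVolume")) volume@data else volume
  stopIfNot3d(a, "volume")
  ax <- orientationAxis(orientation)
  slices <- if (ax == 3L) a else aperm(a, c(setdiff(1:3, ax), ax))
  list(slices = slices, orientation = orientation, shape = dim(a))
}

#' Rebuild a volume from a slice stack
#' @param stack result of \code{\link{extractSlices}} (possibly with modified
#'   slice values).
#' @return 3D array with the original shape.
#' @rdname extractSlices
#' @export
restackSlices <- function(stack) {
  ax <- orientationAxis(stack$orientation)
  a <- stack$slices
  if (ax != 3L) a <- aperm(a, order(c(setdiff(1:3, ax), ax)))
  stopifnot(identical(dim(a), stack$shape))
  a
}
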