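# Evaluation statistics: site-difference error maps and RMSE, Cohen's d,
# along-tract profiles and age correlations, white-matter histograms,
# Mann-Whitney U, and voxel-wise group tests with multiplicity control.

groupMeanMap <- function(dataset, idx) {
  rowMeans(cohortMatrix(dataset, idx))
}

#' Voxel-wise absolute error between two cohorts' group means
#'
#' |mean_A(v) - mean_B(v)| for masked voxels, 0 elsewhere.
#'
#' @param siteA,siteB \linkS4class{SiteDataset}s sharing geometry.
#' @param mask binary 3D analysis mask.
#' @return 3D array.
#' @export
absoluteErrorMap <- function(siteA, siteB, mask = datasetMask(siteA)) {
  checkGeometry(datasetMask(siteA), datasetMask(siteB))
  checkGeometry(datasetMask(siteA), mask, "mask and datasets")
  idx <- which(mask > 0)
  out <- array(0, dim(mask))
  out[idx] <- abs(groupMeanMap(siteA, idx) - groupMeanMap(siteB, idx))
  out
}

#' RMSE of a subject against a reference cohort's voxel-wise group mean
#'
#' sqrt(mean over masked voxels of (subject(v) - reference mean(v))^2).
#' This is the per-subject distance to the reference site used to summarise
#' harmonization error (unpaired cohorts have no subject-level ground truth).
#'
#' @param subject a \linkS4class{MetricVolume}.
#' @param reference a \linkS4class{SiteDataset} (the reference site).
#' @param mask binary 3D mask.
#' @return scalar RMSE.
#' @export
rmseToReference <- function(subject, reference, mask = datasetMask(reference)) {
  checkGeometry(subject@data, mask, "subject and mask")
  idx <- which(mask > 0)
  if (!length(idx)) stop("mask is empty")
  ref <- groupMeanMap(reference, idx)
  sqrt(mean((subject@data[idx] - ref)^2))
}

#' Per-subject RMSE report for a cohort against a reference
#'
#' @param dataset cohort to evaluate.
#' @param reference reference-site cohort.
#' @param mask binary mask.
#' @param method method label recorded in the report.
#' @param foldAveraged logical label recorded in the report.
#' @return an \linkS4class{ErrorReport}.
#' @export
errorReport <- function(dataset, reference, mask = datasetMask(reference),
                        method = "none", foldAveraged = FALSE) {
  rmse <- vapply(dataset@volumes, rmseToReference, 0,
                 reference = reference, mask = mask)
  tab <- data.frame(subject_id = subjectIds(dataset), rmse = rmse,
                    stringsAsFactors = FALSE)
  q <- quantile(rmse, c(0.25, 0.5, 0.75))
  new("ErrorReport",
      absErrorMap = absoluteErrorMap(dataset, reference, mask),
      perSubjectRmse = tab,
      summary = c(q1 = unname(q[1]), median = unname(q[2]), q3 = unname(q[3])),
      method = method, foldAveraged = foldAveraged)
}

#' Cohen's d between two groups
#'
#' d = (M_f - M_m) / S_pooled, with
#' S_pooled = sqrt(((n_f - 1) S_f^2 + (n_m - 1) S_m^2) / (n_f + n_m - 2)),
#' sample standard deviations using n - 1. If both groups are constant with
#' equal means, d = 0 by declared rule; constant groups with unequal means
#' are an error.
#'
#' @param valuesF,valuesM numeric vectors (>= 2 values each), conventionally
#'   the female and male groups.
#' @return an \linkS4class{EffectSizeResult}.
#' @export
cohensD <- function(valuesF, valuesM) {
  nF <- length(valuesF); nM <- length(valuesM)
  if (nF < 2 || nM < 2) stop("both groups need at least 2 values")
  mF <- mean(valuesF); mM <- mean(valuesM)
  sF <- sd(valuesF); sM <- sd(valuesM)
  sp <- sqrt(((nF - 1) * sF^2 + (nM - 1) * sM^2) / (nF + nM - 2))
  d <- if (sp == 0) {
    if (mF != mM) stop("zero pooled standard deviation with unequal means")
    0
  } else (mF - mM) / sp
  new("EffectSizeResult", d = d, meanF = mF, meanM = mM, sdF = sF, sdM = sM,
      nF = as.integer(nF), nM = as.integer(nM), sdPooled = sp)
}

#' Along-tract profile at equally spaced levels
#'
#' Tract voxels are projected onto the tract axis (given, or the principal
#' axis of the voxel coordinates), the projected extent is split into
#' \code{nLevels} equal bins ordered from the end with the smaller projected
#' coordinate, and the per-bin mean metric is returned. An empty bin is an
#' error naming the bin (reduce nLevels for short tracts).
#'
#' @param volume a \linkS4class{MetricVolume} or 3D array.
#' @param tractMask binary 3D array.
#' @param axisDirection optional 3-vector; default: largest-variance
#'   direction of the tract voxel coordinates.
#' @param nLevels number of levels (default 100).
#' @param tract tract name for the result.
#' @return a \linkS4class{TractProfile}.
#' @export
tractProfile <- function(volume, tractMask, axisDirection = NULL,
                         nLevels = 100L, tract = "tract") {
  a <- if (is(volume, "MetricVolume")) volume@data else volume
  checkGeometry(a, tractMask, "volume and tract mask")
  idx <- which(tractMask > 0)
  if (!length(idx)) stop("tract mask is empty")
  coords <- which(tractMask > 0, arr.ind = TRUE)
  if (is.null(axisDirection)) {
    cc <- sweep(coords, 2, colMeans(coords))
    axisDirection <- prcomp(cc, center = FALSE)$rotation[, 1]
  }
  axisDirection <- axisDirection / sqrt(sum(axisDirection^2))
  proj <- as.numeric(coords %*% axisDirection)
  lo <- min(proj); hi <- max(proj)
  if (hi <= lo) stop("tract has zero extent along the requested axis")
  bin <- pmin(pmax(ceiling((proj - lo) / (hi - lo) * nLevels), 1L), nLevels)
  vals <- a[idx]
  counts <- tabulate(bin, nLevels)
  if (any(counts == 0))
    stop("no tract voxels in level(s) ", paste(which(counts == 0), collapse = ", "),
         " of ", nLevels, "; reduce nLevels for short tracts")
  prof <- as.numeric(tapply(vals, factor(bin, levels = seq_len(nLevels)), mean))
  new("TractProfile", tract = tract, values = prof,
      nLevels = as.integer(nLevels))
}

#' Per-location Pearson correlation between tract profiles and age
#'
#' For each of the profile's levels, Pearson's r (and two-sided p) between
#' the per-subject profile value and age across subjects; significance at
#' p < 0.05. Zero-variance locations are flagged and excluded from the
#' significant count.
#'
#' @param profiles list of \linkS4class{TractProfile}s (one per subject, same
#'   tract and length) or a subjects x levels matrix.
#' @param ages numeric vector of subject ages.
#' @return data.frame with columns location, r, p, significant, degenerate.
#' @export
profileAgeCorrelation <- function(profiles, ages) {
  M <- if (is.matrix(profiles)) profiles
       else do.call(rbind, lapply(profiles, profileValues))
  if (nrow(M) != length(ages)) stop("one age per subject profile required")
  if (nrow(M) < 3) stop("need >= 3 subjects")
  out <- data.frame(location = seq_len(ncol(M)), r = NA_real_, p = NA_real_,
                    significant = FALSE, degenerate = FALSE)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (sd(v) == 0 || sd(ages) == 0) {
      out$degenerate[j] <- TRUE
      next
    }
    ct <- cor.test(v, ages, method = "pearson")
    out$r[j] <- unname(ct$estimate)
    out$p[j] <- ct$p.value
    out$significant[j] <- ct$p.value < 0.05
  }
  out
}

#' White-matter histograms per subject and pooled
#'
#' Counts of masked voxel values in \code{bins} equal-width bins over the
#' metric range; the pooled histogram is the sum of the per-subject ones.
#'
#' @param dataset a \linkS4class{SiteDataset}.
#' @param mask binary 3D mask.
#' @param bins number of bins (>= 2).
#' @return list with \code{breaks}, \code{mids}, \code{perSubject} (matrix
#'   subjects x bins) and \code{pooled}.
#' @export
wmHistogram <- function(dataset, mask = datasetMask(dataset), bins = 50L) {
  if (bins < 2) stop("bins must be >= 2")
  idx <- which(mask > 0)
  r <- metricRange(metricName(dataset))
  breaks <- seq(r[1], r[2], length.out = bins + 1L)
  per <- t(vapply(dataset@volumes, function(v) {
    b <- findInterval(v@data[idx], breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
    tabulate(b, bins)
  }, numeric(bins)))
  rownames(per) <- subjectIds(dataset)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       perSubject = per, pooled = colSums(per))
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic for the first group with tie correction; exact
#' two-sided p by enumeration for small tie-free samples (both n <= 20),
#' normal approximation with continuity correction otherwise.
#'
#' @param groupA,groupB numeric vectors.
#' @return list with \code{U} (first group), \code{p} (two-sided) and
#'   \code{exact} (logical).
#' @export
mannWhitneyU <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("both groups must be non-empty")
  nA <- length(groupA); nB <- length(groupB)
  r <- rank(c(groupA, groupB))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- anyDuplicated(c(groupA, groupB)) > 0
  exact <- (nA <= 20 && nB <= 20) && !ties
  wt <- suppressWarnings(wilcox.test(groupA, groupB, exact = exact,
                                     correct = TRUE))
  list(U = unname(U), p = wt$p.value, exact = exact)
}

tStatMatrix <- function(Y, labels) {
  # equal-variance two-sample t per row of Y (V x n); labels logical for A
  n1 <- sum(labels); n2 <- sum(!labels)
  m1 <- rowMeans(Y[, labels, drop = FALSE])
  m2 <- rowMeans(Y[, !labels, drop = FALSE])
  v1 <- rowSums((Y[, labels, drop = FALSE] - m1)^2)
  v2 <- rowSums((Y[, !labels, drop = FALSE] - m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0] <- 0
  t
}

#' Voxel-wise two-sample group test with multiplicity control
#'
#' Simplified stand-in for skeleton-based group testing (not TBSS: no
#' skeleton projection, no TFCE). Either a per-voxel Mann-Whitney test with
#' Benjamini-Hochberg FDR correction, or a max-statistic permutation test
#' (equal-variance t statistic, site labels shuffled) controlling the
#' family-wise error rate. The direction map records which site is higher.
#'
#' @param siteA,siteB \linkS4class{SiteDataset}s (>= 3 subjects each).
#' @param mask binary 3D mask.
#' @param method "permutation_maxstat" or "mannwhitney_fdr".
#' @param nPermutations label permutations (>= 100) for the permutation
#'   method.
#' @param seed RNG seed for the permutations.
#' @param alpha significance level (default 0.05).
#' @return a \linkS4class{GroupTestResult}.
#' @export
voxelwiseGroupTest <- function(siteA, siteB, mask = datasetMask(siteA),
                               method = c("permutation_maxstat",
                                          "mannwhitney_fdr"),
                               nPermutations = 1000L, seed = 1L,
                               alpha = 0.05) {
  method <- match.arg(method)
  checkGeometry(datasetMask(siteA), datasetMask(siteB))
  if (nSubjects(siteA) < 3 || nSubjects(siteB) < 3)
    stop("need >= 3 subjects per site")
  idx <- which(mask > 0)
  YA <- cohortMatrix(siteA, idx)
  YB <- cohortMatrix(siteB, idx)
  Y <- cbind(YA, YB)
  nA <- ncol(YA); nB <- ncol(YB)
  labels <- c(rep(TRUE, nA), rep(FALSE, nB))

  if (method == "permutation_maxstat") {
    if (nPermutations < 100)
      stop("nPermutations must be >= 100 for the permutation method")
    tObs <- tStatMatrix(Y, labels)
    maxNull <- withSeed(seed, vapply(seq_len(nPermutations), function(b) {
      perm <- sample(labels)
      max(abs(tStatMatrix(Y, perm)))
    }, 0))
    p <- (1 + vapply(abs(tObs), function(t0) sum(maxNull >= t0), 0)) /
      (nPermutations + 1)
  } else {
    p <- apply(Y, 1, function(v) {
      suppressWarnings(wilcox.test(v[labels], v[!labels])$p.value)
    })
    p[is.na(p)] <- 1
    p <- p.adjust(p, method = "BH")
    tObs <- tStatMatrix(Y, labels)
  }

  pMap <- array(1, dim(mask))
  pMap[idx] <- p
  sig <- array(0, dim(mask))
  sig[idx] <- as.numeric(p <= alpha)
  dir <- array(0, dim(mask))
  dir[idx] <- -sign(tObs)          # +1 where site B higher
  dir[sig == 0] <- 0
  new("GroupTestResult", pMap = pMap, sigMask = sig, directionMap = dir,
      method = method, alpha = alpha, mask = mask)
}

#' Union of group-test results over cross-validation folds
#'
#' Significance mask is the union of the per-fold masks (a voxel is reported
#' if it was significant in any run); the p map is the per-voxel minimum and
#' the direction is taken from the fold attaining it.
#'
#' @param results list of \linkS4class{GroupTestResult}s with one method and
#'   geometry.
#' @return a combined \linkS4class{GroupTestResult}.
#' @export
unionOverFolds <- function(results) {
  if (!length(results)) stop("no results to combine")
  methods <- vapply(results, function(r) r@method, "")
  if (length(unique(methods)) != 1L)
    stop("cannot combine results of different methods: ",
         paste(unique(methods), collapse = ", "))
  base <- results[[1]]
  pMin <- base@pMap; sig <- base@sigMask; dir <- base@directionMap
  for (r in results[-1]) {
    checkGeometry(base@pMap, r@pMap, "fold results")
    take <- r@pMap < pMin
    dir[take] <- r@directionMap[take]
    pMin <- pmin(pMin, r@pMap)
    sig <- pmax(sig, r@sigMask)
  }
  new("GroupTestResult", pMap = pMin, sigMask = sig, directionMap = dir,
      method = base@method, alpha = base@alpha, mask = base@mask)
}
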