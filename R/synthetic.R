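# Synthetic phantom cohorts: an FA-like template with tube "tracts", smooth
# random site-effect fields, and cohort sampling with known covariate
# structure. Everything downstream is validated against the ground truth
# these generators provide.

#' Build a synthetic FA template with white-matter mask and tube tracts
#'
#' Constructs an ellipsoidal white-matter region with a smoothly varying
#' baseline FA around 0.3 and \code{nTracts} elongated tube tracts running
#' along the first (X) axis with higher baseline FA (about 0.5), emulating the
#' statistical structure of a population FA template plus a tract atlas.
#' Deterministic for a fixed seed.
#'
#' @param shape integer(3) volume shape, at least c(32, 32, 8).
#' @param nTracts number of non-overlapping tracts (>= 1).
#' @param seed integer seed.
#' @param voxelSizeMm voxel edge lengths in mm.
#' @return a \linkS4class{TemplateAtlas}.
#' @examples
#' tpl <- makeTemplate(c(48, 48, 12), nTracts = 2, seed = 1)
#' tpl
#' @export
makeTemplate <- function(shape = c(64, 64, 16), nTracts = 3, seed = 1,
                         voxelSizeMm = c(2, 2, 2)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(32L, 32L, 8L)))
    stop("shape must be 3 integers, each at least (32, 32, 8)")
  if (nTracts < 1L) stop("nTracts must be >= 1")

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  gx <- (seq_len(nx) - cx) / (nx / 2)
  gy <- (seq_len(ny) - cy) / (ny / 2)
  gz <- (seq_len(nz) - cz) / (nz / 2)
  r2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
  wm <- array(as.numeric(r2 <= 0.8^2), shape)

  # tube tracts along X, spaced across the central Y band at mid Z
  radius <- max(1L, round(min(ny, nz) / 12))
  yPos <- cy + (seq_len(nTracts) - (nTracts + 1) / 2) * (2 * radius + 2)
  if (any(yPos < radius + 1) || any(yPos > ny - radius))
    stop("shape too small to contain ", nTracts,
         " non-overlapping tracts of radius ", radius,
         " with spacing ", 2 * radius + 2, " along Y")
  iy <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  iz <- seq_len(nz)

  tractMasks <- list()
  tractAxes <- list()
  for (t in seq_len(nTracts)) {
    d2 <- outer(array(0, c(nx, ny)) + (iy - yPos[t])^2, (iz - cz)^2, "+")
    tube <- array(as.numeric(d2 <= radius^2), shape) * wm
    # keep the tract inside WM along its length; trim ends outside the ellipsoid
    if (sum(tube) == 0) stop("shape too small: tract ", t, " falls outside white matter")
    tractMasks[[paste0("tract", t)]] <- tube
    tractAxes[[paste0("tract", t)]] <- c(1, 0, 0)
  }

  base <- withSeed(seed, {
    variation <- smoothRandomField(shape, sigmaVox = 4 / voxelSizeMm, seed = seed)
    b <- (0.30 + 0.03 * variation) * wm
    b
  })
  for (t in seq_along(tractMasks)) base <- base + 0.18 * tractMasks[[t]]
  base <- pmin(pmax(base, 0), 0.95) * wm
  base[wm > 0] <- pmin(pmax(base[wm > 0], 0.05), 0.95)

  new("TemplateAtlas", baseMap = base, wmMask = wm, tractMasks = tractMasks,
      tractAxes = tractAxes, shape = shape)
}

#' Create a synthetic site-effect field
#'
#' Site effects are modelled as spatially smooth random gain/offset fields
#' plus an optional monotone power nonlinearity and additive site noise,
#' spanning the premise that scanner differences cause spatially
#' heterogeneous, nonlinear metric changes. Smooth fields are seeded white
#' noise smoothed with a Gaussian kernel of width \code{smoothnessMm} and
#' normalized to the requested mean.
#'
#' Kinds: \code{identity} (g = 1, a = 0, gamma = 1); \code{multiplicative}
#' (spatial mean of g equals 1 + magnitude); \code{additive} (spatial mean of
#' a equals magnitude, in metric units); \code{nonlinear} (gamma = 1 +
#' magnitude); \code{mixed} (gain with mean 1 + 0.7 magnitude plus offset
#' with mean 0.3 magnitude x 0.35, so `magnitude` approximates the fractional
#' white-matter mean shift for FA around 0.35).
#'
#' @param shape integer(3).
#' @param kind one of identity, multiplicative, additive, nonlinear, mixed.
#' @param magnitude effect magnitude (>= 0); see kinds above.
#' @param smoothnessMm Gaussian smoothing length of the random fields, mm.
#' @param seed integer seed.
#' @param noiseSdSite additive site-noise standard deviation.
#' @param voxelSizeMm voxel size in mm (converts smoothnessMm to voxels).
#' @return a \linkS4class{SiteEffectField}.
#' @examples
#' fld <- makeSiteEffect(c(32, 32, 8), "multiplicative", 0.05, seed = 2)
#' mean(multField(fld))  # ~1.05
#' @export
makeSiteEffect <- function(shape, kind = c("identity", "multiplicative",
                                           "additive", "nonlinear", "mixed"),
                           magnitude = 0.05, smoothnessMm = 8, seed = 1,
                           noiseSdSite = 0, voxelSizeMm = c(2, 2, 2)) {
  if (length(kind) != 1L || !kind %in% c("identity", "multiplicative",
                                         "additive", "nonlinear", "mixed"))
    stop("unknown kind '", paste(kind, collapse = ","),
         "'; valid kinds: identity, multiplicative, additive, nonlinear, mixed")
  if (magnitude < 0) stop("magnitude must be >= 0")
  shape <- as.integer(shape)
  sigmaVox <- smoothnessMm / voxelSizeMm

  smoothAt <- function(offset) {
    # standardized smooth field re-centred to `offset`; relative fluctuation
    # is half the magnitude so the field varies but keeps its sign
    u <- smoothRandomField(shape, sigmaVox, seed + offset)
    u
  }
  g <- array(1, shape); a <- array(0, shape); gammaNl <- 1; nss <- 0

  if (kind == "multiplicative" || kind == "mixed") {
    m <- if (kind == "mixed") 0.7 * magnitude else magnitude
    g <- (1 + m) + 0.5 * m * smoothAt(1L)
    for (i in 1:3) {                       # keep strictly positive, re-centre
      g <- pmax(g, 0.01)
      g <- g - mean(g) + (1 + m)
    }
    g <- pmax(g, 0.01)
  }
  if (kind == "additive" || kind == "mixed") {
    m <- if (kind == "mixed") 0.3 * magnitude * 0.35 else magnitude
    a <- m + 0.5 * m * smoothAt(2L)
  }
  if (kind == "nonlinear") gammaNl <- 1 + magnitude
  if (kind != "identity") nss <- noiseSdSite

  new("SiteEffectField", kind = kind, multField = g, addField = a,
      gammaNl = gammaNl, noiseSdSite = nss, smoothnessMm = smoothnessMm,
      seed = as.integer(seed))
}

#' Identity site-effect field
#' @param shape integer(3)
#' @return a \linkS4class{SiteEffectField} with g = 1, a = 0, gamma = 1.
#' @export
identityField <- function(shape) makeSiteEffect(shape, "identity", 0)

#' Covariate-effect model for phantom cohorts
#'
#' Defaults emulate a neonatal FA cohort: postmenstrual ages uniform on
#' 38-44 weeks, a 2:1 male:female ratio, a positive age effect on tract FA
#' (0.01 per week), a small female-positive sex effect on tract FA, and
#' between-subject and voxel noise of 0.02 FA each.
#'
#' @param ageRange numeric(2) postmenstrual-age range in weeks.
#' @param maleFraction fraction of males.
#' @param betaAge FA per week inside tract masks.
#' @param betaSex additive FA offset for females inside tract masks.
#' @param subjectSd between-subject FA SD (constant per subject over WM).
#' @param noiseSd voxel noise SD over WM.
#' @return a \linkS4class{CovariateModel}.
#' @export
covariateModel <- function(ageRange = c(38, 44), maleFraction = 2 / 3,
                           betaAge = 0.01, betaSex = 0.01,
                           subjectSd = 0.02, noiseSd = 0.02) {
  new("CovariateModel", ageRange = ageRange, maleFraction = maleFraction,
      betaAge = betaAge, betaSex = betaSex, subjectSd = subjectSd,
      noiseSd = noiseSd)
}

#' Sample one site-free phantom subject
#'
#' Tract-mask FA equals the template baseline plus
#' \code{betaAge * (age - midpoint of ageRange)} plus \code{betaSex} for
#' females; a per-subject random offset (SD \code{subjectSd}) and voxel noise
#' (SD \code{noiseSd}) act over the whole white-matter mask. Values are
#' clipped to the FA range [0, 1].
#'
#' @param template a \linkS4class{TemplateAtlas}.
#' @param covariates a \linkS4class{CovariateModel}.
#' @param age postmenstrual age (weeks), within the model's range.
#' @param sex "male" or "female".
#' @param seed integer seed.
#' @param subjectId,site labels recorded on the volume.
#' @param voxelSizeMm voxel size in mm.
#' @return a \linkS4class{MetricVolume}.
#' @export
sampleSubject <- function(template, covariates, age, sex, seed,
                          subjectId = "subj", site = "site1",
                          voxelSizeMm = c(2, 2, 2)) {
  stopifnot(is(template, "TemplateAtlas"), is(covariates, "CovariateModel"))
  if (age < covariates@ageRange[1] || age > covariates@ageRange[2])
    stop("age ", age, " outside the covariate model's range [",
         covariates@ageRange[1], ", ", covariates@ageRange[2], "]")
  if (!sex %in% c("male", "female")) stop("sex must be male or female")

  wm <- template@wmMask
  tractUnion <- Reduce(`+`, template@tractMasks)
  tractUnion <- pmin(tractUnion, 1)
  mid <- mean(covariates@ageRange)
  vol <- template@baseMap +
    tractUnion * (covariates@betaAge * (age - mid) +
                  covariates@betaSex * (sex == "female"))
  withSeed(seed, {
    if (covariates@subjectSd > 0)
      vol <- vol + wm * rnorm(1, 0, covariates@subjectSd)
    if (covariates@noiseSd > 0)
      vol <- vol + wm * array(rnorm(length(wm), 0, covariates@noiseSd), dim(wm))
  })
  vol <- clipToMetric(vol, "FA") * (template@baseMap > 0 | wm > 0)
  vol <- array(vol, dim(wm))

  new("MetricVolume", data = vol, voxelSize = voxelSizeMm,
      subjectId = subjectId, site = site, ageWeeks = age, sex = sex,
      metricName = "FA")
}

#' Apply a site-effect field to a metric volume
#'
#' Within tissue support (voxels with a positive input value) the output is
#' \code{clip((g(v) x(v) + a(v))^gamma + noise)}; background voxels stay
#' exactly zero (site effects are measurement effects on tissue). The site
#' label of the returned volume is suffixed unless \code{site} is given.
#'
#' @param volume a \linkS4class{MetricVolume}.
#' @param field a \linkS4class{SiteEffectField} of matching shape.
#' @param seed seed for the site-noise draw.
#' @param site new site label (default: keep the input's).
#' @return a transformed \linkS4class{MetricVolume}.
#' @export
applySiteEffect <- function(volume, field, seed = 1, site = NULL) {
  stopifnot(is(volume, "MetricVolume"), is(field, "SiteEffectField"))
  x <- volume@data
  if (!sameShape(x, field@multField))
    stop("volume shape (", paste(dim(x), collapse = "x"),
         ") does not match field shape (",
         paste(dim(field@multField), collapse = "x"), ")")
  support <- x > 0
  y <- x
  base <- pmax(field@multField[support] * x[support] + field@addField[support], 0)
  out <- base^field@gammaNl
  if (field@noiseSdSite > 0)
    out <- out + withSeed(seed, rnorm(length(out), 0, field@noiseSdSite))
  y[support] <- out
  y <- clipToMetric(y, volume@metricName)
  new("MetricVolume", data = array(y, dim(x)), voxelSize = volume@voxelSize,
      subjectId = volume@subjectId,
      site = if (is.null(site)) volume@site else site,
      ageWeeks = volume@ageWeeks, sex = volume@sex,
      metricName = volume@metricName)
}

#' Generate a phantom cohort for one site
#'
#' Ages are drawn uniformly from the covariate model's range; sex is assigned
#' by deterministic proportion (exactly \code{floor(n * maleFraction)} males,
#' order shuffled by seed) so a 28:14 ratio at n = 42 with maleFraction = 2/3
#' is reproduced exactly. Each subject is passed through the site-effect
#' field.
#'
#' @param template a \linkS4class{TemplateAtlas}.
#' @param nSubjects cohort size (>= 2).
#' @param covariates a \linkS4class{CovariateModel}.
#' @param field a \linkS4class{SiteEffectField} (identity for the reference
#'   site).
#' @param seed integer seed; per-subject seeds are derived from it.
#' @param site site label.
#' @param idPrefix subject-id prefix.
#' @return a \linkS4class{SiteDataset} with the template's WM mask attached.
#' @examples
#' tpl <- makeTemplate(c(32, 32, 8), 1, seed = 1)
#' cohort <- generateCohort(tpl, 6, covariateModel(), identityField(dim(wmMask(tpl))),
#'                          seed = 3, site = "site1")
#' manifest(cohort)
#' @export
generateCohort <- function(template, nSubjects, covariates, field, seed = 1,
                           site = "site1", idPrefix = site) {
  stopifnot(is(template, "TemplateAtlas"))
  if (nSubjects < 2) stop("nSubjects must be >= 2")
  nMale <- floor(nSubjects * covariates@maleFraction)
  sexes <- c(rep("male", nMale), rep("female", nSubjects - nMale))
  vols <- withSeed(seed, {
    sexes <- sample(sexes)
    ages <- runif(nSubjects, covariates@ageRange[1], covariates@ageRange[2])
    subjectSeeds <- sample.int(.Machine$integer.max - 1L, nSubjects)
    lapply(seq_len(nSubjects), function(i) {
      v <- sampleSubject(template, covariates, ages[i], sexes[i],
                         seed = subjectSeeds[i],
                         subjectId = sprintf("%s_%02d", idPrefix, i),
                         site = site)
      applySiteEffect(v, field, seed = subjectSeeds[i] + 1L, site = site)
    })
  })
  new("SiteDataset", site = site, volumes = vols, mask = template@wmMask)
}
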