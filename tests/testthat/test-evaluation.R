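# Evaluation statistics: error maps, RMSE, Cohen's d, tract profiles, age
# correlations, histograms, Mann-Whitney, group tests, fold unions.

toyCohort <- function(mats, site = "s", shape = c(6, 6, 2), ages = NULL,
                      sexes = NULL) {
  n <- length(mats)
  if (is.null(ages)) ages <- rep(40, n)
  if (is.null(sexes)) sexes <- rep("male", n)
  vols <- lapply(seq_len(n), function(i)
    new("MetricVolume", data = array(mats[[i]], shape),
        voxelSize = c(2, 2, 2), subjectId = sprintf("%s%02d", site, i),
        site = site, ageWeeks = ages[i], sex = sexes[i], metricName = "FA"))
  new("SiteDataset", site = site, volumes = vols, mask = array(1, shape))
}

test_that("absolute-error map equals a brute-force per-voxel loop", {
  set.seed(1)
  A <- toyCohort(replicate(3, runif(72, 0.2, 0.6), simplify = FALSE), "A")
  B <- toyCohort(replicate(4, runif(72, 0.2, 0.6), simplify = FALSE), "B")
  m <- absoluteErrorMap(A, B)
  for (v in sample(72, 10)) {
    ma <- mean(sapply(volumes(A), function(x) metricData(x)[v]))
    mb <- mean(sapply(volumes(B), function(x) metricData(x)[v]))
    expect_equal(m[v], abs(ma - mb), tolerance = 1e-12)
  }
  expect_true(all(absoluteErrorMap(A, A) == 0))

  cA <- toyCohort(list(rep(0.45, 72)), "A")
  cB <- toyCohort(list(rep(0.40, 72)), "B")
  expect_equal(unique(as.numeric(absoluteErrorMap(cA, cB))), 0.05,
               tolerance = 1e-12)
})

test_that("RMSE to the reference group mean has its closed forms", {
  set.seed(2)
  R <- toyCohort(replicate(4, runif(72, 0.3, 0.5), simplify = FALSE), "R")
  idx <- which(datasetMask(R) > 0)
  gm <- rowMeans(sapply(volumes(R), function(v) metricData(v)[idx]))

  exact <- volumes(R)[[1]]
  exact@data <- array(gm, c(6, 6, 2))
  expect_equal(rmseToReference(exact, R), 0)

  shifted <- exact
  shifted@data <- shifted@data + 0.05
  expect_equal(rmseToReference(shifted, R), 0.05, tolerance = 1e-12)

  probe <- volumes(R)[[2]]
  brute <- sqrt(mean(sapply(seq_along(idx), function(i)
    (metricData(probe)[idx[i]] - gm[i])^2)))
  expect_equal(rmseToReference(probe, R), brute, tolerance = 1e-12)
})

test_that("Cohen's d matches hand evaluation and is antisymmetric", {
  r <- cohensD(c(2, 4), c(1, 3))
  expect_equal(effectSize(r), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(r@sdPooled, sqrt(2), tolerance = 1e-12)

  expect_equal(effectSize(cohensD(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(effectSize(cohensD(c(1, 1), c(1, 1))), 0)   # declared rule
  expect_error(cohensD(c(1, 1), c(2, 2)), "zero pooled")
  expect_error(cohensD(1, c(1, 2)), "at least 2")

  set.seed(3)
  for (i in 1:10) {
    f <- rnorm(sample(3:9, 1)); m <- rnorm(sample(3:9, 1))
    expect_equal(effectSize(cohensD(f, m)), -effectSize(cohensD(m, f)),
                 tolerance = 1e-12)
    # independent step-by-step pooled-SD evaluation
    sp <- sqrt(((length(f) - 1) * var(f) + (length(m) - 1) * var(m)) /
                 (length(f) + length(m) - 2))
    expect_equal(effectSize(cohensD(f, m)), (mean(f) - mean(m)) / sp,
                 tolerance = 1e-12)
  }
})

test_that("tract profiles bin along the axis as declared", {
  tpl <- fixtureTemplate()
  tm <- tractMasks(tpl)[[1]]
  const <- array(0.37, dim(tm))
  pr <- tractProfile(const, tm, nLevels = 10)
  expect_equal(profileValues(pr), rep(0.37, 10))

  # volume equal to the x coordinate -> strictly increasing profile
  xs <- array(rep(seq_len(dim(tm)[1]), times = prod(dim(tm)[2:3])), dim(tm))
  pr2 <- tractProfile(xs / max(xs), tm, axisDirection = c(1, 0, 0),
                      nLevels = 8)
  expect_true(all(diff(profileValues(pr2)) > 0))

  # 100 levels on a long synthetic tract
  long <- array(0, c(128, 32, 8)); long[10:119, 15:17, 4:5] <- 1
  v <- array(0.5, dim(long))
  pr3 <- tractProfile(v, long, nLevels = 100)
  expect_length(profileValues(pr3), 100)

  short <- array(0, dim(tm)); short[2:4, 2, 2] <- 1
  expect_error(tractProfile(const, short, nLevels = 50), "reduce nLevels")
})

test_that("profile-age correlations detect the planted age effect", {
  # perfectly linear in age at one location -> r = 1 there
  ages <- c(38, 39, 41, 43, 44)
  M <- matrix(rnorm(5 * 6), 5, 6)
  M[, 3] <- 0.01 * ages
  out <- profileAgeCorrelation(M, ages)
  expect_equal(out$r[3], 1, tolerance = 1e-12)
  expect_true(out$significant[3])

  # zero-variance location flagged, excluded
  M[, 5] <- 0.4
  out <- profileAgeCorrelation(M, ages)
  expect_true(out$degenerate[5])
  expect_false(isTRUE(out$significant[5]))

  # null calibration: permuted ages -> about 5% of locations significant
  set.seed(4)
  hits <- 0; total <- 0
  for (rep in 1:30) {
    Mn <- matrix(rnorm(12 * 25), 12, 25)
    agesN <- sample(ages, 12, replace = TRUE) + rnorm(12, 0, 0.1)
    o <- profileAgeCorrelation(Mn, agesN)
    hits <- hits + sum(o$significant, na.rm = TRUE); total <- total + 25
  }
  expect_lt(abs(hits / total - 0.05), 0.035)

  # synthetic cohort with betaAge > 0 -> positive median r inside the tract
  tpl <- fixtureTemplate()
  cv <- covariateModel(betaAge = 0.01, subjectSd = 0.005, noiseSd = 0.01)
  co <- generateCohort(tpl, 15, cv, identityField(fixtureShape), seed = 6)
  tm <- tractMasks(tpl)[[1]]
  profs <- lapply(volumes(co), function(v)
    tractProfile(metricData(v), tm, axisDirection = c(1, 0, 0), nLevels = 10))
  o <- profileAgeCorrelation(profs, sapply(volumes(co), ageWeeks))
  expect_gt(median(o$r, na.rm = TRUE), 0)
})

test_that("white-matter histograms conserve counts and shift with gain", {
  px <- fixturePair(n = 4, magnitude = 0.08, seed = 41)
  h1 <- wmHistogram(px$site1, bins = 30)
  nWm <- sum(datasetMask(px$site1))
  expect_true(all(rowSums(h1$perSubject) == nWm))
  expect_equal(h1$pooled, colSums(h1$perSubject))

  h2 <- wmHistogram(px$site2, bins = 30)
  meanOf <- function(h) sum(h$mids * h$pooled) / sum(h$pooled)
  expect_gt(meanOf(h1), meanOf(h2))    # multiplicative gain shifts right

  expect_error(wmHistogram(px$site1, bins = 1), ">= 2")
})

test_that("Mann-Whitney U reproduces exact enumeration and identities", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)   # 2 / choose(6,3)
  expect_true(r$exact)

  r2 <- mannWhitneyU(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$U, 9)                        # nA*nB - U
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    expect_equal(mannWhitneyU(b, a)$U,
                 length(a) * length(b) - mannWhitneyU(a, b)$U)
    # agreement with the standard rank-sum implementation
    expect_equal(mannWhitneyU(a, b)$U,
                 unname(wilcox.test(a, b)$statistic))
  }

  same <- mannWhitneyU(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.9)
})

test_that("group tests flag planted effects with correct direction", {
  set.seed(6)
  base <- replicate(20, runif(72, 0.35, 0.45), simplify = FALSE)
  A <- toyCohort(base[1:10], "A")
  hot <- 1:12
  Bm <- lapply(base[11:20], function(v) { v[hot] <- v[hot] + 0.1; v })
  B <- toyCohort(Bm, "B")

  gt <- voxelwiseGroupTest(A, B, method = "permutation_maxstat",
                           nPermutations = 300, seed = 7)
  sig <- which(significanceMask(gt) > 0)
  expect_true(all(hot %in% sig))
  expect_true(all(directionMap(gt)[hot] == 1))   # site B higher
  expect_lt(length(setdiff(sig, hot)), 4)

  gtF <- voxelwiseGroupTest(A, B, method = "mannwhitney_fdr")
  expect_true(mean(hot %in% which(significanceMask(gtF) > 0)) > 0.8)

  ident <- voxelwiseGroupTest(A, A, method = "permutation_maxstat",
                              nPermutations = 300, seed = 8)
  expect_equal(sum(significanceMask(ident)), 0)

  expect_error(voxelwiseGroupTest(A, B, method = "permutation_maxstat",
                                  nPermutations = 50), ">= 100")
})

test_that("fold unions take any-fold significance and minimum p", {
  set.seed(7)
  A <- toyCohort(replicate(8, runif(72, 0.3, 0.5), simplify = FALSE), "A")
  B <- toyCohort(replicate(8, runif(72, 0.3, 0.5), simplify = FALSE), "B")
  g1 <- voxelwiseGroupTest(A, B, method = "mannwhitney_fdr")
  g2 <- voxelwiseGroupTest(B, A, method = "mannwhitney_fdr")
  u <- unionOverFolds(list(g1, g2))
  expect_identical(pMap(u), pmin(pMap(g1), pMap(g2)))
  expect_identical(significanceMask(u),
                   pmax(significanceMask(g1), significanceMask(g2)))
  expect_identical(pMap(unionOverFolds(list(g1))), pMap(g1))

  g3 <- voxelwiseGroupTest(A, B, method = "permutation_maxstat",
                           nPermutations = 200, seed = 3)
  expect_error(unionOverFolds(list(g1, g3)), "different methods")
})
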