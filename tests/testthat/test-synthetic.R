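# Phantom generator: template structure, site-effect fields, subject
# sampling, cohort assembly.

test_that("templates are deterministic and satisfy their invariants", {
  a <- makeTemplate(c(64, 64, 16), nTracts = 3, seed = 1)
  b <- makeTemplate(c(64, 64, 16), nTracts = 3, seed = 1)
  expect_identical(baseMap(a), baseMap(b))
  expect_identical(tractMasks(a), tractMasks(b))

  wm <- wmMask(a)
  inside <- baseMap(a)[wm > 0]
  expect_true(all(inside > 0 & inside < 1))
  expect_true(all(baseMap(a)[wm == 0] == 0))
  for (tm in tractMasks(a)) expect_true(all(wm[tm > 0] == 1))

  one <- makeTemplate(c(32, 32, 8), nTracts = 1, seed = 2)
  expect_length(tractMasks(one), 1L)
})

test_that("tract baseline FA exceeds surrounding white matter", {
  a <- makeTemplate(c(64, 64, 16), nTracts = 3, seed = 1)
  tract <- pmin(Reduce(`+`, tractMasks(a)), 1)
  rest <- wmMask(a) * (1 - tract)
  expect_gt(mean(baseMap(a)[tract > 0]), mean(baseMap(a)[rest > 0]))
})

test_that("impossible tract packing is rejected with a clear error", {
  expect_error(makeTemplate(c(32, 32, 8), nTracts = 12, seed = 1),
               "non-overlapping tracts")
})

test_that("site-effect kinds satisfy their contracts", {
  shape <- c(32, 32, 8)
  idf <- makeSiteEffect(shape, "identity", 0.3, seed = 1)
  expect_true(all(multField(idf) == 1))
  expect_true(all(addField(idf) == 0))
  expect_equal(idf@gammaNl, 1)
  expect_equal(idf@noiseSdSite, 0)

  mf <- makeSiteEffect(shape, "multiplicative", 0.05, seed = 2)
  expect_equal(mean(multField(mf)), 1.05, tolerance = 0.005)
  expect_true(all(multField(mf) > 0))
  expect_gt(sd(multField(mf)), 0)           # spatially varying

  mf2 <- makeSiteEffect(shape, "multiplicative", 0.05, seed = 2)
  expect_identical(multField(mf), multField(mf2))

  af <- makeSiteEffect(shape, "additive", 0.02, seed = 3)
  expect_equal(mean(addField(af)), 0.02, tolerance = 1e-12)

  expect_error(makeSiteEffect(shape, "quadratic", 0.1), "valid kinds")
})

test_that("subject sampling reproduces the covariate-effect arithmetic", {
  tpl <- fixtureTemplate()
  quiet <- quietCovariates(betaAge = 0, betaSex = 0)
  v <- sampleSubject(tpl, quiet, age = 41, sex = "male", seed = 1)
  expect_equal(metricData(v), baseMap(tpl))

  # 0.01/week slope, 2 weeks apart -> tract means differ by exactly 0.02
  cv <- quietCovariates(betaAge = 0.01, betaSex = 0)
  v1 <- sampleSubject(tpl, cv, age = 40, sex = "male", seed = 1)
  v2 <- sampleSubject(tpl, cv, age = 42, sex = "male", seed = 1)
  tract <- pmin(Reduce(`+`, tractMasks(tpl)), 1)
  d <- metricData(v2) - metricData(v1)
  expect_equal(mean(d[tract > 0]), 0.02, tolerance = 1e-12)
  expect_true(all(d[tract == 0] == 0))

  # sex effect confined to tract masks
  cs <- quietCovariates(betaAge = 0, betaSex = 0.02)
  vm <- sampleSubject(tpl, cs, age = 41, sex = "male", seed = 1)
  vf <- sampleSubject(tpl, cs, age = 41, sex = "female", seed = 1)
  d <- metricData(vf) - metricData(vm)
  expect_equal(mean(d[tract > 0]), 0.02, tolerance = 1e-12)
  expect_true(all(d[tract == 0] == 0))

  expect_error(sampleSubject(tpl, cv, age = 55, sex = "male", seed = 1),
               "outside")
})

test_that("site-effect application follows the declared transform", {
  tpl <- fixtureTemplate()
  v <- sampleSubject(tpl, quietCovariates(), age = 41, sex = "male", seed = 1)

  idf <- identityField(fixtureShape)
  expect_equal(metricData(applySiteEffect(v, idf)), metricData(v))

  # constant gain 1.05: 0.4 -> 0.42
  g <- idf
  g@multField[] <- 1.05
  flat <- v
  flat@data[wmMask(tpl) > 0] <- 0.4
  out <- applySiteEffect(flat, g)
  expect_equal(unique(metricData(out)[wmMask(tpl) > 0]), 0.42,
               tolerance = 1e-12)

  # power nonlinearity: 0.5^1.1
  nl <- idf
  nl@gammaNl <- 1.1
  flat@data[wmMask(tpl) > 0] <- 0.5
  out <- applySiteEffect(flat, nl)
  expect_equal(unique(metricData(out)[wmMask(tpl) > 0]), 0.5^1.1,
               tolerance = 1e-12)

  bad <- makeSiteEffect(c(32, 32, 12), "identity", 0)
  expect_error(applySiteEffect(v, bad), "shape")
})

test_that("cohorts reproduce the 28:14 sex ratio and are seed-stable", {
  tpl <- fixtureTemplate()
  co <- generateCohort(tpl, 42, covariateModel(maleFraction = 2 / 3),
                       identityField(fixtureShape), seed = 9)
  man <- manifest(co)
  expect_equal(unname(table(man$sex)[c("male", "female")]), c(28L, 14L),
               ignore_attr = TRUE)
  expect_true(all(man$age_weeks >= 38 & man$age_weeks <= 44))

  co2 <- generateCohort(tpl, 42, covariateModel(maleFraction = 2 / 3),
                        identityField(fixtureShape), seed = 9)
  expect_identical(lapply(volumes(co), metricData),
                   lapply(volumes(co2), metricData))

  # identity field, all randomness off -> every subject has identical voxels
  # up to covariate effects; with betaAge = betaSex = 0 they are identical
  quiet <- quietCovariates(betaAge = 0, betaSex = 0)
  coQ <- generateCohort(tpl, 4, quiet, identityField(fixtureShape), seed = 3)
  for (v in volumes(coQ)) expect_equal(metricData(v), baseMap(tpl))
})

test_that("FA range and multiplicative group-ratio invariants hold", {
  px <- fixturePair(n = 5, magnitude = 0.08, seed = 13,
                    covariates = quietCovariates(betaAge = 0, betaSex = 0))
  for (v in c(volumes(px$site1), volumes(px$site2)))
    expect_true(all(metricData(v) >= 0 & metricData(v) <= 1))

  # with subject/noise randomness off, site1 mean / site2 mean = g(v) exactly
  idx <- wmIdx(px$template)
  m1 <- rowMeans(sapply(volumes(px$site1), function(v) metricData(v)[idx]))
  m2 <- rowMeans(sapply(volumes(px$site2), function(v) metricData(v)[idx]))
  g <- multField(px$field)[idx]
  ok <- m2 > 0.05 & g * m2 < 0.99        # away from the clipping bounds
  expect_equal(m1[ok] / m2[ok], g[ok], tolerance = 1e-10)
})
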