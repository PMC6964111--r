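# Training-loop contracts at toy scale: seeded determinism, loss-history
# bookkeeping, harmonize geometry/covariate preservation, background
# handling. Efficacy at study scale is exercised by the acceptance tests.

tinyRun <- function(seed = 11, updates = 6L) {
  px <- fixturePair(n = 4, magnitude = 0.1, seed = 51)
  gc <- generatorConfig("2D", depth = 2, baseChannels = 4)
  dc <- discriminatorConfig("2D",
                            kernels = rbind(c(4L, 4L), c(4L, 4L), c(3L, 3L)),
                            strides = rbind(c(2L, 2L), c(2L, 2L), c(1L, 1L)),
                            channels = c(4L, 8L, 1L),
                            targetField = c(18L, 18L))
  tc <- trainConfig(epochs = 2L, learningRate = 1e-4, batchSize = 4L,
                    criticSteps = 2L, seed = seed,
                    maxGeneratorUpdates = updates)
  list(model = trainDualGAN(px$site1, px$site2, gc, dc, tc), pair = px)
}

test_that("a fixed seed makes the whole training loop bit-reproducible", {
  r1 <- tinyRun(seed = 11)
  r2 <- tinyRun(seed = 11)
  expect_identical(lossHistory(r1$model), lossHistory(r2$model))
  expect_identical(r1$model@generatorAB$enc[[1]]$w,
                   r2$model@generatorAB$enc[[1]]$w)

  r3 <- tinyRun(seed = 12)
  expect_false(identical(lossHistory(r1$model), lossHistory(r3$model)))
})

test_that("loss history is complete, finite, and labelled per update", {
  r <- tinyRun(updates = 5L)
  h <- lossHistory(r$model)
  expect_equal(nrow(h), 5L)
  expect_identical(h$iter, 1:5)
  expect_true(all(is.finite(as.matrix(h[, -(1:2)]))))
  expect_true(all(c("advA", "advB", "gpA", "gpB", "recon", "genAdv",
                    "genTotal") %in% names(h)))
  expect_equal(h$genTotal, h$genAdv + 20 * h$recon, tolerance = 1e-12)
})

test_that("harmonize preserves geometry and covariates, restores background", {
  r <- tinyRun()
  v <- volumes(r$pair$site1)[[1]]
  out <- harmonize(r$model, v, "AtoB")
  expect_equal(dim(metricData(out)), dim(metricData(v)))
  expect_equal(ageWeeks(out), ageWeeks(v))
  expect_equal(subjectSex(out), subjectSex(v))
  expect_equal(siteLabel(out), "site2")
  # out-of-mask voxels are untouched
  m <- datasetMask(r$pair$site1)
  expect_identical(metricData(out)[m == 0], metricData(v)[m == 0])
  expect_true(all(metricData(out) >= 0 & metricData(out) <= 1))

  out2 <- harmonize(r$model, v, "2to1")
  expect_equal(siteLabel(out2), "site1")
  expect_error(harmonize(r$model, v, "sideways"))

  wrong <- v
  wrong@data <- array(0.3, c(16, 16, 4))
  expect_error(harmonize(r$model, wrong, "AtoB"), "mismatch")
})

test_that("background-dominated slices are excluded from training pools", {
  px <- fixturePair(n = 3, magnitude = 0.05, seed = 61)
  pool <- dtigan:::slicePool(px$site1, "axial", 0.01)
  mStack <- extractSlices(datasetMask(px$site1), "axial")$slices
  keep <- colMeans(matrix(mStack, ncol = dim(mStack)[3])) >= 0.01
  expect_equal(dim(pool$arr)[4], sum(keep) * 3)
  expect_equal(pool$nKept, sum(keep))
})

test_that("a 3D-kernel model trains and harmonizes at toy scale", {
  px <- fixturePair(n = 3, magnitude = 0.1, seed = 71)
  gc <- generatorConfig("3D", depth = 2, baseChannels = 2)
  dc <- discriminatorConfig("3D",
                            kernels = rbind(c(3L, 3L, 3L), c(3L, 3L, 2L)),
                            strides = rbind(c(2L, 2L, 2L), c(1L, 1L, 1L)),
                            channels = c(2L, 1L),
                            targetField = c(7L, 7L, 5L))
  tc <- trainConfig(epochs = 2L, learningRate = 1e-4, batchSize = 2L,
                    criticSteps = 1L, seed = 5, maxGeneratorUpdates = 2)
  m <- trainDualGAN(px$site1, px$site2, gc, dc, tc)
  expect_equal(nrow(lossHistory(m)), 2L)
  v <- volumes(px$site1)[[1]]
  out <- harmonize(m, v, "AtoB")
  expect_equal(dim(metricData(out)), dim(metricData(v)))
})

test_that("dual-GAN models persist and restore losslessly", {
  r <- tinyRun(updates = 3L)
  d <- tempfile()
  saveDualGANModel(r$model, d)
  m2 <- loadDualGANModel(d)
  v <- volumes(r$pair$site1)[[1]]
  expect_identical(metricData(harmonize(m2, v, "AtoB")),
                   metricData(harmonize(r$model, v, "AtoB")))
  expect_identical(lossHistory(m2), lossHistory(r$model))
  expect_true(file.exists(file.path(d, "loss_history.csv")))
  expect_true(file.exists(file.path(d, "model.txt")))
})
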