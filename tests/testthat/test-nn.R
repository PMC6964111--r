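# Network construction contracts: shapes, channel bookkeeping, receptive
# fields (analytic vs empirical probing), and gradient correctness of the
# engine against finite differences.

dt <- asNamespace("dtigan")

test_that("generators preserve shape in 2D and 3D", {
  g <- buildGenerator(generatorConfig("2D", depth = 3, baseChannels = 8),
                      seed = 1)
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  expect_equal(dim(generatorApply(g, x)), dim(x))

  g3 <- buildGenerator(generatorConfig("3D", depth = 2, baseChannels = 4),
                       seed = 1)
  x3 <- array(runif(16 * 16 * 8), c(16, 16, 8, 1, 1))
  expect_equal(dim(generatorApply(g3, x3)), dim(x3))

  expect_error(generatorApply(g, array(0, c(60, 60, 1, 1))), "divisible")
  expect_error(buildGenerator(generatorConfig("2D", depth = 6),
                              inputSize = c(32, 32)), "depth")
})

test_that("zero-initialised residual head makes a fresh generator the identity", {
  g <- buildGenerator(generatorConfig("2D", depth = 2, baseChannels = 4),
                      seed = 2)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  expect_equal(generatorApply(g, x), x, tolerance = 1e-14)
})

test_that("skip connections change decoder input channels by the encoder widths", {
  cfgOn <- generatorConfig("2D", depth = 3, baseChannels = 8)
  cfgOff <- generatorConfig("2D", depth = 3, baseChannels = 8,
                            skipConnections = FALSE)
  pOn <- attr(buildGenerator(cfgOn, seed = 1), "layerPlan")
  pOff <- attr(buildGenerator(cfgOff, seed = 1), "layerPlan")
  enc <- pOn$encoderChannels                      # 8 16 32
  # innermost decoder level sees no concat; the others gain exactly enc[l]
  expect_equal(pOn$decoderInputChannels[3], pOff$decoderInputChannels[3])
  expect_equal(pOn$decoderInputChannels[1:2] - pOff$decoderInputChannels[1:2],
               enc[1:2])
})

test_that("default discriminators hit the 30x30 and 30x30x8 patch sizes", {
  d2 <- buildDiscriminator(discriminatorConfig("2D"), seed = 3)
  expect_identical(receptiveField(d2, "probe"), c(30L, 30L))
  expect_identical(receptiveField(d2, "analytic"), c(30L, 30L))
  expect_false(any(grepl("gamma", rapply(d2$layers, names, how = "unlist"))))

  d3 <- buildDiscriminator(discriminatorConfig("3D"), seed = 3)
  expect_identical(receptiveField(d3, "probe"), c(30L, 30L, 8L))
  expect_identical(receptiveField(d3, "analytic"), c(30L, 30L, 8L))
})

test_that("receptive-field contract is enforced at build time", {
  bad <- discriminatorConfig("2D",
                             kernels = rbind(c(5L, 5L), c(5L, 5L)),
                             strides = rbind(c(2L, 2L), c(1L, 1L)),
                             channels = c(8L, 1L))
  expect_error(buildDiscriminator(bad), "13x13.*30x30")
})

test_that("analytic and probed receptive fields agree over a plan grid", {
  plans <- list(
    list(k = rbind(c(5L, 5L)), s = rbind(c(1L, 1L)), rf = c(5L, 5L)),
    list(k = rbind(c(1L, 1L)), s = rbind(c(1L, 1L)), rf = c(1L, 1L)),
    list(k = rbind(c(3L, 3L), c(3L, 3L)), s = rbind(c(2L, 2L), c(1L, 1L)),
         rf = c(7L, 7L)),
    list(k = rbind(c(4L, 2L), c(3L, 3L), c(2L, 2L)),
         s = rbind(c(2L, 1L), c(2L, 2L), c(1L, 1L)), rf = NULL)
  )
  for (p in plans) {
    rfA <- analyticReceptiveField(p$k, p$s)
    if (!is.null(p$rf)) expect_identical(rfA, p$rf)
    cfg <- discriminatorConfig("2D", kernels = p$k, strides = p$s,
                               channels = c(rep(4L, nrow(p$k) - 1L), 1L),
                               targetField = rfA)
    d <- buildDiscriminator(cfg, seed = 7)
    expect_identical(receptiveField(d, "probe"), rfA)
  }
})

test_that("critic map averaging yields the per-sample score", {
  d2 <- buildDiscriminator(discriminatorConfig("2D"), seed = 5)
  x <- array(runif(64 * 64 * 3), c(64, 64, 1, 3))
  out <- discriminatorApply(d2, x)
  expect_length(out$scores, 3)
  expect_gt(prod(dim(out$map)[1:2]), 1)   # a spatial map, not a scalar
  expect_equal(out$scores[2], mean(out$map[, , 1, 2]))
})

test_that("engine gradients match finite differences", {
  set.seed(4)
  g <- buildGenerator(generatorConfig("2D", depth = 2, baseChannels = 4),
                      seed = 4)
  g$dec[[1]]$w[] <- rnorm(length(g$dec[[1]]$w)) * 0.1   # unblock the head
  xb <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  fw <- dt$unetForward(g, xb, training = TRUE)
  bw <- dt$unetBackward(fw$net, fw$cache, fw$y)   # d/dtheta of sum(y^2)/2
  loss <- function(net) sum(dt$unetForward(net, xb, training = TRUE)$y^2) / 2
  eps <- 1e-6
  for (leaf in list(c("enc", 1, "w"), c("enc", 2, "gamma"), c("dec", 2, "w"),
                    c("dec", 1, "w"), c("enc", 1, "b"))) {
    part <- leaf[1]; l <- as.integer(leaf[2]); nm <- leaf[3]
    num <- vapply(1:3, function(i) {
      n1 <- fw$net; n1[[part]][[l]][[nm]][i] <- n1[[part]][[l]][[nm]][i] + eps
      n2 <- fw$net; n2[[part]][[l]][[nm]][i] <- n2[[part]][[l]][[nm]][i] - eps
      (loss(n1) - loss(n2)) / (2 * eps)
    }, 0)
    expect_equal(bw[[part]][[l]][[nm]][1:3], num, tolerance = 1e-4,
                 label = paste("grad", part, l, nm))
  }
})

test_that("gradient-penalty parameter gradients match finite differences", {
  d <- buildDiscriminator(discriminatorConfig(
    "2D", kernels = rbind(c(3L, 3L), c(3L, 3L)),
    strides = rbind(c(2L, 2L), c(1L, 1L)),
    channels = c(4L, 1L), targetField = c(7L, 7L)), seed = 8)
  xhat <- array(runif(12 * 12 * 2), c(12, 12, 1, 2))
  gp <- dt$discGradPenalty(d, xhat)
  pen <- function(net) dt$discGradPenalty(net, xhat)$penalty
  eps <- 1e-6
  for (l in 1:2) {
    num <- vapply(1:3, function(i) {
      n1 <- d; n1$layers[[l]]$w[i] <- n1$layers[[l]]$w[i] + eps
      n2 <- d; n2$layers[[l]]$w[i] <- n2$layers[[l]]$w[i] - eps
      (pen(n1) - pen(n2)) / (2 * eps)
    }, 0)
    expect_equal(gp$grads[[l]]$w[1:3], num, tolerance = 1e-4,
                 label = paste("GP grad layer", l))
  }
})
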