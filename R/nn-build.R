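# Network construction: U-Net generator and Markovian patch critic builders,
# receptive-field arithmetic and empirical gradient probing.

#' Generator configuration
#'
#' @param kernelStyle "2D" (slice-wise) or "3D" (whole volume).
#' @param orientation slice orientation for 2D kernels.
#' @param depth encoder levels; spatial input dims must be divisible by
#'   2^depth.
#' @param baseChannels channels of the first level (doubling per level).
#'   Defaults (depth 3, base 16) suit 64 x 64 inputs; use depth 4, base 32
#'   for 128 x 128.
#' @param leakySlope LeakyReLU negative slope.
#' @param batchNorm,skipConnections,residualHead architecture switches; see
#'   \linkS4class{GeneratorConfig}.
#' @return a \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(kernelStyle = c("2D", "3D"),
                            orientation = c("axial", "coronal", "sagittal"),
                            depth = 3L, baseChannels = 16L, leakySlope = 0.2,
                            batchNorm = TRUE, skipConnections = TRUE,
                            residualHead = TRUE) {
  kernelStyle <- match.arg(kernelStyle)
  orientation <- match.arg(orientation)
  new("GeneratorConfig", kernelStyle = kernelStyle, orientation = orientation,
      kernelSize = 5L, stride = 2L, depth = as.integer(depth),
      baseChannels = as.integer(baseChannels), leakySlope = leakySlope,
      batchNorm = batchNorm, skipConnections = skipConnections,
      residualHead = residualHead)
}

defaultDiscPlan <- function(kernelStyle) {
  if (kernelStyle == "2D") {
    list(kernels = rbind(c(4L, 4L), c(4L, 4L), c(4L, 4L), c(3L, 3L)),
         strides = rbind(c(2L, 2L), c(2L, 2L), c(1L, 1L), c(1L, 1L)),
         channels = c(16L, 32L, 64L, 1L),
         target = c(30L, 30L))
  } else {
    list(kernels = rbind(c(4L, 4L, 3L), c(4L, 4L, 3L), c(4L, 4L, 3L),
                         c(3L, 3L, 2L)),
         strides = rbind(c(2L, 2L, 1L), c(2L, 2L, 1L), c(1L, 1L, 1L),
                         c(1L, 1L, 1L)),
         channels = c(16L, 32L, 64L, 1L),
         target = c(30L, 30L, 8L))
  }
}

#' Discriminator configuration
#'
#' The default layer plans realise the required patch sizes exactly:
#' 2D, kernels 4/4/4/3 with strides 2/2/1/1, receptive field 30 x 30;
#' 3D, in-plane the same with through-plane kernels 3/3/3/2 at stride 1,
#' receptive field 30 x 30 x 8. Custom plans are accepted but must satisfy
#' the receptive-field contract at build time.
#'
#' @param kernelStyle "2D" or "3D".
#' @param kernels integer matrix (layers x spatial dims) of kernel sizes.
#' @param strides matching stride matrix.
#' @param channels output channels per layer; the last must be 1 (score map).
#' @param targetField target receptive field per spatial dimension.
#' @param leakySlope LeakyReLU negative slope.
#' @return a \linkS4class{DiscriminatorConfig}.
#' @export
discriminatorConfig <- function(kernelStyle = c("2D", "3D"), kernels = NULL,
                                strides = NULL, channels = NULL,
                                targetField = NULL, leakySlope = 0.2) {
  kernelStyle <- match.arg(kernelStyle)
  plan <- defaultDiscPlan(kernelStyle)
  if (is.null(kernels)) kernels <- plan$kernels
  if (is.null(strides)) strides <- plan$strides
  if (is.null(channels)) channels <- plan$channels
  if (is.null(targetField)) targetField <- plan$target
  kernels <- matrix(as.integer(kernels), nrow = nrow(kernels))
  strides <- matrix(as.integer(strides), nrow = nrow(strides))
  if (tail(channels, 1) != 1L) stop("last layer must emit a single score channel")
  new("DiscriminatorConfig", kernelStyle = kernelStyle, kernels = kernels,
      strides = strides, channels = as.integer(channels),
      targetField = as.integer(targetField), leakySlope = leakySlope)
}

#' Training configuration
#'
#' @param lambdaRecon cycle-reconstruction weight (default 20).
#' @param lambdaGp gradient-penalty weight (default 10).
#' @param epochs training epochs (default 300).
#' @param learningRate RMSProp learning rate for the generators (default
#'   5e-5).
#' @param criticLrMult learning-rate multiplier for the critics (default 4;
#'   two-time-scale updates keep the critics ahead of the generators).
#' @param batchSize mini-batch size (default 16).
#' @param criticSteps discriminator updates per generator update (default 5).
#' @param seed RNG seed for the whole training run.
#' @param backgroundSlicePolicy minimum mask-coverage fraction for a slice to
#'   enter 2D training batches (default 0.01).
#' @param maxGeneratorUpdates optional hard cap on generator updates.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(lambdaRecon = 20, lambdaGp = 10, epochs = 300L,
                        learningRate = 5e-5, criticLrMult = 4,
                        batchSize = 16L, criticSteps = 5L, seed = 1L,
                        backgroundSlicePolicy = 0.01,
                        maxGeneratorUpdates = Inf) {
  new("TrainConfig", lambdaRecon = lambdaRecon, lambdaGp = lambdaGp,
      epochs = as.integer(epochs), learningRate = learningRate,
      criticLrMult = criticLrMult, batchSize = as.integer(batchSize),
      criticSteps = as.integer(criticSteps), seed = as.integer(seed),
      backgroundSlicePolicy = backgroundSlicePolicy,
      maxGeneratorUpdates = maxGeneratorUpdates)
}

#' Build a U-Net generator
#'
#' Returns a generator network object; apply it to a batch with
#' \code{\link{generatorApply}}. The network maps batches to identically
#' shaped outputs (encoder features are concatenated into the matching
#' decoder levels when skip connections are on). Layer channel counts are
#' inspectable via \code{attr(net, "layerPlan")}.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param inputSize optional spatial input size to validate against depth.
#' @param seed seed for weight initialisation.
#' @return a generator network (list, class "dtiganGenerator").
#' @export
buildGenerator <- function(config, inputSize = NULL, seed = 1L) {
  nd <- if (config@kernelStyle == "2D") 2L else 3L
  if (!is.null(inputSize)) {
    if (any(inputSize %% 2^config@depth != 0) ||
        any(inputSize / 2^config@depth < 1))
      stop("depth ", config@depth, " requires spatial dims divisible by ",
           2^config@depth, " (and at least ", 2^config@depth,
           "); got ", paste(inputSize, collapse = "x"))
  }
  net <- withSeed(seed, unetInit(
    nd = nd, depth = config@depth, base = config@baseChannels,
    k = config@kernelSize, bn = config@batchNorm,
    skips = config@skipConnections, residual = config@residualHead,
    slope = config@leakySlope))
  ch <- net$channels
  decIn <- vapply(seq_along(net$dec), function(l)
    dim(net$dec[[l]]$w)[nd + 2L], 0)
  attr(net, "layerPlan") <- list(
    encoderChannels = ch,
    decoderInputChannels = decIn,
    skipConnections = config@skipConnections)
  class(net) <- c("dtiganGenerator", "list")
  net
}

#' Analytic receptive field of a convolution stack
#'
#' r = 1 + sum over layers of (k_l - 1) * prod of previous strides, per
#' spatial dimension.
#'
#' @param kernels integer matrix (layers x dims).
#' @param strides integer matrix (layers x dims).
#' @return integer vector of per-dimension receptive-field extents.
#' @export
analyticReceptiveField <- function(kernels, strides) {
  nd <- ncol(kernels)
  r <- rep(1L, nd); j <- rep(1L, nd)
  for (l in seq_len(nrow(kernels))) {
    r <- r + (kernels[l, ] - 1L) * j
    j <- j * strides[l, ]
  }
  as.integer(r)
}

#' Build a Markovian patch discriminator
#'
#' Fully convolutional critic emitting a spatial map of local scores (no
#' batch normalization anywhere); the image-level score is the mean of the
#' map. The layer plan's analytic receptive field is verified against the
#' configured target at build time and the build fails if they differ.
#'
#' @param config a \linkS4class{DiscriminatorConfig}.
#' @param seed seed for weight initialisation.
#' @return a critic network (list, class "dtiganDiscriminator").
#' @export
buildDiscriminator <- function(config, seed = 1L) {
  rf <- analyticReceptiveField(config@kernels, config@strides)
  if (!identical(rf, config@targetField))
    stop("layer plan receptive field (", paste(rf, collapse = "x"),
         ") does not equal the target (",
         paste(config@targetField, collapse = "x"), ")")
  nd <- if (config@kernelStyle == "2D") 2L else 3L
  net <- withSeed(seed, discInit(nd, config@kernels, config@strides,
                                 config@channels, slope = config@leakySlope))
  net$targetField <- config@targetField
  class(net) <- c("dtiganDiscriminator", "list")
  net
}

#' Apply a generator to a batch
#'
#' @param net a generator from \code{\link{buildGenerator}}.
#' @param x batch array: (H, W, C, N) for 2D, (H, W, D, C, N) for 3D.
#' @param training logical; use batch statistics (TRUE) or running
#'   statistics (FALSE) in batch normalization.
#' @return output batch of identical shape.
#' @export
generatorApply <- function(net, x, training = FALSE) {
  unetForward(net, x, training = training)$y
}

#' Apply a discriminator to a batch
#'
#' @param net a critic from \code{\link{buildDiscriminator}}.
#' @param x batch array.
#' @return list with \code{map} (spatial score map per sample) and
#'   \code{scores} (per-sample mean of the map).
#' @export
discriminatorApply <- function(net, x) {
  fw <- discForward(net, x)
  list(map = fw$map, scores = discScores(fw$map))
}

#' Measure a discriminator's receptive field
#'
#' Empirically: the gradient of one interior output unit is set to 1,
#' backpropagated to the input, and the per-dimension extent of the bounding
#' box of nonzero input sensitivity is returned. \code{method = "analytic"}
#' returns the stride/kernel arithmetic instead.
#'
#' @param net a critic from \code{\link{buildDiscriminator}}.
#' @param method "probe" (gradient support) or "analytic".
#' @param inputSize spatial probe-input size (default: generous multiple of
#'   the analytic field so the probed unit is interior).
#' @return integer vector of per-dimension extents.
#' @export
receptiveField <- function(net, method = c("probe", "analytic"),
                           inputSize = NULL) {
  method <- match.arg(method)
  rfA <- analyticReceptiveField(net$kernels, net$strides)
  if (method == "analytic") return(rfA)
  nd <- net$nd
  if (is.null(inputSize)) inputSize <- 2L * rfA + 8L
  x <- array(0, c(inputSize, 1L, 1L))
  fw <- discForward(net, x)
  md <- dim(fw$map)
  centre <- pmax(1L, md[seq_len(nd)] %/% 2L)
  gmap <- array(0, md)
  gmap[matrix(c(centre, 1L, 1L), 1L)] <- 1
  gx <- discBackward(net, fw$cache, gmap)$gx
  support <- abs(gx) > 0
  ext <- integer(nd)
  for (ax in seq_len(nd)) {
    hit <- which(apply(support, ax, any))
    ext[ax] <- if (length(hit)) max(hit) - min(hit) + 1L else 0L
  }
  ext
}
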