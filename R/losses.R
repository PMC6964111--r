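# Public loss operations of the Wasserstein dual-GAN objective. A critic D
# may be a discriminator network (see buildDiscriminator) or, for analytic
# checks, a list(value = function(batch) scores, grad = function(batch)
# per-sample input gradients).

criticScores <- function(D, batch) {
  if (inherits(D, "dtiganDiscriminator")) return(discScores(discForward(D, batch)$map))
  if (is.list(D) && is.function(D$value)) return(D$value(batch))
  if (is.function(D)) return(D(batch))
  stop("D must be a discriminator network, a function, or list(value, grad)")
}

#' Wasserstein adversarial loss
#'
#' E[D(real)] - E[D(fake)], expectations over the batch (and, for a patch
#' critic, over the spatial score map). The critic ascends this quantity; the
#' generator descends its negation.
#'
#' @param D critic: a discriminator network, a function mapping a batch to
#'   per-sample scores, or list(value, grad).
#' @param realBatch,fakeBatch batches of identical shape; the batch dimension
#'   is last.
#' @return list with \code{loss}, \code{meanReal}, \code{meanFake}.
#' @export
adversarialLoss <- function(D, realBatch, fakeBatch) {
  if (!length(realBatch) || !length(fakeBatch)) stop("empty batch")
  mr <- mean(criticScores(D, realBatch))
  mf <- mean(criticScores(D, fakeBatch))
  list(loss = mr - mf, meanReal = mr, meanFake = mf)
}

#' WGAN gradient penalty
#'
#' Interpolates each real/fake pair as x-hat = alpha x + (1 - alpha) y with
#' alpha ~ Uniform(0, 1) per pair, and returns
#' E[(||grad_xhat D(x-hat)||_2 - 1)^2]. The full critic objective subtracts
#' lambda_gp times this penalty (lambda_gp = 10 by default in training).
#'
#' @inheritParams adversarialLoss
#' @param seed seed for the interpolation draw.
#' @param alpha optional fixed interpolation weight(s) overriding the
#'   uniform draw (alpha = 1 reproduces the real sample exactly).
#' @return list with \code{penalty}, \code{gradNorms} and the interpolated
#'   batch \code{interp}.
#' @export
gradientPenalty <- function(D, realBatch, fakeBatch, seed = 1L, alpha = NULL) {
  d <- dim(realBatch)
  stopifnot(identical(d, dim(fakeBatch)))
  N <- d[length(d)]
  if (is.null(alpha)) alpha <- withSeed(seed, runif(N))
  alpha <- rep_len(alpha, N)
  per <- prod(d) / N
  aFull <- array(rep(alpha, each = per), d)
  xhat <- aFull * realBatch + (1 - aFull) * fakeBatch

  if (inherits(D, "dtiganDiscriminator")) {
    gp <- discGradPenalty(D, xhat)
    return(list(penalty = gp$penalty, gradNorms = gp$norms, interp = xhat))
  }
  if (is.list(D) && is.function(D$grad)) {
    g <- D$grad(xhat)
    gm <- matrix(g, ncol = N)
    norms <- sqrt(colSums(gm^2))
    return(list(penalty = mean((norms - 1)^2), gradNorms = norms,
                interp = xhat))
  }
  stop("gradient penalty needs a discriminator network or list(value, grad)")
}

#' L1 cycle-reconstruction loss
#'
#' Mean absolute deviation of both cycle reconstructions,
#' mean|x - G_B(G_A(x))| + mean|y - G_A(G_B(y))|, each term averaged per
#' element so the weight lambda is resolution-independent.
#'
#' @param x,xRecon site-A batch and its cycle reconstruction.
#' @param y,yRecon site-B batch and its cycle reconstruction.
#' @return scalar loss.
#' @export
reconstructionLoss <- function(x, xRecon, y, yRecon) {
  if (!identical(dim(x), dim(xRecon)) || !identical(dim(y), dim(yRecon)))
    stop("shape mismatch between originals and reconstructions")
  mean(abs(x - xRecon)) + mean(abs(y - yRecon))
}

#' Total generator objective
#'
#' adv + lambda * recon (lambda = 20 by default in training).
#'
#' @param adv adversarial term.
#' @param recon reconstruction term.
#' @param lambda nonnegative weight.
#' @return scalar.
#' @export
totalLoss <- function(adv, recon, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  adv + lambda * recon
}
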