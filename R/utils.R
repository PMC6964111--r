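# Shared array helpers: metric ranges, clipping, seeded evaluation, and
# separable Gaussian smoothing used to build spatially smooth random fields.

metricRange <- function(metricName) {
  switch(metricName,
    FA = c(0, 1),
    MD = c(0, 4e-3),
    stop("unknown metric '", metricName, "' (expected FA or MD)")
  )
}

clipToMetric <- function(x, metricName) {
  r <- metricRange(metricName)
  pmin(pmax(x, r[1]), r[2])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

gaussianKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

smoothAxis <- function(a, axis, kernel) {
  if (length(kernel) == 1L) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(seq_along(d), axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  r <- (length(kernel) - 1L) / 2L
  padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  f <- stats::filter(padded, kernel, sides = 2)
  out <- matrix(as.numeric(f[(r + 1L):(r + dp[1]), , drop = FALSE]), nrow = dp[1])
  dim(out) <- dp
  aperm(out, order(perm))
}

# Separable Gaussian smoothing with zero padding; `normalize = TRUE` divides
# by the smoothed indicator so edges are not darkened (normalized convolution).
gaussianSmooth3d <- function(a, sigmaVox, normalize = TRUE) {
  sigmaVox <- rep(sigmaVox, length.out = 3)
  out <- a
  for (ax in 1:3) out <- smoothAxis(out, ax, gaussianKernel1d(sigmaVox[ax]))
  if (normalize) {
    w <- array(1, dim(a))
    for (ax in 1:3) w <- smoothAxis(w, ax, gaussianKernel1d(sigmaVox[ax]))
    out <- out / pmax(w, .Machine$double.eps)
  }
  out
}

# Smooth standardized random field (volume mean 0, sd 1), reproducible by seed.
smoothRandomField <- function(shape, sigmaVox, seed) {
  withSeed(seed, {
    noise <- array(rnorm(prod(shape)), shape)
    f <- gaussianSmooth3d(noise, sigmaVox)
    s <- sd(f)
    if (s < .Machine$double.eps) array(0, shape) else (f - mean(f)) / s
  })
}

stopIfNot3d <- function(x, what = "array") {
  if (length(dim(x)) != 3L)
    stop(what, " must be a 3D array, got ", length(dim(x)), " dimensions")
  invisible(x)
}

sameShape <- function(a, b) identical(dim(a), dim(b))
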