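# Conv-net engine for the dual-GAN: strided convolution / transposed
# convolution (2D and 3D), LeakyReLU, batch normalization, a U-Net
# generator, a fully convolutional patch critic, WGAN gradient-penalty
# double backpropagation, and RMSProp. Activation batches are stored as
# (H, W, C, N) in 2D and (H, W, D, C, N) in 3D; weights as
# (k..., Cin, Cout). All heavy kernels live in src/conv.cpp.

spatialDims <- function(x) {
  d <- dim(x)
  d[seq_len(length(d) - 2L)]
}

channelCount <- function(x) {
  d <- dim(x)
  d[length(d) - 1L]
}

batchCount <- function(x) {
  d <- dim(x)
  d[length(d)]
}

channelSums <- function(x) {
  d <- dim(x)
  S <- prod(d[seq_len(length(d) - 2L)])
  C <- d[length(d) - 1L]
  rowSums(matrix(colSums(matrix(x, nrow = S)), C))
}

expandChannel <- function(v, d) {
  S <- prod(d[seq_len(length(d) - 2L)])
  N <- d[length(d)]
  rep(rep(v, each = S), times = N)
}

lreluMask <- function(z, slope) {
  m <- array(1, dim(z))
  m[z <= 0] <- slope
  m
}
lrelu <- function(z, slope) z * lreluMask(z, slope)

convForward <- function(x, w, b, stride, pad) {
  if (is.null(b)) b <- numeric(0)
  if (length(dim(x)) == 4L)
    cpp_conv2d_fwd(x, w, b, stride[1], stride[2], pad[1], pad[2])
  else
    cpp_conv3d_fwd(x, w, b, as.integer(stride), as.integer(pad))
}

convGradIn <- function(gy, w, stride, pad, inSpatial) {
  if (length(dim(gy)) == 4L)
    cpp_conv2d_gradin(gy, w, stride[1], stride[2], pad[1], pad[2],
                      inSpatial[1], inSpatial[2])
  else
    cpp_conv3d_gradin(gy, w, as.integer(stride), as.integer(pad),
                      as.integer(inSpatial))
}

convGradW <- function(x, gy, stride, pad, ksize) {
  if (length(dim(x)) == 4L)
    cpp_conv2d_gradw(x, gy, stride[1], stride[2], pad[1], pad[2],
                     ksize[1], ksize[2])
  else
    cpp_conv3d_gradw(x, gy, as.integer(stride), as.integer(pad),
                     as.integer(ksize))
}

# transposed convolution: weight dims (k..., Cbig, Csmall); maps a small map
# with Csmall channels to a big one with Cbig channels (adjoint of the
# corresponding strided convolution)
convTForward <- function(x, w, b, stride, pad, outSpatial) {
  y <- convGradIn(x, w, stride, pad, outSpatial)
  if (!is.null(b) && length(b)) y <- y + expandChannel(b, dim(y))
  y
}

# ----------------------------------------------------------- batch norm ----

bnForward <- function(h, p, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(h)
  S <- prod(d[seq_len(length(d) - 2L)])
  C <- d[length(d) - 1L]
  N <- d[length(d)]
  if (training) {
    m <- matrix(h, nrow = S)
    cs <- matrix(colSums(m), C)
    mu <- rowSums(cs) / (S * N)
    cs2 <- matrix(colSums(m^2), C)
    v <- rowSums(cs2) / (S * N) - mu^2
    v <- pmax(v, 0)
    rm <- (1 - momentum) * p$rm + momentum * mu
    rv <- (1 - momentum) * p$rv + momentum * v
  } else {
    mu <- p$rm; v <- p$rv; rm <- p$rm; rv <- p$rv
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (h - expandChannel(mu, d)) * expandChannel(invstd, d)
  dim(xhat) <- d
  y <- xhat * expandChannel(p$gamma, d) + expandChannel(p$beta, d)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d),
       rm = rm, rv = rv)
}

bnBackward <- function(p, cache, gy) {
  d <- cache$d
  S <- prod(d[seq_len(length(d) - 2L)])
  C <- d[length(d) - 1L]
  N <- d[length(d)]
  n <- S * N
  sum1 <- rowSums(matrix(colSums(matrix(gy, nrow = S)), C))
  sum2 <- rowSums(matrix(colSums(matrix(gy * cache$xhat, nrow = S)), C))
  gGamma <- sum2
  gBeta <- sum1
  gx <- expandChannel(p$gamma * cache$invstd, d) *
    (gy - expandChannel(sum1 / n, d) - cache$xhat * expandChannel(sum2 / n, d))
  dim(gx) <- d
  list(gx = gx, gGamma = gGamma, gBeta = gBeta)
}

# -------------------------------------------------------------- weights ----

heInit <- function(dims, fanIn) {
  array(rnorm(prod(dims), 0, sqrt(2 / fanIn)), dims)
}

# ----------------------------------------------------------------- unet ----

# Builds the parameter tree for a U-Net generator. `nd` is the number of
# spatial dimensions (2 or 3); channels double per level from `base`.
unetInit <- function(nd, depth, base, k = 5L, inChannels = 1L,
                     bn = TRUE, skips = TRUE, residual = TRUE, slope = 0.2) {
  ch <- base * 2^(seq_len(depth) - 1L)
  kd <- rep(k, nd)
  enc <- vector("list", depth)
  for (l in seq_len(depth)) {
    cin <- if (l == 1L) inChannels else ch[l - 1L]
    w <- heInit(c(kd, cin, ch[l]), prod(kd) * cin)
    enc[[l]] <- list(w = w, b = numeric(ch[l]),
                     gamma = rep(1, ch[l]), beta = numeric(ch[l]),
                     rm = numeric(ch[l]), rv = rep(1, ch[l]))
  }
  dec <- vector("list", depth)
  for (l in seq(depth, 1L)) {
    din <- if (l == depth) ch[depth]
           else if (skips) 2L * ch[l] else ch[l]
    cout <- if (l == 1L) inChannels else ch[l - 1L]
    # convT weight dims (k..., Cbig=cout, Csmall=din)
    w <- heInit(c(kd, cout, din), prod(kd) * din)
    if (l == 1L) w[] <- 0            # zero-init residual head: identity start
    dec[[l]] <- list(w = w, b = numeric(cout),
                     gamma = if (l > 1L) rep(1, cout) else NULL,
                     beta = if (l > 1L) numeric(cout) else NULL,
                     rm = if (l > 1L) numeric(cout) else NULL,
                     rv = if (l > 1L) rep(1, cout) else NULL)
  }
  list(kind = "unet", nd = nd, depth = depth, base = base, k = kd,
       channels = ch, inChannels = inChannels, bn = bn, skips = skips,
       residual = residual, slope = slope, enc = enc, dec = dec)
}

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  nd <- length(da)
  out <- array(0, c(da[seq_len(nd - 2L)], da[nd - 1L] + db[nd - 1L], da[nd]))
  idx <- as.list(rep(TRUE, nd))
  ia <- idx; ia[[nd - 1L]] <- seq_len(da[nd - 1L])
  ib <- idx; ib[[nd - 1L]] <- da[nd - 1L] + seq_len(db[nd - 1L])
  out <- do.call(`[<-`, c(list(out), ia, list(a)))
  out <- do.call(`[<-`, c(list(out), ib, list(b)))
  out
}

splitChannels <- function(g, c1) {
  nd <- length(dim(g))
  idx <- as.list(rep(TRUE, nd))
  i1 <- idx; i1[[nd - 1L]] <- seq_len(c1)
  i2 <- idx; i2[[nd - 1L]] <- (c1 + 1L):dim(g)[nd - 1L]
  a <- do.call(`[`, c(list(g), i1, list(drop = FALSE)))
  b <- do.call(`[`, c(list(g), i2, list(drop = FALSE)))
  list(a, b)
}

unetForward <- function(net, x, training = FALSE) {
  nd <- net$nd
  sp <- spatialDims(x)
  if (any(sp %% 2^net$depth != 0))
    stop("generator depth ", net$depth, " requires spatial dims divisible by ",
         2^net$depth, "; got ", paste(sp, collapse = "x"))
  stride <- rep(2L, nd); pad <- rep(2L, nd)
  encA <- vector("list", net$depth)
  encCache <- vector("list", net$depth)
  a <- x
  for (l in seq_len(net$depth)) {
    z <- convForward(a, net$enc[[l]]$w, net$enc[[l]]$b, stride, pad)
    mask <- lreluMask(z, net$slope)
    h <- z * mask
    if (net$bn) {
      bo <- bnForward(h, net$enc[[l]], training)
      if (training) { net$enc[[l]]$rm <- bo$rm; net$enc[[l]]$rv <- bo$rv }
      encCache[[l]] <- list(aIn = a, mask = mask, bn = bo$cache)
      a <- bo$y
    } else {
      encCache[[l]] <- list(aIn = a, mask = mask, bn = NULL)
      a <- h
    }
    encA[[l]] <- a
  }
  decCache <- vector("list", net$depth)
  d <- encA[[net$depth]]
  if (net$depth > 1L) for (l in seq(net$depth, 2L)) {
    outSp <- spatialDims(d) * 2L
    u <- convTForward(d, net$dec[[l]]$w, net$dec[[l]]$b, stride, pad, outSp)
    mask <- lreluMask(u, net$slope)
    h <- u * mask
    if (net$bn) {
      bo <- bnForward(h, net$dec[[l]], training)
      if (training) { net$dec[[l]]$rm <- bo$rm; net$dec[[l]]$rv <- bo$rv }
      aDec <- bo$y
      decCache[[l]] <- list(dIn = d, mask = mask, bn = bo$cache)
    } else {
      aDec <- h
      decCache[[l]] <- list(dIn = d, mask = mask, bn = NULL)
    }
    d <- if (net$skips) catChannels(aDec, encA[[l - 1L]]) else aDec
  }
  outSp <- spatialDims(d) * 2L
  out <- convTForward(d, net$dec[[1L]]$w, net$dec[[1L]]$b, stride, pad, outSp)
  decCache[[1L]] <- list(dIn = d)
  y <- if (net$residual) x + out else out
  dim(y) <- dim(x)
  list(y = y, net = net,
       cache = list(x = x, encCache = encCache, decCache = decCache))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unetBackward <- function(net, cache, gy) {
  nd <- net$nd
  stride <- rep(2L, nd); pad <- rep(2L, nd)
  depth <- net$depth
  gEnc <- vector("list", depth)   # grads for enc params
  gDec <- vector("list", depth)
  skipG <- vector("list", depth)  # gradient wrt enc activation from skips

  gx <- if (net$residual) gy else array(0, dim(gy))
  gOut <- gy

  # final (linear) transposed convolution, level 1
  d1 <- cache$decCache[[1L]]$dIn
  gW <- convGradW(gOut, d1, stride, pad, net$k)
  gDec[[1L]] <- list(w = gW$gw, b = channelSums(gOut))
  gd <- convForward(gOut, net$dec[[1L]]$w, NULL, stride, pad)

  if (depth > 1L) for (l in seq(2L, depth)) {
    cD <- cache$decCache[[l]]
    cOut <- if (l == 1L) net$inChannels else net$channels[l - 1L]
    if (net$skips) {
      sp <- splitChannels(gd, cOut)
      gA <- sp[[1L]]
      skipG[[l - 1L]] <- sp[[2L]]
    } else gA <- gd
    if (net$bn) {
      bb <- bnBackward(net$dec[[l]], cD$bn, gA)
      gH <- bb$gx
      gGamma <- bb$gGamma; gBeta <- bb$gBeta
    } else {
      gH <- gA; gGamma <- NULL; gBeta <- NULL
    }
    gU <- gH * cD$mask
    dim(gU) <- dim(cD$mask)
    gW <- convGradW(gU, cD$dIn, stride, pad, net$k)
    gDec[[l]] <- list(w = gW$gw, b = channelSums(gU),
                      gamma = gGamma, beta = gBeta)
    gd <- convForward(gU, net$dec[[l]]$w, NULL, stride, pad)
  }

  # gd is now the gradient wrt encA[[depth]]
  gATop <- gd
  for (l in seq(depth, 1L)) {
    cE <- cache$encCache[[l]]
    gA <- gATop
    if (!is.null(skipG[[l]])) gA <- gA + skipG[[l]]
    if (net$bn) {
      bb <- bnBackward(net$enc[[l]], cE$bn, gA)
      gH <- bb$gx; gGamma <- bb$gGamma; gBeta <- bb$gBeta
    } else {
      gH <- gA; gGamma <- NULL; gBeta <- NULL
    }
    gZ <- gH * cE$mask
    dim(gZ) <- dim(cE$mask)
    gW <- convGradW(cE$aIn, gZ, stride, pad, net$k)
    gEnc[[l]] <- list(w = gW$gw, b = gW$gb, gamma = gGamma, beta = gBeta)
    gPrev <- convGradIn(gZ, net$enc[[l]]$w, stride, pad, spatialDims(cE$aIn))
    if (l > 1L) gATop <- gPrev else gx <- gx + gPrev
  }
  dim(gx) <- dim(gy)
  list(enc = gEnc, dec = gDec, gx = gx)
}

# ----------------------------------------------------------- patch critic ----

# layers: list of list(w, b, stride, pad, k); LeakyReLU between layers, the
# last layer linear with a single output channel (the local score map).
discInit <- function(nd, kernels, strides, channels, inChannels = 1L,
                     slope = 0.2) {
  L <- nrow(kernels)
  layers <- vector("list", L)
  cin <- inChannels
  for (l in seq_len(L)) {
    kd <- kernels[l, ]
    w <- heInit(c(kd, cin, channels[l]), prod(kd) * cin)
    layers[[l]] <- list(w = w, b = numeric(channels[l]),
                        stride = as.integer(strides[l, ]),
                        pad = as.integer(pmax(floor((kd - 1) / 2), 0L)),
                        k = as.integer(kd))
    cin <- channels[l]
  }
  list(kind = "patchCritic", nd = nd, slope = slope, layers = layers,
       kernels = kernels, strides = strides, channels = channels)
}

discForward <- function(net, x) {
  L <- length(net$layers)
  aIn <- vector("list", L)
  masks <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    aIn[[l]] <- a
    z <- convForward(a, ly$w, ly$b, ly$stride, ly$pad)
    if (l < L) {
      masks[[l]] <- lreluMask(z, net$slope)
      a <- z * masks[[l]]
    } else a <- z
  }
  list(map = a, cache = list(aIn = aIn, masks = masks))
}

# Per-sample critic scores: mean of the local score map.
discScores <- function(map) {
  d <- dim(map)
  S <- prod(d[seq_len(length(d) - 1L)])   # spatial x 1 channel
  colMeans(matrix(map, nrow = S))
}

discBackward <- function(net, cache, gmap) {
  L <- length(net$layers)
  grads <- vector("list", L)
  g <- gmap
  for (l in seq(L, 1L)) {
    ly <- net$layers[[l]]
    if (l < L) {
      g <- g * cache$masks[[l]]
      dim(g) <- dim(cache$masks[[l]])
    }
    gW <- convGradW(cache$aIn[[l]], g, ly$stride, ly$pad, ly$k)
    grads[[l]] <- list(w = gW$gw, b = gW$gb)
    g <- convGradIn(g, ly$w, ly$stride, ly$pad, spatialDims(cache$aIn[[l]]))
  }
  list(layers = grads, gx = g)
}

# Gradient of the per-sample critic score wrt the input (seed 1/S per map
# unit), reusing a forward cache. Returns the input-shaped gradient.
discInputGrad <- function(net, cache, map) {
  d <- dim(map)
  S <- prod(d[seq_len(length(d) - 1L)])
  discBackward(net, cache, array(1 / S, d))$gx
}

# WGAN gradient penalty and its parameter gradients by double
# backpropagation. For piecewise-linear critics (conv + LeakyReLU) the
# activation pattern is locally constant, so the input-gradient chain is a
# linear map in the weights; differentiating through that chain is exact
# almost everywhere. Biases receive zero gradient from this term.
discGradPenalty <- function(net, xhat) {
  L <- length(net$layers)
  fw <- discForward(net, xhat)
  map <- fw$map
  d <- dim(map)
  nd <- length(d)
  S <- prod(d[seq_len(nd - 1L)])
  N <- d[nd]

  # backward chain: g = grad_x D(x) per sample, keeping per-layer t_l
  tl <- vector("list", L)
  s <- array(1 / S, d)
  for (l in seq(L, 1L)) {
    ly <- net$layers[[l]]
    tcur <- if (l < L) {
      m <- s * fw$cache$masks[[l]]
      dim(m) <- dim(fw$cache$masks[[l]])
      m
    } else s
    tl[[l]] <- tcur
    s <- convGradIn(tcur, ly$w, ly$stride, ly$pad,
                    spatialDims(fw$cache$aIn[[l]]))
  }
  g <- s
  gm <- matrix(g, ncol = N)
  norms <- sqrt(colSums(gm^2))
  penalty <- mean((norms - 1)^2)

  # dP/dg, then push forward through the (reversed) chain collecting dP/dW
  coefs <- ifelse(norms > 0, 2 * (norms - 1) / (norms * N), 0)
  r <- array(t(t(gm) * coefs), dim(g))
  grads <- vector("list", L)
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    gW <- convGradW(r, tl[[l]], ly$stride, ly$pad, ly$k)
    grads[[l]] <- list(w = gW$gw, b = numeric(length(ly$b)))
    if (l < L) {
      r <- convForward(r, ly$w, NULL, ly$stride, ly$pad)
      r <- r * fw$cache$masks[[l]]
      dim(r) <- dim(fw$cache$masks[[l]])
    }
  }
  list(penalty = penalty, grads = grads, norms = norms)
}

# --------------------------------------------------------------- RMSProp ----

rmspropInit <- function() new.env(parent = emptyenv())

rmspropStep <- function(p, g, state, key, lr, rho = 0.9, eps = 1e-8) {
  v <- if (!is.null(state[[key]])) state[[key]] else 0
  v <- rho * v + (1 - rho) * g^2
  state[[key]] <- v
  p - lr * g / (sqrt(v) + eps)
}

# Applies gradient lists to a unet / critic parameter tree in place.
applyGradsUnet <- function(net, grads, state, prefix, lr) {
  for (part in c("enc", "dec")) {
    for (l in seq_along(net[[part]])) {
      for (nm in c("w", "b", "gamma", "beta")) {
        g <- grads[[part]][[l]][[nm]]
        if (is.null(g) || is.null(net[[part]][[l]][[nm]])) next
        key <- paste(prefix, part, l, nm, sep = ".")
        net[[part]][[l]][[nm]] <- rmspropStep(net[[part]][[l]][[nm]], g,
                                              state, key, lr)
      }
    }
  }
  net
}

applyGradsCritic <- function(net, grads, state, prefix, lr) {
  for (l in seq_along(net$layers)) {
    for (nm in c("w", "b")) {
      g <- grads[[l]][[nm]]
      if (is.null(g)) next
      key <- paste(prefix, l, nm, sep = ".")
      net$layers[[l]][[nm]] <- rmspropStep(net$layers[[l]][[nm]], g,
                                           state, key, lr)
    }
  }
  net
}

addGradTrees <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- addGradTrees(a[[i]], b[[i]])
    return(out)
  }
  a + b
}
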