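# Minimal neural-network engine: 1-D convolution, max-pooling, batch
# normalization, leaky ReLU, dropout, GRU, dense layers, sigmoid/binary
# cross-entropy, and Adam. Written against base R matrix algebra with
# explicit backward passes; gradients are verified against finite
# differences in the test suite.
#
# Tensor convention: sequence tensors are arrays (N, L, C) — batch, length,
# channels. A conv weight is a matrix (k*C_in, F) whose row index is
# (c-1)*k + ki (channel-major blocks of kernel taps); conversions between
# array and matrix views rely on R's column-major order with the batch
# index fastest.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout, dims = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

add_bias <- function(Y, b) Y + matrix(b, nrow(Y), length(b), byrow = TRUE)

# ---- conv1d ---------------------------------------------------------------

conv_forward <- function(X, W, b, k, s) {
  d <- dim(X); N <- d[1L]; C <- d[3L]
  Lout <- (d[2L] - k) %/% s + 1L
  P <- matrix(0, N * Lout, k * C)
  for (t in seq_len(Lout)) {
    sl <- X[, ((t - 1L) * s + 1L):((t - 1L) * s + k), , drop = FALSE]
    P[((t - 1L) * N + 1L):(t * N), ] <- matrix(sl, N, k * C)
  }
  Y <- add_bias(P %*% W, b)
  list(Y = array(Y, c(N, Lout, ncol(W))), P = P, dimX = d)
}

conv_backward <- function(dY, cache, W, k, s) {
  d <- cache$dimX; N <- d[1L]; C <- d[3L]
  Lout <- dim(dY)[2L]; nf <- dim(dY)[3L]
  dYm <- matrix(dY, N * Lout, nf)
  dW <- crossprod(cache$P, dYm)
  db <- colSums(dYm)
  dP <- tcrossprod(dYm, W)
  dX <- array(0, d)
  for (t in seq_len(Lout)) {
    blk <- array(dP[((t - 1L) * N + 1L):(t * N), ], c(N, k, C))
    idx <- ((t - 1L) * s + 1L):((t - 1L) * s + k)
    dX[, idx, ] <- dX[, idx, , drop = FALSE] + blk
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- max pooling (width 2, stride 2; trailing odd position dropped) -------

pool_forward <- function(X) {
  d <- dim(X); Lp <- d[2L] %/% 2L
  i1 <- seq.int(1L, 2L * Lp, by = 2L)
  X1 <- X[, i1, , drop = FALSE]
  X2 <- X[, i1 + 1L, , drop = FALSE]
  mask1 <- X1 >= X2
  list(Y = pmax(X1, X2), mask1 = mask1, dimX = d)
}

pool_backward <- function(dY, cache) {
  dX <- array(0, cache$dimX)
  Lp <- dim(dY)[2L]
  i1 <- seq.int(1L, 2L * Lp, by = 2L)
  dX[, i1, ] <- dY * cache$mask1
  dX[, i1 + 1L, ] <- dY * !cache$mask1
  dX
}

# ---- batch normalization (rows = observations, cols = channels) -----------

bn_forward <- function(Xm, gamma, beta, rmean, rvar, training,
                       eps = 1e-5, momentum = 0.9) {
  if (training && nrow(Xm) > 1L) {
    mu <- colMeans(Xm)
    xc <- sweep(Xm, 2L, mu)
    v <- colMeans(xc * xc)
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * v
    used_batch <- TRUE
  } else {
    mu <- rmean; v <- rvar
    xc <- sweep(Xm, 2L, mu)
    used_batch <- FALSE
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  Y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(Y = Y, xhat = xhat, invstd = invstd,
       rmean = rmean, rvar = rvar, used_batch = used_batch)
}

bn_backward <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, "*")
  if (cache$used_batch) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dX <- sweep(dxhat * n, 2L, s1) - sweep(cache$xhat, 2L, s2, "*")
    dX <- sweep(dX, 2L, cache$invstd / n, "*")
  } else {
    dX <- sweep(dxhat, 2L, cache$invstd, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations / dropout ------------------------------------------------

LRELU_ALPHA <- 0.1

lrelu_forward <- function(X) {
  Y <- pmax(X, 0) + LRELU_ALPHA * pmin(X, 0)
  list(Y = Y, pos = X > 0)
}

lrelu_backward <- function(dY, cache) {
  dY * (cache$pos + LRELU_ALPHA * !cache$pos)
}

drop_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(Y = X, mask = NULL))
  mask <- (runif(length(X)) >= p) / (1 - p)
  dim(mask) <- dim(X)
  list(Y = X * mask, mask = mask)
}

drop_backward <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# ---- GRU ------------------------------------------------------------------

gru_init <- function(cin, units) {
  list(Wz = glorot(cin, units), Uz = glorot(units, units), bz = rep(0, units),
       Wr = glorot(cin, units), Ur = glorot(units, units), br = rep(0, units),
       Wh = glorot(cin, units), Uh = glorot(units, units), bh = rep(0, units))
}

gru_forward <- function(X, p) {
  d <- dim(X); N <- d[1L]; tt <- d[2L]; C <- d[3L]
  H <- ncol(p$Wz)
  h <- matrix(0, N, H)
  out <- array(0, c(N, tt, H))
  cache <- vector("list", tt)
  for (t in seq_len(tt)) {
    xt <- matrix(X[, t, ], N, C)
    z <- sigmoid(add_bias(xt %*% p$Wz + h %*% p$Uz, p$bz))
    r <- sigmoid(add_bias(xt %*% p$Wr + h %*% p$Ur, p$br))
    hh <- tanh(add_bias(xt %*% p$Wh + (r * h) %*% p$Uh, p$bh))
    hn <- (1 - z) * h + z * hh
    cache[[t]] <- list(xt = xt, hprev = h, z = z, r = r, hh = hh)
    h <- hn
    out[, t, ] <- h
  }
  list(Y = out, cache = cache, dimX = d)
}

gru_backward <- function(dOut, fw, p) {
  d <- fw$dimX; N <- d[1L]; tt <- d[2L]; C <- d[3L]
  H <- ncol(p$Wz)
  g <- lapply(p, function(x) array(0, dim = if (is.matrix(x)) dim(x) else length(x)))
  dX <- array(0, d)
  dh <- matrix(0, N, H)
  for (t in rev(seq_len(tt))) {
    cc <- fw$cache[[t]]
    dht <- matrix(dOut[, t, ], N, H) + dh
    dhh <- dht * cc$z
    dz <- dht * (cc$hh - cc$hprev)
    dhprev <- dht * (1 - cc$z)
    dahh <- dhh * (1 - cc$hh^2)
    drh <- tcrossprod(dahh, p$Uh)
    dr <- drh * cc$hprev
    dhprev <- dhprev + drh * cc$r
    daz <- dz * cc$z * (1 - cc$z)
    dar <- dr * cc$r * (1 - cc$r)
    dxt <- tcrossprod(dahh, p$Wh) + tcrossprod(daz, p$Wz) + tcrossprod(dar, p$Wr)
    dhprev <- dhprev + tcrossprod(daz, p$Uz) + tcrossprod(dar, p$Ur)
    g$Wh <- g$Wh + crossprod(cc$xt, dahh)
    g$Uh <- g$Uh + crossprod(cc$r * cc$hprev, dahh)
    g$bh <- g$bh + colSums(dahh)
    g$Wz <- g$Wz + crossprod(cc$xt, daz)
    g$Uz <- g$Uz + crossprod(cc$hprev, daz)
    g$bz <- g$bz + colSums(daz)
    g$Wr <- g$Wr + crossprod(cc$xt, dar)
    g$Ur <- g$Ur + crossprod(cc$hprev, dar)
    g$br <- g$br + colSums(dar)
    dX[, t, ] <- dxt
    dh <- dhprev
  }
  list(dX = dX, grads = g)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(x) array(0, dim = if (is.null(dim(x))) length(x) else dim(x)))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
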