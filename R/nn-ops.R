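# Minimal convolutional-network engine used by the segmenter.
#
# Feature maps are numeric arrays H x W x C (column-major, channel last).
# Convolutions are evaluated as im2col matrix products so the heavy
# lifting runs through BLAS; every op has an exact hand-derived backward
# pass, which keeps training fully deterministic on one CPU.

pad_hw <- function(x, p, fill = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(fill, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

# (Ho*Wo) x (k*k*C) patch matrix; column blocks ordered by kernel offset
im2col <- function(xp, k, stride, Ho, Wo) {
  C <- dim(xp)[3]
  out <- matrix(0, Ho * Wo, k * k * C)
  blk <- 1L
  for (b in 0:(k - 1L)) {
    cols <- seq.int(1L + b, by = stride, length.out = Wo)
    for (a in 0:(k - 1L)) {
      rows <- seq.int(1L + a, by = stride, length.out = Ho)
      out[, ((blk - 1L) * C + 1L):(blk * C)] <-
        matrix(xp[rows, cols, , drop = FALSE], Ho * Wo, C)
      blk <- blk + 1L
    }
  }
  out
}

col2im <- function(dXc, dims_p, k, stride, Ho, Wo) {
  C <- dims_p[3]
  dxp <- array(0, dims_p)
  blk <- 1L
  for (b in 0:(k - 1L)) {
    cols <- seq.int(1L + b, by = stride, length.out = Wo)
    for (a in 0:(k - 1L)) {
      rows <- seq.int(1L + a, by = stride, length.out = Ho)
      dxp[rows, cols, ] <- dxp[rows, cols, ] +
        array(dXc[, ((blk - 1L) * C + 1L):(blk * C)], c(Ho, Wo, C))
      blk <- blk + 1L
    }
  }
  dxp
}

conv_fwd <- function(x, par, k, stride, pad, keep) {
  d <- dim(x)
  Ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  xp <- pad_hw(x, pad)
  Xc <- im2col(xp, k, stride, Ho, Wo)
  Y <- Xc %*% par$W
  Y <- Y + rep(par$b, each = nrow(Y))
  list(y = array(Y, c(Ho, Wo, length(par$b))),
       cache = if (keep) list(Xc = Xc, dims_p = dim(xp), in_dims = d) else NULL)
}

conv_bwd <- function(dy, cache, par, k, stride, pad) {
  Ho <- dim(dy)[1]; Wo <- dim(dy)[2]
  dYm <- matrix(dy, Ho * Wo, dim(dy)[3])
  dW <- crossprod(cache$Xc, dYm)
  db <- colSums(dYm)
  dXc <- tcrossprod(dYm, par$W)
  dxp <- col2im(dXc, cache$dims_p, k, stride, Ho, Wo)
  d <- cache$in_dims
  dx <- if (pad > 0) {
    dxp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), , drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

# 2x2 stride-2 transpose convolution: each output pixel receives exactly
# one kernel tap, so the op splits into four plain matrix products.
tconv_fwd <- function(x, par, keep) {
  d <- dim(x)
  C <- d[3]; Co <- length(par$b)
  xm <- matrix(x, d[1] * d[2], C)
  y <- array(0, c(2L * d[1], 2L * d[2], Co))
  for (o in 1:4) {
    a <- (o - 1L) %% 2L; b <- (o - 1L) %/% 2L
    Wb <- par$W[((o - 1L) * C + 1L):(o * C), , drop = FALSE]
    Ym <- xm %*% Wb
    Ym <- Ym + rep(par$b, each = nrow(Ym))
    y[seq.int(1L + a, by = 2L, length.out = d[1]),
      seq.int(1L + b, by = 2L, length.out = d[2]), ] <-
      array(Ym, c(d[1], d[2], Co))
  }
  list(y = y, cache = if (keep) list(xm = xm, in_dims = d) else NULL)
}

tconv_bwd <- function(dy, cache, par) {
  d <- cache$in_dims
  C <- d[3]; Co <- dim(dy)[3]
  dW <- matrix(0, 4L * C, Co)
  db <- numeric(Co)
  dxm <- matrix(0, d[1] * d[2], C)
  for (o in 1:4) {
    a <- (o - 1L) %% 2L; b <- (o - 1L) %/% 2L
    dYm <- matrix(dy[seq.int(1L + a, by = 2L, length.out = d[1]),
                     seq.int(1L + b, by = 2L, length.out = d[2]), ,
                     drop = FALSE], d[1] * d[2], Co)
    Wb <- par$W[((o - 1L) * C + 1L):(o * C), , drop = FALSE]
    dW[((o - 1L) * C + 1L):(o * C), ] <- crossprod(cache$xm, dYm)
    db <- db + colSums(dYm)
    dxm <- dxm + tcrossprod(dYm, Wb)
  }
  list(dx = array(dxm, d), dW = dW, db = db)
}

# 3x3 stride-2 max pool with pad 1 (the classic residual-stem pool)
maxpool_fwd <- function(x, keep) {
  d <- dim(x)
  k <- 3L; stride <- 2L; pad <- 1L
  Ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  xp <- pad_hw(x, pad, fill = -Inf)
  best <- array(-Inf, c(Ho, Wo, d[3]))
  arg <- array(0L, c(Ho, Wo, d[3]))
  o <- 1L
  for (b in 0:(k - 1L)) {
    cols <- seq.int(1L + b, by = stride, length.out = Wo)
    for (a in 0:(k - 1L)) {
      rows <- seq.int(1L + a, by = stride, length.out = Ho)
      slice <- xp[rows, cols, , drop = FALSE]
      upd <- slice > best
      best[upd] <- slice[upd]
      arg[upd] <- o
      o <- o + 1L
    }
  }
  list(y = best,
       cache = if (keep) list(arg = arg, dims_p = dim(xp), in_dims = d) else NULL)
}

maxpool_bwd <- function(dy, cache) {
  k <- 3L; stride <- 2L; pad <- 1L
  Ho <- dim(dy)[1]; Wo <- dim(dy)[2]
  dxp <- array(0, cache$dims_p)
  o <- 1L
  for (b in 0:(k - 1L)) {
    cols <- seq.int(1L + b, by = stride, length.out = Wo)
    for (a in 0:(k - 1L)) {
      rows <- seq.int(1L + a, by = stride, length.out = Ho)
      tmp <- array(0, dim(dy))
      sel <- cache$arg == o
      tmp[sel] <- dy[sel]
      dxp[rows, cols, ] <- dxp[rows, cols, ] + tmp
      o <- o + 1L
    }
  }
  d <- cache$in_dims
  dxp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), , drop = FALSE]
}

# per-pixel softmax over the channel dimension
softmax_hw <- function(z) {
  d <- dim(z)
  m <- z[, , 1]
  for (k in seq_len(d[3])[-1]) m <- pmax(m, z[, , k])
  e <- exp(z - array(rep(m, d[3]), d))
  s <- e[, , 1]
  for (k in seq_len(d[3])[-1]) s <- s + e[, , k]
  e / array(rep(s, d[3]), d)
}

# weighted cross-entropy value and gradient w.r.t. logits
wce_from_logits <- function(logits, target, class_weights, eps = 1e-12) {
  p <- softmax_hw(logits)
  d <- dim(p)
  n <- d[1] * d[2]
  tvec <- as.vector(target)
  wt <- class_weights[tvec + 1L]
  lin <- seq_len(n) + n * tvec   # linear index of the target channel
  pt <- pmax(as.vector(p)[lin], eps)
  loss <- sum(wt * (-log(pt))) / n
  onehot <- array(0, d)
  onehot[lin] <- 1
  dlogits <- (p - onehot) * array(rep(wt, d[3]), d) / n
  list(loss = loss, dlogits = dlogits, probs = p)
}
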