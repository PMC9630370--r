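# Differentiable layer primitives on (X, Y, Z, C) arrays.
#
# Each *Fw returns list(y, cache); each *Bw consumes the cache and the
# upstream gradient and returns the input gradient plus parameter
# gradients. Convolutions dispatch to the compiled im2col/GEMM kernels.

convFw <- function(x, w, b, stride = 1L, pad = 0L) {
  cpp_conv3d_fw(x, w, b, stride, pad)
}

convBw <- function(x, w, gy, stride = 1L, pad = 0L) {
  cpp_conv3d_bw(x, w, gy, stride, pad)
}

# transposed convolution, kernel = stride (2): doubles each spatial dim.
# Weights use the adjoint-conv convention: dim (k, k, k, Cout, Cin).
tconvFw <- function(x, w, b) {
  d <- dim(x)
  wd <- dim(w)
  y <- cpp_conv3d_bw_data(x, w, 2L, 0L,
                          as.integer(c(d[1:3] * 2L, wd[4])))
  nv <- prod(dim(y)[1:3])
  ym <- matrix(y, nv)
  ym <- sweep(ym, 2, b, `+`)
  array(ym, dim(y))
}

tconvBw <- function(x, w, gy) {
  zeroB <- numeric(dim(w)[5])
  gx <- cpp_conv3d_fw(gy, w, zeroB, 2L, 0L)
  gw <- cpp_tconv3d_bw_filter(gy, x, w, 2L, 0L)$gw
  gb <- colSums(matrix(gy, prod(dim(gy)[1:3])))
  list(gx = gx, gw = gw, gb = gb)
}

instNormFw <- function(x, g, b, eps = 1e-5) {
  d <- dim(x)
  nv <- prod(d[1:3])
  xm <- matrix(x, nv)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
  list(y = array(y, d), cache = list(xhat = xhat, inv = inv, g = g, d = d))
}

instNormBw <- function(cache, gy) {
  d <- cache$d
  nv <- prod(d[1:3])
  gym <- matrix(gy, nv)
  gb <- colSums(gym)
  gg <- colSums(gym * cache$xhat)
  dxh <- sweep(gym, 2, cache$g, `*`)
  t1 <- sweep(dxh, 2, colSums(dxh) / nv)
  t2 <- sweep(cache$xhat, 2, colSums(dxh * cache$xhat) / nv, `*`)
  gx <- sweep(t1 - t2, 2, cache$inv, `*`)
  list(gx = array(gx, d), gg = gg, gb = gb)
}

reluFw <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

reluBw <- function(x, gy) gy * (x > 0)

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

splitChannels <- function(g, ca) {
  d <- dim(g)
  nv <- prod(d[1:3])
  ga <- array(g[seq_len(nv * ca)], c(d[1:3], ca))
  gb <- array(g[-seq_len(nv * ca)], c(d[1:3], d[4] - ca))
  list(ga, gb)
}

# channel-axis softmax with the usual max-shift stabilization
softmaxChannels <- function(x) {
  d <- dim(x)
  nv <- prod(d[1:3])
  xm <- matrix(x, nv)
  m <- xm[, 1]
  for (c in seq_len(d[4])[-1]) m <- pmax(m, xm[, c])
  e <- exp(xm - m)
  array(e / rowSums(e), d)
}

# gradient through softmax given grad in probability space
softmaxBw <- function(p, gp) {
  d <- dim(p)
  nv <- prod(d[1:3])
  pm <- matrix(p, nv)
  gm <- matrix(gp, nv)
  array(pm * (gm - rowSums(gm * pm)), d)
}
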