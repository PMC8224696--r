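# Low-level 1-D network primitives. Activations travel as arrays of shape
# (channels, length, batch). The hot paths (im2col convolution, max pooling,
# batch norm) are compiled kernels whose matrix products go through BLAS; a
# pure-R reference implementation of the convolution (explicit gather plus a
# sparse col2im scatter) is kept alongside and used as an independent
# cross-check in the tests.

# Stride-1 convolutions run their GEMMs in single precision by default
# (weights and activations stay double-precision in R; the kernel converts
# at entry and exit). Set options(anomdiff.precision = "double") for fully
# double-precision passes, e.g. for finite-difference gradient checks.
conv_single <- function() {
  !identical(getOption("anomdiff.precision", "single"), "double")
}

conv1d_fw <- function(x, W, stride = 1L, pad = 0L) {
  conv1d_fw_cpp(x, W, dim(x), as.integer(stride), as.integer(pad),
                conv_single())
}

conv1d_bw <- function(dy, x, W, stride = 1L, pad = 0L) {
  conv1d_bw_cpp(dy, x, W, dim(x), as.integer(stride), as.integer(pad),
                conv_single())
}

maxpool_fw <- function(x, k = 3L, stride = 2L, pad = 1L) {
  res <- maxpool_fw_cpp(x, dim(x), as.integer(k), as.integer(stride),
                        as.integer(pad))
  list(y = res$y, cache = list(amax = res$amax, dims = dim(x), k = k,
                               stride = stride, pad = pad))
}

maxpool_bw <- function(dy, cache) {
  maxpool_bw_cpp(dy, cache$amax, cache$dims, as.integer(cache$k),
                 as.integer(cache$stride), as.integer(cache$pad))
}

new_bn <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C), theta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C))
}

bn_fw <- function(x, bn, training, momentum = 0.1, eps = 1e-5) {
  res <- bn_fw_cpp(x, dim(x), bn$gamma, bn$beta, bn$theta, training,
                   bn$run_mean, bn$run_var, momentum, eps)
  if (training) {
    bn$run_mean <- res$run_mean
    bn$run_var <- res$run_var
  }
  list(y = res$y, bn = bn,
       cache = if (training) list(xhat = res$xhat, invstd = res$invstd) else NULL)
}

bn_bw <- function(dy, cache, gamma) {
  res <- bn_bw_cpp(dy, cache$xhat, cache$invstd, gamma, dim(dy))
  list(dx = res$dx,
       grads = list(gamma = res$dgamma, beta = res$dbeta, theta = -res$dbeta))
}

act_fw <- function(x, type) {
  switch(type,
         relu = relu_fw_cpp(x),
         leaky_relu = ifelse(x > 0, x, 0.01 * x),
         elu = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
         sigmoid = 1 / (1 + exp(-x)),
         abort(sprintf("Unknown activation '%s'.", type)))
}

act_bw <- function(dy, y, x, type) {
  switch(type,
         relu = relu_bw_cpp(dy, x),
         leaky_relu = dy * ifelse(x > 0, 1, 0.01),
         elu = dy * ifelse(x > 0, 1, y + 1),
         sigmoid = dy * y * (1 - y))
}

avgpool2_fw <- function(x) {
  d <- dim(x)
  Lout <- (d[2] - 2L) %/% 2L + 1L
  odd <- seq_len(Lout) * 2L - 1L
  (x[, odd, , drop = FALSE] + x[, odd + 1L, , drop = FALSE]) / 2
}

avgpool2_bw <- function(dy, L) {
  d <- dim(dy)
  dx <- array(0, dim = c(d[1], L, d[3]))
  odd <- seq_len(d[2]) * 2L - 1L
  dx[, odd, ] <- dy / 2
  dx[, odd + 1L, ] <- dy / 2
  dx
}

gap_fw <- function(x) {
  d <- dim(x)
  y <- matrix(0, d[1], d[3])
  for (l in seq_len(d[2])) y <- y + matrix(x[, l, ], d[1], d[3])
  y / d[2]
}

gap_bw <- function(dy, L) {
  d <- dim(dy)
  dx <- array(0, dim = c(d[1], L, d[2]))
  per <- dy / L
  for (l in seq_len(L)) dx[, l, ] <- per
  dx
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# ---- Pure-R reference convolution (independent algorithm: index gather for
# im2col, cached sparse-matrix product for the col2im scatter). Used by the
# test suite to cross-check the compiled path.

.conv_cache <- new.env(parent = emptyenv())

conv_geometry <- function(C, L, k, stride, pad) {
  Lp <- L + 2L * pad
  Lout <- (Lp - k) %/% stride + 1L
  key <- paste(C, L, k, stride, pad, sep = "_")
  geo <- .conv_cache[[key]]
  if (is.null(geo)) {
    tap <- rep(seq_len(k), each = C)
    ch <- rep(seq_len(C), times = k)
    start <- (seq_len(Lout) - 1L) * stride
    idx <- outer((tap - 1L) * C + ch, start * C, "+")
    S <- Matrix::sparseMatrix(i = as.integer(idx), j = seq_along(idx), x = 1,
                              dims = c(C * Lp, length(idx)))
    geo <- list(Lp = Lp, Lout = Lout, idx = as.integer(idx), S = S)
    .conv_cache[[key]] <- geo
  }
  geo
}

pad_input <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, dim = c(d[1], d[2] + 2L * pad, d[3]))
  xp[, (pad + 1L):(pad + d[2]), ] <- x
  xp
}

im2col_ref <- function(xp, geo, C, B) {
  per <- C * geo$Lp
  idxb <- rep(geo$idx, times = B) + rep.int((seq_len(B) - 1L) * per,
                                            rep(length(geo$idx), B))
  matrix(xp[idxb], nrow = length(geo$idx) %/% geo$Lout)
}

conv1d_fw_ref <- function(x, W, stride = 1L, pad = 0L) {
  d <- dim(x)
  C <- d[1]; B <- d[3]
  k <- ncol(W) %/% C
  geo <- conv_geometry(C, d[2], k, stride, pad)
  y <- W %*% im2col_ref(pad_input(x, pad), geo, C, B)
  array(y, dim = c(nrow(W), geo$Lout, B))
}

conv1d_bw_ref <- function(dy, x, W, stride = 1L, pad = 0L) {
  d <- dim(x)
  C <- d[1]; L <- d[2]; B <- d[3]
  k <- ncol(W) %/% C
  geo <- conv_geometry(C, L, k, stride, pad)
  cols <- im2col_ref(pad_input(x, pad), geo, C, B)
  dy_m <- matrix(dy, nrow = dim(dy)[1])
  dW <- dy_m %*% t(cols)
  dcols <- crossprod(W, dy_m)
  dxp <- geo$S %*% matrix(dcols, ncol = B)
  dxp <- array(as.numeric(dxp), dim = c(C, geo$Lp, B))
  dx <- if (pad > 0L) dxp[, (pad + 1L):(pad + L), , drop = FALSE] else dxp
  list(dx = dx, dW = dW)
}
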