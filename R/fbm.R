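# Exact sampling of fractional Gaussian noise (the increment process of
# fractional Brownian motion) by circulant embedding, with a Cholesky
# fallback if the embedding is not non-negative definite at the requested
# (n, H). Increments at spacing dt have variance dt^(2H) and autocovariance
#   g(j) = dt^(2H)/2 * (|j+1|^(2H) - 2|j|^(2H) + |j-1|^(2H)).

fgn_autocov <- function(j, H, dt) {
  dt^(2 * H) / 2 * (abs(j + 1)^(2 * H) - 2 * abs(j)^(2 * H) + abs(j - 1)^(2 * H))
}

#' Sample fractional Gaussian noise exactly
#'
#' Returns `n` increments of a fractional Brownian motion with Hurst index
#' `H` sampled at spacing `dt`, drawn from the exact joint Gaussian law
#' (circulant embedding; Cholesky decomposition of the covariance if the
#' embedding fails, which does not occur for `H <= 1/2`).
#'
#' @param n Number of increments (>= 1).
#' @param H Hurst index in (0, 1).
#' @param dt Sampling interval.
#' @return Numeric vector of length `n`.
#' @export
fgn_sample <- function(n, H, dt = 1) {
  if (n < 1) abort("`n` must be at least 1.")
  if (H <= 0 || H >= 1) abort("`H` must lie in (0, 1).")
  if (n == 1) return(rnorm(1, 0, dt^H))
  g <- fgn_autocov(0:n, H, dt)
  row <- c(g[1:n], g[n + 1], g[n:2])           # circulant first row, length 2n
  lambda <- Re(fft(row))
  m <- 2 * n
  if (min(lambda) < -1e-9 * max(lambda)) {
    return(fgn_sample_chol(n, g))
  }
  lambda[lambda < 0] <- 0
  # Hermitian-symmetric spectral noise; fixed draw order for reproducibility.
  z_re <- rnorm(n + 1)
  z_im <- rnorm(n - 1)
  w <- complex(length.out = m)
  w[1] <- sqrt(lambda[1] / m) * z_re[1]
  w[n + 1] <- sqrt(lambda[n + 1] / m) * z_re[n + 1]
  idx <- 2:n
  w[idx] <- sqrt(lambda[idx] / (2 * m)) * complex(real = z_re[idx], imaginary = z_im)
  w[m + 2 - idx] <- Conj(w[idx])
  Re(fft(w))[1:n]
}

fgn_sample_chol <- function(n, g) {
  G <- matrix(g[abs(outer(1:n, 1:n, "-")) + 1], n, n)
  L <- chol(G)
  as.numeric(crossprod(L, rnorm(n)))
}
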