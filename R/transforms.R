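#' Orthonormal transform matrices used by the collaborative filter
#'
#' `dct_matrix()` returns the orthonormal (type-II) discrete cosine transform
#' matrix of size `n`; `haar_matrix()` returns the orthonormal dyadic Haar
#' wavelet matrix for a power-of-two size. Both satisfy `T %*% t(T) == I`,
#' which the transform-domain variance computations rely on. For `m = 1` the
#' Haar "transform" is the 1x1 identity (single-block groups).
#'
#' @param n,m transform length; `m` must be a power of two.
#' @return An `n x n` (or `m x m`) orthonormal matrix; rows are basis functions.
#' @examples
#' D <- dct_matrix(8)
#' max(abs(D %*% t(D) - diag(8))) < 1e-12
#' @export
dct_matrix <- function(n) {
  stopifnot(n >= 1)
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  D[1, ] <- sqrt(1 / n)
  D
}

#' @rdname dct_matrix
#' @export
haar_matrix <- function(m) {
  stopifnot(m >= 1, bitwAnd(m, m - 1L) == 0)
  if (m == 1) return(matrix(1, 1, 1))
  H <- matrix(1, 1, 1)
  while (nrow(H) < m) {
    n <- nrow(H)
    H <- rbind(
      kronecker(H, matrix(c(1, 1) / sqrt(2), 1, 2)),
      kronecker(diag(n), matrix(c(1, -1) / sqrt(2), 1, 2))
    )
  }
  H
}

# 2-D FFT helpers fixing the project-wide DFT convention: unnormalized
# forward transform, inverse divided by the number of elements.
fft2 <- function(x) stats::fft(x)

ifft2 <- function(x, real = TRUE) {
  y <- stats::fft(x, inverse = TRUE) / length(x)
  if (real) Re(y) else y
}

# Largest power of two <= n
pow2_floor <- function(n) {
  stopifnot(n >= 1)
  2L^as.integer(floor(log2(n)))
}
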