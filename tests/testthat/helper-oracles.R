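# Independent oracles used by the tests. These deliberately avoid the
# package's own FFT-based code paths: explicit double-sum DFTs and dense
# covariance constructions, feasible only at tiny sizes.

# O(n^4) double-sum 2-D DFT
brute_dft2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0 + 0i, nr, nc)
  for (u in 0:(nr - 1)) for (v in 0:(nc - 1)) {
    s <- 0 + 0i
    for (a in 0:(nr - 1)) for (b in 0:(nc - 1))
      s <- s + x[a + 1, b + 1] * exp(-2i * pi * (u * a / nr + v * b / nc))
    out[u + 1, v + 1] <- s
  }
  out
}

# brute-force autocovariance from a PSD (inverse double-sum DFT, real part)
brute_autocov <- function(psi) {
  nr <- nrow(psi); nc <- ncol(psi)
  out <- matrix(0, nr, nc)
  for (a in 0:(nr - 1)) for (b in 0:(nc - 1)) {
    s <- 0 + 0i
    for (u in 0:(nr - 1)) for (v in 0:(nc - 1))
      s <- s + psi[u + 1, v + 1] * exp(2i * pi * (u * a / nr + v * b / nc))
    out[a + 1, b + 1] <- Re(s) / (nr * nc)
  }
  out
}

# dense covariance oracle for group-spectrum variances: builds the MN x MN
# pixel covariance from the autocovariance and evaluates the quadratic form
# of every explicit tensor-product basis vector.
oracle_group_variances <- function(psi, block_size, positions, image_shape,
                                   t2d, t1d) {
  nr <- image_shape[1]; nc <- image_shape[2]
  r <- brute_autocov(psi)
  M <- nrow(positions); bs <- block_size; N <- bs^2
  pr <- integer(0); pc <- integer(0)
  for (m in seq_len(M)) for (q in seq_len(bs)) for (p in seq_len(bs)) {
    pr <- c(pr, positions[m, 1] + p - 1)
    pc <- c(pc, positions[m, 2] + q - 1)
  }
  S <- matrix(0, M * N, M * N)
  for (i in seq_len(M * N)) for (j in seq_len(M * N)) {
    S[i, j] <- r[((pr[i] - pr[j]) %% nr) + 1, ((pc[i] - pc[j]) %% nc) + 1]
  }
  out <- matrix(0, N, M)
  for (jj in seq_len(M)) {
    i <- 0
    for (q in seq_len(bs)) for (p in seq_len(bs)) {
      i <- i + 1
      u <- numeric(M * N)
      for (m in seq_len(M)) {
        base <- (m - 1) * N
        k <- 0
        for (qq in seq_len(bs)) for (pp in seq_len(bs)) {
          k <- k + 1
          u[base + k] <- t2d[p, pp] * t2d[q, qq] * t1d[jj, m]
        }
      }
      out[i, jj] <- drop(t(u) %*% S %*% u)
    }
  }
  out
}

# random symmetric nonnegative PSD (PSD of a real field is always symmetric
# under frequency negation: construct one from a real random field)
random_psd <- function(nr, nc) {
  Mod(stats::fft(matrix(rnorm(nr * nc), nr, nc)))^2
}

# smooth synthetic sinogram (sum of wide Gaussian traces), used where tests
# need a signal with negligible detail-filter leakage
smooth_sinogram <- function(m, n) {
  ang <- seq(0, pi, length.out = m)
  out <- matrix(0, m, n)
  for (blob in list(c(0.3, 0.15, 1), c(-0.2, 0.1, 0.6), c(0.05, 0.3, 0.8))) {
    ctr <- (n + 1) / 2 + blob[1] * n / 2 * cos(ang + blob[2] * pi)
    for (i in seq_len(m))
      out[i, ] <- out[i, ] + blob[3] * exp(-((seq_len(n) - ctr[i])^2) /
                                             (2 * (blob[2] * n / 3)^2))
  }
  out
}
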