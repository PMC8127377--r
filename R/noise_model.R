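# Stationary correlated-noise model: correlation kernels, power spectral
# densities, noise synthesis, and exact transform-domain coefficient
# variances for the collaborative filter.
#
# Conventions fixed project-wide:
#   * unnormalized forward 2-D DFT; inverse DFT divides by the number of
#     elements (see fft2()/ifft2()),
#   * psd_from_kernel(g, shape) = |DFT(g embedded on shape)|^2,
#   * autocovariance r = Re(IDFT(Psi)), so r[0,0] = ||g||_2^2 = per-pixel
#     noise variance, and white noise of variance s^2 has Psi == s^2.
# These choices are enforced by the round-trip and synthesis-consistency
# tests rather than by any external reference.

#' Correlation kernel of stationary spatially correlated noise
#'
#' A correlation kernel `g` defines stationary correlated noise as the
#' circular convolution of a unit-variance i.i.d. Gaussian field with `g`;
#' its L2 norm equals the per-pixel noise standard deviation.
#'
#' @param values numeric matrix (kernel support, rows x cols).
#' @return An object of class `correlation_kernel` (a matrix with a class
#'   attribute).
#' @seealso [psd_from_kernel()], [generate_noise()], [streak_kernel()]
#' @export
correlation_kernel <- function(values) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), all(is.finite(values)))
  structure(values, class = c("correlation_kernel", "matrix"))
}

#' @rdname correlation_kernel
#' @param x object to test / print.
#' @param ... unused.
#' @export
print.correlation_kernel <- function(x, ...) {
  cat(sprintf("correlation kernel %d x %d, ||g||_2 = %.6g\n",
              nrow(x), ncol(x), kernel_std(x)))
  invisible(x)
}

#' Per-pixel noise standard deviation of a kernel (its L2 norm)
#' @param g correlation kernel (matrix).
#' @export
kernel_std <- function(g) sqrt(sum(g^2))

# Embed a kernel on a larger support, centered at the DFT origin with
# circular wraparound (zero frequency at element [1, 1]).
embed_kernel <- function(g, shape) {
  nr <- shape[1]; nc <- shape[2]
  kr <- nrow(g); kc <- ncol(g)
  if (kr > nr || kc > nc)
    stop("kernel support (", kr, "x", kc, ") exceeds target shape (",
         nr, "x", nc, ")")
  out <- matrix(0, nr, nc)
  cr <- floor(kr / 2); cc <- floor(kc / 2)  # center offset
  ri <- ((seq_len(kr) - 1 - cr) %% nr) + 1
  ci <- ((seq_len(kc) - 1 - cc) %% nc) + 1
  out[ri, ci] <- out[ri, ci] + g
  out
}

#' Power spectral density of the noise defined by a correlation kernel
#'
#' The PSD is the squared magnitude of the 2-D DFT of the kernel embedded
#' (centered at the origin, with circular wraparound) on the given support.
#' Under the project DFT convention, the mean of the PSD equals the per-pixel
#' noise variance `||g||_2^2`.
#'
#' @param g correlation kernel (matrix).
#' @param shape integer vector `c(rows, cols)`; must be at least the kernel
#'   support.
#' @return A `power_spectrum` object (nonnegative matrix, DC at `[1, 1]`).
#' @export
psd_from_kernel <- function(g, shape = dim(g)) {
  e <- embed_kernel(g, shape)
  structure(Mod(fft2(e))^2, class = c("power_spectrum", "matrix"))
}

#' Zero-phase correlation kernel realizing a given power spectral density
#'
#' Returns the real inverse 2-D DFT of the elementwise square root of `psi`
#' (the zero-phase "root" kernel). For any PSD of a real stationary field
#' (i.e. symmetric under frequency negation) the round trip
#' `psd_from_kernel(kernel_from_psd(psi), dim(psi))` recovers `psi`.
#'
#' @param psi nonnegative matrix (PSD, DC at `[1, 1]`).
#' @export
kernel_from_psd <- function(psi) {
  psi <- unclass(psi)
  if (any(psi < 0)) stop("PSD must be elementwise nonnegative")
  g <- ifft2(sqrt(psi), real = FALSE)
  if (max(abs(Im(g))) > 1e-8 * (max(abs(g)) + 1e-300))
    warning("PSD is not symmetric under frequency negation; ",
            "imaginary residue discarded")
  correlation_kernel(Re(g))
}

#' Noise autocovariance from a power spectral density
#'
#' Inverse DFT of the PSD under the project convention; `r[1, 1]` is the
#' per-pixel variance, entry `[dr + 1, dc + 1]` the covariance at circular
#' offset `(dr, dc)`.
#'
#' @param psi PSD matrix.
#' @export
autocovariance <- function(psi) {
  r <- ifft2(unclass(psi), real = FALSE)
  if (max(abs(Im(r))) > 1e-10 * (1 + max(abs(Re(r)))))
    stop("PSD yields non-real autocovariance (imaginary residue too large)")
  Re(r)
}

#' Synthesize stationary correlated noise
#'
#' Circular convolution of a unit-variance i.i.d. Gaussian field with the
#' kernel `g`. Deterministic given `seed`; the per-pixel standard deviation
#' converges to `||g||_2` over realizations.
#'
#' @param g correlation kernel.
#' @param shape `c(rows, cols)` of the output field.
#' @param seed integer seed, or `NULL` to use (and advance) the current RNG
#'   state.
#' @export
generate_noise <- function(g, shape, seed = NULL) {
  nr <- shape[1]; nc <- shape[2]
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  nu <- matrix(rnorm(nr * nc), nr, nc)
  G <- fft2(embed_kernel(g, shape))
  ifft2(fft2(nu) * G)
}

#' Vertically constant streak-noise kernel
#'
#' Single-column, full-height constant kernel modeling horizontally white and
#' vertically constant streak noise; each entry is `sigma / sqrt(height)` so
#' that `||g||_2 = sigma`, the per-pixel streak standard deviation.
#'
#' @param height field height in pixels (kernel spans the full height).
#' @param sigma per-pixel streak noise standard deviation.
#' @export
streak_kernel <- function(height, sigma) {
  stopifnot(height >= 1, sigma >= 0)
  correlation_kernel(matrix(sigma / sqrt(height), height, 1))
}

#' Residual streak kernel after coarse-scale replacement
#'
#' At every scale finer than the coarsest, the horizontally coarse content of
#' the sinogram is replaced by the (assumed perfectly denoised) coarser-scale
#' estimate, so the streak noise that remains is the high-horizontal-frequency
#' residual `w - debin(bin(w))` of white streak noise `w`. This function
#' estimates the 1-D spectral profile of that residual by Monte Carlo (sample
#' standard deviation per frequency over `mc_iters` white draws), converts it
#' to a zero-phase unit-L2 kernel, and tiles it vertically. The kernel is
#' input-independent and cached per `(width, height, mc_iters)`.
#'
#' @param width horizontal support (the denoised segment width), at least 4.
#' @param height vertical tiling height (field height); the kernel is
#'   vertically constant.
#' @param mc_iters Monte Carlo iterations (at least 2).
#' @param seed seed for the (cached) simulation.
#' @return A `correlation_kernel` of size `height x width` with unit L2 norm.
#' @export
residual_streak_kernel <- function(width, height = 1, mc_iters = 2000,
                                   seed = 20260910) {
  stopifnot(width >= 4)
  if (mc_iters < 2) stop("mc_iters must be at least 2")
  key <- sprintf("resk_%d_%d_%d_%d", width, height, mc_iters, seed)
  hit <- .sinostrip_cache[[key]]
  if (!is.null(hit)) return(hit)
  prof <- residual_profile_1d(width, mc_iters, seed)
  q <- Re(stats::fft(prof, inverse = TRUE)) / width     # zero-phase 1-D kernel
  q <- q / sqrt(sum(q^2))
  g <- correlation_kernel(matrix(rep(q, each = height) / sqrt(height),
                                 height, width, byrow = FALSE))
  .sinostrip_cache[[key]] <- g
  g
}

# Monte Carlo per-frequency sample std of w - debin(bin(w)) for white 1-D w.
residual_profile_1d <- function(width, mc_iters, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  acc <- numeric(width)
  for (it in seq_len(mc_iters)) {
    w <- rnorm(width)
    r <- w - debin(bin(matrix(w, 1), axis = "cols", factor = 2),
                   axis = "cols", target_extent = width)[1, ]
    acc <- acc + Mod(stats::fft(r))^2
  }
  sqrt(acc / mc_iters)
}

#' Geometry of a group of matched blocks
#'
#' @param block_size square block side in pixels.
#' @param positions integer matrix `M x 2` of top-left block coordinates
#'   (row, col), 1-based.
#' @param image_shape `c(rows, cols)` of the image the blocks live in.
#' @export
group_geometry <- function(block_size, positions, image_shape) {
  positions <- matrix(as.integer(positions), ncol = 2)
  stopifnot(block_size >= 1, nrow(positions) >= 1)
  if (any(positions < 1) ||
      any(positions[, 1] + block_size - 1 > image_shape[1]) ||
      any(positions[, 2] + block_size - 1 > image_shape[2]))
    stop("all blocks must lie fully inside the image")
  structure(list(block_size = as.integer(block_size), positions = positions,
                 image_shape = as.integer(image_shape)),
            class = "group_geometry")
}

# Per-coefficient cross-covariance lookup tables: luts[dr+1, dc+1, i] is the
# covariance between the i-th 2-D transform coefficient of two blocks at
# circular offset (dr, dc), under stationary noise with PSD psi.
# Coefficient order is column-major over the bs x bs coefficient grid.
coef_cov_luts <- function(psi, block_size, t2d = dct_matrix(block_size)) {
  psi <- unclass(psi)
  nr <- nrow(psi); nc <- ncol(psi)
  if (nr < block_size || nc < block_size)
    stop("PSD support smaller than block size")
  N <- block_size^2
  luts <- array(0, c(nr, nc, N))
  i <- 0L
  for (q in seq_len(block_size)) {
    for (p in seq_len(block_size)) {
      i <- i + 1L
      w <- matrix(0, nr, nc)
      w[seq_len(block_size), seq_len(block_size)] <- outer(t2d[p, ], t2d[q, ])
      luts[, , i] <- ifft2(psi * Mod(fft2(w))^2)
    }
  }
  luts
}

#' Exact variances of the 3-D group-spectrum coefficients
#'
#' Variance of every coefficient of the joint 3-D transform (2-D transform per
#' block, then a 1-D transform across the stack of `M` matched blocks) under
#' stationary noise with PSD `psi`. The defining contract is the dense route:
#' build the `MN x MN` covariance of the stacked block pixels from the noise
#' autocovariance and evaluate `w' S w` for each tensor-product basis vector
#' `w`. The spectral route computes the same quantities through per-coefficient
#' cross-covariance lookup tables and is used automatically for larger groups;
#' both routes agree to numerical precision.
#'
#' @param psi PSD matrix, same shape as the image the geometry refers to.
#' @param geom a [group_geometry()].
#' @param t2d orthonormal 2-D transform matrix (`block_size x block_size`).
#' @param t1d orthonormal 1-D transform matrix (`M x M`).
#' @param method `"auto"` (dense for `M * N <= 4096`), `"dense"`, or
#'   `"spectral"`.
#' @return `N x M` matrix of nonnegative variances; row `i` indexes the 2-D
#'   coefficient (column-major), column `j` the 1-D basis function.
#' @export
group_variances <- function(psi, geom,
                            t2d = dct_matrix(geom$block_size),
                            t1d = haar_matrix(nrow(geom$positions)),
                            method = c("auto", "dense", "spectral")) {
  method <- match.arg(method)
  psi <- unclass(psi)
  if (!all(dim(psi) == geom$image_shape))
    stop("PSD shape (", paste(dim(psi), collapse = "x"),
         ") does not match image shape (",
         paste(geom$image_shape, collapse = "x"), ")")
  bs <- geom$block_size
  M <- nrow(geom$positions)
  N <- bs^2
  stopifnot(nrow(t1d) == M, nrow(t2d) == bs)
  if (method == "auto") method <- if (M * N <= 4096) "dense" else "spectral"
  if (method == "dense") {
    group_variances_dense(psi, geom, t2d, t1d)
  } else {
    luts <- coef_cov_luts(psi, bs, t2d)
    group_variances_spectral(luts, geom, t1d)
  }
}

group_variances_dense <- function(psi, geom, t2d, t1d) {
  nr <- nrow(psi); nc <- ncol(psi)
  bs <- geom$block_size; M <- nrow(geom$positions); N <- bs^2
  r <- autocovariance(psi)
  # absolute pixel coordinates of the stacked group, block-major
  pr <- integer(M * N); pc <- integer(M * N)
  idx <- 0L
  for (m in seq_len(M)) {
    for (q in seq_len(bs)) {     # column-major within block
      for (p in seq_len(bs)) {
        idx <- idx + 1L
        pr[idx] <- geom$positions[m, 1] + p - 1L
        pc[idx] <- geom$positions[m, 2] + q - 1L
      }
    }
  }
  dr <- (outer(pr, pr, "-") %% nr) + 1L
  dc <- (outer(pc, pc, "-") %% nc) + 1L
  S <- matrix(r[cbind(as.vector(dr), as.vector(dc))], M * N, M * N)
  out <- matrix(0, N, M)
  w2 <- matrix(0, N, N)  # 2-D basis vectors as columns, column-major coef order
  i <- 0L
  for (q in seq_len(bs)) for (p in seq_len(bs)) {
    i <- i + 1L
    w2[, i] <- as.vector(outer(t2d[p, ], t2d[q, ]))
  }
  for (j in seq_len(M)) {
    for (i in seq_len(N)) {
      u <- as.vector(outer(w2[, i], t1d[j, ]))  # block-major stacking
      out[i, j] <- drop(crossprod(u, S %*% u))
    }
  }
  pmax(out, 0)
}

group_variances_spectral <- function(luts, geom, t1d) {
  nr <- geom$image_shape[1]; nc <- geom$image_shape[2]
  M <- nrow(geom$positions); N <- dim(luts)[3]
  dr <- (outer(geom$positions[, 1], geom$positions[, 1], "-") %% nr) + 1L
  dc <- (outer(geom$positions[, 2], geom$positions[, 2], "-") %% nc) + 1L
  out <- matrix(0, N, M)
  for (i in seq_len(N)) {
    lut <- luts[, , i]
    V <- matrix(lut[cbind(as.vector(dr), as.vector(dc))], M, M)
    out[i, ] <- rowSums((t1d %*% V) * t1d)
  }
  pmax(out, 0)
}

#' Transform-domain variances of the difference of two blocks
#'
#' Variance of each 2-D transform coefficient of the difference between a
#' block at the origin and a block at relative offset `d`, under stationary
#' noise with PSD `psi`. Used to compensate the block-matching distance for
#' noise correlation.
#'
#' @param psi PSD matrix (support is the image the offsets are taken in).
#' @param block_size square block side.
#' @param offset integer `c(dr, dc)` relative offset.
#' @param t2d orthonormal 2-D transform matrix.
#' @return Length-`block_size^2` vector of variances (column-major coefficient
#'   order).
#' @export
block_difference_variances <- function(psi, block_size, offset,
                                       t2d = dct_matrix(block_size)) {
  psi <- unclass(psi)
  nr <- nrow(psi); nc <- ncol(psi)
  luts <- coef_cov_luts(psi, block_size, t2d)
  dr <- (offset[1] %% nr) + 1L
  dc <- (offset[2] %% nc) + 1L
  v0 <- luts[1, 1, ]
  vd <- luts[dr, dc, ]
  pmax(2 * (v0 - vd), 0)
}
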