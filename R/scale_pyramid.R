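# Binning / iterative spline debinning and the coarse-to-fine multiscale
# denoising recursion.

#' Pixel binning by summation
#'
#' Replaces non-overlapping windows of `factor` adjacent pixels along `axis`
#' by their sum (binning by sum, not mean: all noise-level bookkeeping in the
#' multiscale model assumes sums, under which one horizontal binning doubles
#' the white streak-noise variance). A tail shorter than `factor` is completed
#' by edge replication before summing.
#'
#' @param x numeric matrix.
#' @param axis `"rows"` (bin down each column, reducing the number of rows)
#'   or `"cols"` (bin along each row, reducing the number of columns).
#' @param factor integer binning factor, at least 1.
#' @export
bin <- function(x, axis = c("cols", "rows"), factor = 2L) {
  axis <- match.arg(axis)
  factor <- as.integer(factor)
  stopifnot(is.matrix(x), factor >= 1)
  if (axis == "rows") return(t(bin(t(x), "cols", factor)))
  n <- ncol(x)
  if (factor > n) stop("binning factor exceeds extent (", n, ")")
  if (factor == 1L) return(x)
  nb <- ceiling(n / factor)
  pad <- nb * factor - n
  if (pad > 0) x <- cbind(x, x[, rep(n, pad), drop = FALSE])
  out <- matrix(0, nrow(x), nb)
  for (k in seq_len(factor)) out <- out + x[, seq(k, nb * factor, by = factor), drop = FALSE]
  out
}

# cubic-spline upsampling of binned samples back onto the fine grid:
# binned sample t sits at the center of its window, fine coordinates
# (t - 0.5) * factor + 0.5.
spline_upsample <- function(y, factor, target_extent) {
  nb <- ncol(y)
  xs <- (seq_len(nb) - 0.5) * factor + 0.5
  xt <- seq_len(target_extent)
  out <- matrix(0, nrow(y), target_extent)
  for (i in seq_len(nrow(y))) {
    out[i, ] <- if (nb >= 4) {
      stats::spline(xs, y[i, ], xout = xt, method = "natural")$y
    } else if (nb >= 2) {
      stats::approx(xs, y[i, ], xout = xt, rule = 2)$y
    } else {
      rep(y[i, 1], target_extent)
    }
  }
  out
}

#' Iterative spline debinning (right inverse of [bin()])
#'
#' Upsamples a binned image back to `target_extent` so that re-binning
#' reproduces the input: initialized with cubic-spline upsampling of
#' `y / factor`, then corrected iteratively with
#' `u <- u + spline_upsample((y - bin(u)) / factor)` until the binning
#' residual falls below `tol` or `n_iters` is reached.
#'
#' @param y binned matrix.
#' @param axis as in [bin()].
#' @param target_extent original extent along `axis`; must be consistent with
#'   the binning that produced `y`.
#' @param factor binning factor.
#' @param n_iters maximum correction iterations (default 25; convergence
#'   is geometric, roughly a factor 3 per iteration, and typically stalls
#'   below `tol` after about 20).
#' @param tol stop when `max |y - bin(u)| < tol` (default 1e-8).
#' @export
debin <- function(y, axis = c("cols", "rows"), target_extent, factor = 2L,
                  n_iters = 25L, tol = 1e-8) {
  axis <- match.arg(axis)
  if (axis == "rows") return(t(debin(t(y), "cols", target_extent, factor, n_iters, tol)))
  factor <- as.integer(factor)
  nb <- ncol(y)
  if (nb != ceiling(target_extent / factor))
    stop("target_extent ", target_extent, " inconsistent with ", nb,
         " bins of factor ", factor)
  if (factor == 1L) return(y)
  u <- spline_upsample(y / factor, factor, target_extent)
  for (it in seq_len(n_iters)) {
    res <- y - bin(u, "cols", factor)
    if (max(abs(res)) < tol) break
    u <- u + spline_upsample(res / factor, factor, target_extent)
  }
  u
}

#' Replace the coarse-scale components of an image by a coarser estimate
#'
#' Computes `z + debin(y_coarse - bin(z))`: the result re-bins to `y_coarse`
#' (within debinning tolerance) while retaining the fine-scale detail of `z`.
#'
#' @param z fine-scale matrix.
#' @param y_coarse coarse-scale matrix, shaped like `bin(z, axis, factor)`.
#' @param axis,factor,n_iters as in [bin()] / [debin()].
#' @export
replace_coarse <- function(z, y_coarse, axis = c("cols", "rows"), factor = 2L,
                           n_iters = 25L) {
  axis <- match.arg(axis)
  b <- bin(z, axis, factor)
  if (!all(dim(b) == dim(y_coarse)))
    stop("y_coarse shape (", paste(dim(y_coarse), collapse = "x"),
         ") does not match bin(z) (", paste(dim(b), collapse = "x"), ")")
  ext <- if (axis == "cols") ncol(z) else nrow(z)
  z + debin(y_coarse - b, axis, ext, factor, n_iters)
}

#' Choose the vertical bin factor and number of horizontal scales
#'
#' The sinogram is first binned vertically to a height near `target_height`
#' (64 pixels by default, slightly above the 39-pixel matching neighborhood,
#' so slowly varying streaks remain quasi-constant within the binned window),
#' then halved horizontally `K` times while keeping the coarsest width at or
#' above `min_width` so it still accommodates the search neighborhood.
#'
#' @param m sinogram height (number of angles).
#' @param n sinogram width (number of displacements).
#' @param target_height target height after vertical binning.
#' @param min_width minimum width of the coarsest scale.
#' @return list with `f_v` (vertical bin factor) and `K` (horizontal scales).
#' @export
choose_scales <- function(m, n, target_height = 64, min_width = 64) {
  stopifnot(m >= 1, n >= 1)
  f_v <- max(1L, as.integer(round(m / target_height)))
  K <- max(0L, as.integer(floor(log2(n / min_width))))
  list(f_v = f_v, K = K)
}

#' Multiscale collaborative denoising of a single sinogram
#'
#' Input orientation: streaks vertical, i.e. angle is the row dimension and
#' displacement the column dimension. The sinogram is binned vertically once,
#' then halved horizontally `K` times; the coarsest scale is denoised under
#' the white streak-noise model, and each finer scale is denoised after its
#' coarse horizontal content has been replaced by the coarser estimate, under
#' the residual streak model. At every scale the noise level is
#' self-calibrated per overlapping horizontal segment (see
#' [calibrate_segments()]). Finally the denoised vertically binned estimate
#' replaces the vertical coarse components of the input.
#'
#' @param z sinogram matrix (angle x displacement).
#' @param cfg a [pipeline_config()] (or [filter_config()] fields are taken
#'   from it).
#' @param return_profile if `TRUE`, attach the per-scale calibration profiles
#'   as attribute `"calibration"`.
#' @return Denoised sinogram, same shape as `z`.
#' @export
multiscale_denoise <- function(z, cfg = pipeline_config(), return_profile = FALSE) {
  stopifnot(is.matrix(z))
  m <- nrow(z); n <- ncol(z)
  sc <- choose_scales(m, n, cfg$target_height, cfg$min_width)
  f_v <- if (!is.null(cfg$f_v)) cfg$f_v else sc$f_v
  K <- if (!is.null(cfg$K)) cfg$K else sc$K
  bs <- cfg$block_size
  if (m < bs || n < bs) stop("sinogram smaller than the filter block size")

  z0 <- bin(z, "rows", f_v)
  zs <- vector("list", K + 1)
  zs[[1]] <- z0
  if (K > 0) for (k in seq_len(K)) zs[[k + 1]] <- bin(zs[[k]], "cols", 2L)

  profiles <- vector("list", K + 1)
  # coarsest scale: white streak model
  cal <- calibrate_segments(zs[[K + 1]], model = "streak", cfg = cfg)
  profiles[[K + 1]] <- cal
  y_k <- denoise_segmented(zs[[K + 1]], cal, cfg)
  if (K > 0) {
    for (k in seq(K - 1, 0)) {
      zt <- replace_coarse(zs[[k + 1]], y_k, "cols", 2L, cfg$debin_iters)
      cal <- calibrate_segments(zt, model = "residual", cfg = cfg)
      profiles[[k + 1]] <- cal
      y_k <- denoise_segmented(zt, cal, cfg)
    }
  }
  out <- z + debin(y_k - bin(z, "rows", f_v), "rows", m, f_v, cfg$debin_iters)
  if (return_profile) attr(out, "calibration") <- profiles
  out
}

# Denoise one scale: filter each overlapping full-height segment as a
# separate image with its own calibrated PSD, then recombine the segment
# estimates with the partition-of-unity windows of the profile.
denoise_segmented <- function(zk, cal, cfg) {
  m <- nrow(zk); n <- ncol(zk)
  out <- matrix(0, m, n)
  for (s in seq_len(nrow(cal$segments))) {
    a <- cal$segments$start[s]; b <- cal$segments$end[s]
    seg <- zk[, a:b, drop = FALSE]
    sig <- cal$segments$sigma[s]
    ul <- unit_model_tables(cal$model, m, b - a + 1, cfg)
    est <- if (sig > 0) {
      denoise_core(seg, sig^2 * ul$luts, sig^2 * ul$plut, cfg)
    } else seg
    out[, a:b] <- out[, a:b] + est * matrix(cal$windows[s, a:b], m, b - a + 1,
                                            byrow = TRUE)
  }
  out
}

# unit-level (sigma = 1) covariance tables for a model on a given support,
# cached (they depend only on the model and the segment shape)
unit_model_tables <- function(model, m, n, cfg) {
  key <- sprintf("utab_%s_%d_%d_%d_%d", model, m, n, cfg$block_size,
                 cfg$residual_mc_iters)
  hit <- .sinostrip_cache[[key]]
  if (!is.null(hit)) return(hit)
  psi <- unclass(unit_model_psd(model, m, n, cfg))
  tab <- list(luts = coef_cov_luts(psi, cfg$block_size),
              plut = match_penalty_lut(psi, cfg$block_size))
  .sinostrip_cache[[key]] <- tab
  tab
}

# Unit-level (sigma = 1) model PSD on a given support, cached.
unit_model_psd <- function(model, m, n, cfg) {
  key <- sprintf("upsd_%s_%d_%d_%d", model, m, n, cfg$residual_mc_iters)
  hit <- .sinostrip_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- if (model == "streak") streak_kernel(m, 1)
       else residual_streak_kernel(n, height = m, mc_iters = cfg$residual_mc_iters)
  psi <- psd_from_kernel(g, c(m, n))
  .sinostrip_cache[[key]] <- psi
  psi
}
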