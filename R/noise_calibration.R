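# Self-calibration of the streak noise level: detail filter (vertical
# low-pass Gaussian x horizontal high-pass db3 wavelet), robust MAD
# estimation, and per-segment nonstationary calibration.

# 6-tap Daubechies db3 orthonormal scaling (low-pass) filter.
db3_lowpass <- c(0.3326705529509569, 0.8068915093133388, 0.4598775021193313,
                 -0.13501102001039084, -0.08544127388224149,
                 0.035226291882100656)

# Quadrature-mirror high-pass companion; unit L2 norm, three vanishing
# moments (annihilates polynomials of degree <= 2).
db3_highpass <- function() {
  h <- db3_lowpass
  n <- length(h)
  rev(h) * (-1)^(seq_len(n) - 1)
}

#' Detail filter kernel for streak-noise level estimation
#'
#' Separable kernel `g_d = phi (x) psi`: `phi` is a vertical column Gaussian
#' of length `floor(m_v / 2)` and standard deviation `m_v / 12`, normalized
#' to unit sum (unit vertical gain on vertically constant fields); `psi` is
#' the horizontal 6-tap high-pass Daubechies 'db3' wavelet filter with unit
#' L2 norm. Convolution with `g_d` low-passes vertically and high-passes
#' horizontally, suppressing the signal while passing the streak noise, so
#' the noise level can be read off the filtered field.
#'
#' @param m_v height of the (vertically binned) sinogram; at least 12 so the
#'   Gaussian has at least 6 taps.
#' @return A `correlation_kernel` of size `floor(m_v / 2) x 6`.
#' @export
detail_kernel <- function(m_v) {
  if (m_v < 12) stop("m_v must be at least 12 (Gaussian length m_v/2 >= 6)")
  L <- floor(m_v / 2)
  x <- seq_len(L) - (L + 1) / 2
  phi <- dnorm(x, sd = m_v / 12)
  phi <- phi / sum(phi)
  correlation_kernel(outer(phi, db3_highpass()))
}

#' Robust standard deviation via the median absolute deviation
#'
#' `1.4826 * median(|v - median(v)|)`; the factor calibrates the estimate to
#' the standard deviation of a normal distribution (it is the reciprocal of
#' the 0.75 normal quantile).
#'
#' @param values numeric vector with at least 2 values.
#' @export
mad_std <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("mad_std needs at least 2 values")
  1.4826 * median(abs(values - median(values)))
}

# circular 2-D convolution of an image with a kernel (kernel centered at the
# DFT origin).
conv2_circ <- function(x, g) {
  ifft2(fft2(x) * fft2(embed_kernel(g, dim(x))))
}

# per-pixel std of the detail-filtered unit-level model noise ("gain" of the
# detail filter for the model); exact, via the model PSD and the filter
# transfer function. Cached.
detail_filter_gain <- function(model = c("streak", "residual"), m, n,
                               mc_iters = 2000) {
  model <- match.arg(model)
  key <- sprintf("dgain_%s_%d_%d_%d", model, m, n, mc_iters)
  hit <- .sinostrip_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- if (model == "streak") streak_kernel(m, 1)
       else residual_streak_kernel(n, height = m, mc_iters = mc_iters)
  psi <- unclass(psd_from_kernel(g, c(m, n)))
  Gd <- fft2(embed_kernel(detail_kernel(m), c(m, n)))
  gain <- sqrt(mean(psi * Mod(Gd)^2))
  .sinostrip_cache[[key]] <- gain
  gain
}

#' Estimate the streak noise level of a sinogram at one scale
#'
#' Convolves the input (circularly) with the detail kernel, optionally
#' restricts to a column segment, takes the MAD-based robust standard
#' deviation of the filtered values (excluding border rows/columns affected
#' by circular wraparound), and divides by the detail-filter gain of the
#' scale's noise model: `"streak"` for the coarsest scale (horizontally white
#' streaks) and `"residual"` for finer scales, whose coarse horizontal
#' content has been replaced by the denoised coarser estimate.
#'
#' @param z sinogram at the scale being calibrated (the coarsest-scale input,
#'   or the coarse-replaced input for finer scales).
#' @param model `"streak"` or `"residual"`.
#' @param segment optional integer `c(first, last)` column interval; at least
#'   12 columns.
#' @param mc_iters Monte Carlo iterations for the cached residual kernel.
#' @return Nonnegative scalar estimate of the per-pixel streak noise std.
#' @export
estimate_sigma <- function(z, model = c("streak", "residual"), segment = NULL,
                           mc_iters = 2000) {
  model <- match.arg(model)
  detail_sigma(conv2_circ(z, detail_kernel(nrow(z))), nrow(z), ncol(z),
               model, segment, mc_iters)
}

# MAD-based level estimate on an already detail-filtered field (shared by
# calibrate_segments so the convolution is done once per scale)
detail_sigma <- function(d, m, n, model, segment, mc_iters) {
  rows <- seq_len(m)
  hb <- ceiling(floor(m / 2) / 2)
  if (m - 2 * hb >= 8) rows <- (hb + 1):(m - hb)
  cols <- seq_len(n)
  if (!is.null(segment)) {
    if (segment[2] - segment[1] + 1 < 12) stop("segment narrower than 12 px")
    cols <- segment[1]:segment[2]
  }
  # guard the horizontal wraparound of the 6-tap filter at the image edges
  guard <- 3L
  cols <- cols[cols > guard & cols <= n - guard]
  if (length(cols) < 6) cols <- seq_len(n)
  sig_d <- mad_std(d[rows, cols])
  seg_n <- if (is.null(segment)) n else segment[2] - segment[1] + 1
  sig_d / detail_filter_gain(model, m, max(seg_n, 12L), mc_iters)
}

#' Segmentwise calibration profile of a sinogram scale
#'
#' Splits the width into overlapping full-height segments (width
#' `seg_width`, 50% overlap by default, the last segment clamped to the
#' right edge), estimates the streak noise level on each via
#' [estimate_sigma()], and builds raised-cosine recombination windows
#' normalized to sum to 1 at every column.
#'
#' @param z sinogram at the scale being calibrated.
#' @param model noise model for the scale (see [estimate_sigma()]).
#' @param seg_width segment width in pixels (default 39, the matching
#'   neighborhood width).
#' @param overlap fractional overlap between consecutive segments.
#' @param cfg optional [pipeline_config()] supplying `seg_width`, `overlap`
#'   and `residual_mc_iters`.
#' @return An object of class `calibration_profile`: list with `model`,
#'   `segments` (data.frame `start`, `end`, `sigma`) and `windows`
#'   (`n_segments x width` matrix, columns summing to 1).
#' @export
calibrate_segments <- function(z, model = c("streak", "residual"),
                               seg_width = NULL, overlap = NULL, cfg = NULL) {
  model <- match.arg(model)
  if (is.null(seg_width)) seg_width <- if (!is.null(cfg)) cfg$seg_width else 39L
  if (is.null(overlap)) overlap <- if (!is.null(cfg)) cfg$seg_overlap else 0.5
  mc <- if (!is.null(cfg)) cfg$residual_mc_iters else 2000
  n <- ncol(z)
  w <- min(as.integer(seg_width), n)
  step <- max(1L, as.integer(round(w * (1 - overlap))))
  starts <- seq(1L, max(1L, n - w + 1L), by = step)
  if (starts[length(starts)] != n - w + 1L) starts <- c(starts, n - w + 1L)
  starts <- unique(starts)
  ends <- starts + w - 1L
  m <- nrow(z)
  d <- conv2_circ(z, detail_kernel(m))
  sig <- vapply(seq_along(starts), function(s) {
    seg <- if (w >= 12) c(starts[s], ends[s]) else NULL
    detail_sigma(d, m, n, model, seg, mc)
  }, numeric(1))
  wins <- matrix(0, length(starts), n)
  for (s in seq_along(starts)) {
    t <- seq_len(w)
    wins[s, starts[s]:ends[s]] <- 0.5 - 0.5 * cos(2 * pi * (t - 0.5) / w)
  }
  tot <- colSums(wins)
  wins <- sweep(wins, 2, tot, "/")
  structure(list(model = model,
                 segments = data.frame(start = starts, end = ends, sigma = sig),
                 windows = wins),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf("calibration profile (%s model), %d segments\n",
              x$model, nrow(x$segments)))
  print(x$segments)
  invisible(x)
}
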