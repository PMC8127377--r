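# Synthetic experiment: Shepp-Logan phantom sinogram, mixed streak + Poisson
# corruption, SNR metric, and the benchmark grid.

# Modified Shepp-Logan ellipse parameters over the unit square:
# columns: x-center, y-center, semi-axis a (x), semi-axis b (y),
# rotation (degrees), intensity.
shepp_logan_ellipses <- function() {
  matrix(c(
      0,      0,  0.69,   0.92,    0,  1.0,
      0, -0.0184, 0.6624, 0.8740,  0, -0.8,
    0.22,     0,  0.11,   0.31,  -18, -0.2,
   -0.22,     0,  0.16,   0.41,   18, -0.2,
      0,   0.35,  0.21,   0.25,    0,  0.1,
      0,    0.1,  0.046,  0.046,   0,  0.1,
      0,   -0.1,  0.046,  0.046,   0,  0.1,
   -0.08, -0.605, 0.046,  0.023,   0,  0.1,
      0,  -0.606, 0.023,  0.023,   0,  0.1,
    0.06, -0.605, 0.023,  0.046,   0,  0.1
  ), ncol = 6, byrow = TRUE)
}

# Analytic Radon transform of the ellipse phantom: line integrals at angles
# `theta` (radians) and detector offsets `s` (unit-square coordinates).
radon_ellipses <- function(s, theta, ell = shepp_logan_ellipses()) {
  R <- matrix(0, length(s), length(theta))
  for (e in seq_len(nrow(ell))) {
    x0 <- ell[e, 1]; y0 <- ell[e, 2]
    a <- ell[e, 3]; b <- ell[e, 4]
    phi <- ell[e, 5] * pi / 180; rho <- ell[e, 6]
    for (j in seq_along(theta)) {
      t <- theta[j]
      sp <- s - (x0 * cos(t) + y0 * sin(t))
      g <- t - phi
      d2 <- (a * cos(g))^2 + (b * sin(g))^2
      under <- d2 - sp^2
      m <- under > 0
      R[m, j] <- R[m, j] + rho * 2 * a * b * sqrt(under[m]) / d2
    }
  }
  pmax(R, 0)
}

#' Noise-free Shepp-Logan phantom sinogram
#'
#' Radon transform of the (modified) Shepp-Logan head phantom at `n_angles`
#' one-degree steps with `n_det` detector bins spanning the diagonal of the
#' phantom's bounding square, followed by a sign change and an exponential
#' transformation `exp(-c * R)` turning line integrals into strictly positive
#' transmission-like intensities. With the default `c = 2` (line integrals in
#' unit-square coordinates) the subsequent affine scaling of [corrupt_sinogram()]
#' reproduces the log-domain signal variance underlying the reference noisy
#' SNR values of the benchmark.
#'
#' @param n_det number of detector bins (rows of the output).
#' @param n_angles number of one-degree projection angles (columns).
#' @param c attenuation scaling applied to the line integrals.
#' @return `n_det x n_angles` matrix (displacement x angle), all entries in
#'   `(0, 1]`.
#' @export
shepp_logan_sinogram <- function(n_det = 627L, n_angles = 180L, c = 2) {
  # detector geometry matching a 441x441 pixel raster: bins at unit spacing
  # across the diagonal, phantom unit square mapped to a radius of 220.5 px
  radius <- 220.5 * (n_det / 627)
  s <- (seq_len(n_det) - (n_det + 1) / 2) / radius
  theta <- (seq_len(n_angles) - 1) * pi / 180
  R <- radon_ellipses(s, theta)
  exp(-c * R)
}

#' Corrupt a phantom sinogram with streak and Poisson noise
#'
#' Scales the clean sinogram `A` affinely to the intensity range implied by
#' `peak` (`[peak/2, peak]`; `peak = Inf` uses the high-SNR range
#' `[1280, 2560]` but omits the Poisson component), then applies vertically
#' constant, horizontally white multiplicative streak noise (one Gaussian
#' draw of standard deviation `sigma_streak` per displacement column) and,
#' for finite `peak`, Poisson counting noise. Returns the noisy log-domain
#' sinogram `Z = ln[(1 + eta) A + pi]` together with the streak-free
#' reference `Y = ln[A + pi / (1 + eta)]`, oriented angle (rows) x
#' displacement (columns) so that streaks are vertical and `Z - Y =
#' ln(1 + eta)` is constant down each column.
#'
#' @param A clean sinogram from [shepp_logan_sinogram()] (displacement x
#'   angle).
#' @param sigma_streak streak noise standard deviation (e.g. 0.005-0.05).
#' @param peak `Inf`, or the peak intensity (e.g. 2560 or 1280) setting the
#'   Poisson noise level.
#' @param seed integer seed; the draw is deterministic given it.
#' @param eps clamp for nonpositive noisy intensities before the log.
#' @return List of class `noisy_sinogram_pair` with `Z`, `Y` (angle x
#'   displacement matrices), `A_scaled`, `eta` (per-column streak factors),
#'   and the parameters.
#' @export
corrupt_sinogram <- function(A, sigma_streak, peak = Inf, seed = NULL,
                             eps = 1e-12) {
  stopifnot(sigma_streak >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  scale_peak <- if (is.finite(peak)) peak else 2560
  As <- scale_peak / 2 + (A - min(A)) / (max(A) - min(A)) * (scale_peak / 2)
  As <- t(As)  # angle x displacement: streaks vertical
  n <- ncol(As)
  eta <- rnorm(n, sd = sigma_streak)
  bad <- which(1 + eta <= 0)
  while (length(bad) > 0) {
    warning("redrawing ", length(bad), " streak draw(s) with 1 + eta <= 0")
    eta[bad] <- rnorm(length(bad), sd = sigma_streak)
    bad <- which(1 + eta <= 0)
  }
  E <- matrix(eta, nrow(As), n, byrow = TRUE)
  if (is.finite(peak)) {
    pois <- matrix(rpois(length(As), lambda = As), nrow(As), n) - As
  } else {
    pois <- matrix(0, nrow(As), n)
  }
  Z <- log(pmax((1 + E) * As + pois, eps))
  Y <- log(pmax(As + pois / (1 + E), eps))
  structure(list(Z = Z, Y = Y, A_scaled = As, eta = eta,
                 sigma_streak = sigma_streak, peak = peak, seed = seed),
            class = "noisy_sinogram_pair")
}

#' Signal-to-noise ratio in decibels
#'
#' `10 * log10(svar(Y) / smean((Yhat - Y)^2))` with `svar` the sample
#' variance of the reference and `smean` the mean squared error; `Inf` when
#' the estimate is exact.
#'
#' @param y_hat estimate matrix.
#' @param y reference matrix, same shape.
#' @export
snr_db <- function(y_hat, y) {
  stopifnot(all(dim(y_hat) == dim(y)))
  mse <- mean((y_hat - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(stats::var(as.vector(y)) / mse)
}

#' Phantom SNR benchmark over a grid of noise settings
#'
#' For every combination of `peaks` and `sigmas`, generates `reps` noisy
#' phantom sinogram pairs, runs the full multiscale destreaking pipeline, and
#' reports the average SNR of the noisy input and of the pipeline estimate.
#'
#' @param reps noise realizations per setting.
#' @param sigmas streak noise standard deviations.
#' @param peaks `Inf` and/or finite peak intensities.
#' @param seed base seed; realization `r` of setting `i` uses
#'   `seed + 1000 * i + r`.
#' @param cfg a [pipeline_config()].
#' @param denoise_fn pipeline applied to each noisy sinogram (default
#'   [multiscale_denoise()]); settable for harness experiments.
#' @return data.frame with columns `peak`, `sigma`, `snr_noisy`,
#'   `snr_denoised`, `gain_db`.
#' @export
phantom_benchmark <- function(reps = 10L,
                              sigmas = c(0.005, 0.01, 0.02, 0.05),
                              peaks = c(Inf, 2560, 1280),
                              seed = 1L, cfg = pipeline_config(),
                              denoise_fn = function(z) multiscale_denoise(z, cfg)) {
  A <- shepp_logan_sinogram()
  grid <- expand.grid(sigma = sigmas, peak = peaks)
  out <- data.frame(peak = grid$peak, sigma = grid$sigma,
                    snr_noisy = NA_real_, snr_denoised = NA_real_)
  for (i in seq_len(nrow(grid))) {
    sn <- sd_ <- numeric(reps)
    for (r in seq_len(reps)) {
      pair <- corrupt_sinogram(A, grid$sigma[i], grid$peak[i],
                               seed = seed + 1000L * i + r)
      sn[r] <- snr_db(pair$Z, pair$Y)
      sd_[r] <- snr_db(denoise_fn(pair$Z), pair$Y)
    }
    out$snr_noisy[i] <- mean(sn)
    out$snr_denoised[i] <- mean(sd_)
  }
  out$gain_db <- out$snr_denoised - out$snr_noisy
  out
}
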