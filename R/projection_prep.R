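# Bright-/dark-field normalization, log transform, extreme-streak detection
# and repair, and the end-to-end stack orchestration.

#' Bright-/dark-field normalization and log transform
#'
#' `P_norm = (P_raw - I_D) / (I_B - I_D)`, clamped below at `eps`, followed by
#' the Beer-Lambert log transform `P_log = -ln(P_norm)` (attenuation-positive
#' convention: full transmission maps to 0, transmission `1/e` to unit optical
#' depth). Multiple bright/dark frames (3-D arrays) are averaged first.
#'
#' @param p_raw 3-D array (angle x row x column) of raw projections.
#' @param bright bright-field: 2-D array (row x column), or 3-D stack of
#'   frames to average.
#' @param dark dark-field, same conventions; `NULL` means a zero dark-field.
#' @param eps lower clamp applied to the normalized transmission.
#' @return 3-D array of log-domain projections, same shape as `p_raw`.
#' @export
normalize_and_log <- function(p_raw, bright, dark = NULL, eps = 1e-6) {
  stopifnot(length(dim(p_raw)) == 3)
  avg_field <- function(f) if (length(dim(f)) == 3) apply(f, c(2, 3), mean) else as.matrix(f)
  ib <- avg_field(bright)
  id <- if (is.null(dark)) matrix(0, dim(p_raw)[2], dim(p_raw)[3]) else avg_field(dark)
  if (!all(dim(ib) == dim(p_raw)[2:3]) || !all(dim(id) == dim(ib)))
    stop("bright/dark field shapes inconsistent with projections")
  den <- ib - id
  nbad <- sum(den <= 0)
  if (nbad > 0)
    stop("bright-field does not exceed dark-field at ", nbad, " pixel(s)")
  na <- dim(p_raw)[1]
  out <- p_raw
  nclamped <- 0L
  for (a in seq_len(na)) {
    pn <- (p_raw[a, , ] - id) / den
    nclamped <- nclamped + sum(pn < eps)
    out[a, , ] <- -log(pmax(pn, eps))
  }
  if (nclamped > 0)
    message("normalize_and_log: clamped ", nclamped,
            " nonpositive transmission value(s) at eps = ", eps)
  out
}

#' Median over the angular dimension of a projection stack
#'
#' Per-(row, column) median across angles. Streaks from defective detector
#' pixels, being angle-constant, survive the median and present as pixels
#' extremely brighter or darker than their smooth surroundings.
#'
#' @param p_log 3-D array (angle x row x column).
#' @return 2-D matrix (row x column).
#' @export
angular_median <- function(p_log) {
  stopifnot(length(dim(p_log)) == 3, dim(p_log)[1] >= 1)
  apply(p_log, c(2, 3), median)
}

# bivariate polynomial design matrix (degree <= 3: 10 terms) on scaled window
# coordinates; returned as the orthonormal Q of its QR decomposition.
poly_q <- function(dr, dc, h) {
  x <- dc / max(h, 1); y <- dr / max(h, 1)
  X <- cbind(1, x, y, x^2, x * y, y^2, x^3, x^2 * y, x * y^2, y^3)
  qr.Q(qr(X))
}

#' Detect defective detector pixels causing extreme streaks
#'
#' For every pixel of the angular-median map, a bivariate cubic polynomial is
#' fit by least squares over a centered window (clamped at the borders); the
#' pixel is marked defective when its fit residual exceeds `c_sigma` times
#' the sample standard deviation of the window residuals.
#'
#' @param m 2-D angular-median map (row x column).
#' @param window odd window side (default 19).
#' @param c_sigma detection threshold in residual standard deviations
#'   (default 5: only extreme outliers, consistent with Gaussian modeling of
#'   ordinary streak noise).
#' @return Logical matrix of defective pixels (a `defect_mask`).
#' @export
detect_defective <- function(m, window = 19L, c_sigma = 5.0) {
  stopifnot(is.matrix(m), window %% 2 == 1)
  nr <- nrow(m); nc <- ncol(m)
  h <- (window - 1L) %/% 2L
  mask <- matrix(FALSE, nr, nc)
  qcache <- new.env(parent = emptyenv())
  for (r in seq_len(nr)) {
    r0 <- max(1L, r - h); r1 <- min(nr, r + h)
    for (c in seq_len(nc)) {
      c0 <- max(1L, c - h); c1 <- min(nc, c + h)
      npix <- (r1 - r0 + 1L) * (c1 - c0 + 1L)
      if (npix < 20L) next  # fewer than 2x the cubic terms: skip
      key <- paste(r - r0, r1 - r, c - c0, c1 - c, sep = "_")
      Q <- qcache[[key]]
      if (is.null(Q)) {
        dr <- rep(r0:r1 - r, times = c1 - c0 + 1L)
        dc <- rep(c0:c1 - c, each = r1 - r0 + 1L)
        Q <- poly_q(dr, dc, h)
        qcache[[key]] <- Q
      }
      w <- as.vector(m[r0:r1, c0:c1])
      res <- w - Q %*% crossprod(Q, w)
      ic <- (c - c0) * (r1 - r0 + 1L) + (r - r0 + 1L)
      s <- sd(res)
      # ignore residuals at numerical-rounding scale (exactly polynomial data)
      floor_s <- 1e-8 * max(abs(w), 1e-300)
      if (is.finite(s) && s > floor_s && abs(res[ic]) > c_sigma * s)
        mask[r, c] <- TRUE
    }
  }
  structure(mask, class = c("defect_mask", "matrix"))
}

#' Repair defective sinogram columns
#'
#' Per angle, each defective pixel is replaced by the median of the
#' non-defective pixels inside a square window in the detector (row, column)
#' plane around it; the window (default 5x5) grows until at least
#' `min_valid` non-defective pixels are available. Repaired columns may still
#' carry residual streak noise -- the aim is only to bring extreme values
#' back into the range the collaborative filter can handle.
#'
#' @param p_log 3-D array (angle x row x column).
#' @param mask logical (row x column) defective-pixel mask.
#' @param window initial window side (odd).
#' @param min_valid minimum number of non-defective pixels in the window.
#' @export
repair_columns <- function(p_log, mask, window = 5L, min_valid = 3L) {
  stopifnot(length(dim(p_log)) == 3, all(dim(mask) == dim(p_log)[2:3]))
  if (!any(mask)) return(p_log)
  nr <- nrow(mask); nc <- ncol(mask)
  bad <- which(mask, arr.ind = TRUE)
  na <- dim(p_log)[1]
  out <- p_log
  for (b in seq_len(nrow(bad))) {
    r <- bad[b, 1]; c <- bad[b, 2]
    h <- (window - 1L) %/% 2L
    repeat {
      r0 <- max(1L, r - h); r1 <- min(nr, r + h)
      c0 <- max(1L, c - h); c1 <- min(nc, c + h)
      ok <- !mask[r0:r1, c0:c1, drop = FALSE]
      if (sum(ok) >= min_valid) break
      if (r0 == 1L && r1 == nr && c0 == 1L && c1 == nc)
        stop("repair window exhausted the image without finding ",
             min_valid, " valid pixels")
      h <- h + 1L
    }
    for (a in seq_len(na)) {
      win <- p_log[a, r0:r1, c0:c1, drop = FALSE]
      out[a, r, c] <- median(win[ok])
    }
  }
  out
}

#' Full streak-attenuation pipeline for a projection stack
#'
#' Normalizes and log-transforms the raw projections, detects and repairs
#' extreme streaks from defective detector pixels, then destreaks every
#' sinogram (one per detector row, oriented angle x column so streaks are
#' vertical) with the self-calibrated multiscale collaborative filter. Fully
#' automatic; the output stays in the log domain.
#'
#' @param p_raw 3-D array (angle x row x column) of raw projections.
#' @param bright,dark bright-/dark-field (see [normalize_and_log()]).
#' @param cfg a [pipeline_config()].
#' @return 3-D array of destreaked log-domain projections; attribute
#'   `"defect_mask"` carries the detected defective-pixel mask.
#' @export
destreak_stack <- function(p_raw, bright, dark = NULL, cfg = pipeline_config()) {
  p_log <- normalize_and_log(p_raw, bright, dark, cfg$eps)
  med <- angular_median(p_log)
  mask <- detect_defective(med, cfg$detect_window, cfg$c_sigma)
  p_log <- repair_columns(p_log, mask, cfg$repair_window)
  out <- p_log
  for (r in seq_len(dim(p_log)[2])) {
    out[, r, ] <- multiscale_denoise(p_log[, r, , drop = TRUE], cfg)
  }
  attr(out, "defect_mask") <- mask
  out
}
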