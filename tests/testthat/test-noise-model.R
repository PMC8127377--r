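# Correlated-noise model: kernels, PSDs, synthesis, transform-domain
# variances.

test_that("psd_from_kernel matches the definition and handles edge cases", {
  # unit impulse -> flat spectrum at ||g||^2
  psi <- psd_from_kernel(correlation_kernel(matrix(2)), c(6, 7))
  expect_equal(unclass(psi), matrix(4, 6, 7))

  # full-height constant column kernel -> energy only on the zero vertical
  # frequency row
  psi <- psd_from_kernel(streak_kernel(8, 1), c(8, 10))
  expect_equal(psi[1, ], rep(8, 10))
  expect_equal(max(abs(psi[-1, ])), 0)

  # random 3x3 kernel on 8x8 support vs brute-force double-sum DFT
  set.seed(101)
  g <- correlation_kernel(matrix(rnorm(9), 3))
  psi <- psd_from_kernel(g, c(8, 8))
  emb <- sinostrip:::embed_kernel(g, c(8, 8))
  expect_equal(unclass(psi), Mod(brute_dft2(emb))^2, tolerance = 1e-12)

  expect_error(psd_from_kernel(streak_kernel(16, 1), c(8, 8)), "exceeds")
})

test_that("kernel_from_psd inverts psd_from_kernel on valid spectra", {
  # flat spectrum -> impulse kernel
  g <- kernel_from_psd(matrix(4, 8, 8))
  expect_equal(g[1, 1], 2)
  expect_equal(sum(abs(g)) - abs(g[1, 1]), 0, tolerance = 1e-12)

  # spectrum on the zero-vertical-frequency row only -> vertically constant
  v <- runif(5)
  psi <- matrix(0, 8, 8); psi[1, ] <- c(v, v[4], v[3], v[2])  # symmetric row
  g <- kernel_from_psd(psi)
  expect_lt(max(abs(sweep(g, 2, g[1, ]))), 1e-12)

  # round trip on random symmetric nonnegative spectra
  set.seed(7)
  for (rep in 1:3) {
    psi <- random_psd(16, 16)
    psi2 <- psd_from_kernel(kernel_from_psd(psi), c(16, 16))
    expect_lt(max(abs(psi2 - psi)) / max(psi), 1e-8)
  }

  expect_error(kernel_from_psd(matrix(-1, 4, 4)), "nonnegative")
})

test_that("generate_noise is seeded, structured, and at the right level", {
  imp <- correlation_kernel(matrix(1))
  a <- generate_noise(imp, c(16, 16), seed = 5)
  b <- generate_noise(imp, c(16, 16), seed = 5)
  expect_identical(a, b)                      # determinism
  set.seed(5)
  expect_equal(a, matrix(rnorm(256), 16, 16), tolerance = 1e-12)  # impulse = raw draw

  # streak kernel: vertically constant columns; empirical std near ||g||_2
  g <- streak_kernel(64, 0.5)
  vals <- numeric(0)
  for (s in 1:500) {
    eta <- generate_noise(g, c(64, 64), seed = 1000 + s)
    expect_lt(max(abs(sweep(eta, 2, eta[1, ]))), 1e-10)
    vals <- c(vals, eta[1, ])
  }
  se <- 0.5 / sqrt(2 * length(vals))
  expect_lt(abs(sd(vals) - 0.5), 3 * se)
})

test_that("streak_kernel normalization", {
  g <- streak_kernel(8, 1)
  expect_equal(dim(g), c(8L, 1L))
  expect_equal(unique(as.vector(g)), 1 / sqrt(8))
  expect_equal(kernel_std(streak_kernel(10, 0.25)), 0.25)
  expect_equal(sum(abs(streak_kernel(8, 0))), 0)
  # scale-k level: variance doubles per horizontal binning, 2^(k/2) in std
  expect_equal(kernel_std(streak_kernel(8, 2^(2 / 2) * 0.005)), 0.010)
})

test_that("residual_streak_kernel matches the dense linear-operator oracle", {
  w <- 16L
  iters <- 20000L
  g <- residual_streak_kernel(w, height = 1, mc_iters = iters, seed = 99)
  expect_equal(kernel_std(g), 1, tolerance = 1e-12)

  # exact per-frequency std: propagate L = I - debin o bin through identity
  # covariance, diagonal of F L L' F^H
  L <- matrix(0, w, w)
  for (k in seq_len(w)) {
    e <- numeric(w); e[k] <- 1
    L[, k] <- e - debin(bin(matrix(e, 1), "cols", 2), "cols", w)[1, ]
  }
  Fm <- exp(-2i * pi * outer(0:(w - 1), 0:(w - 1)) / w)
  exact <- sqrt(Re(diag(Fm %*% L %*% t(L) %*% Conj(t(Fm)))))
  mc <- Mod(stats::fft(as.vector(g)))     # kernel spectrum, proportional
  scale <- sum(exact * mc) / sum(mc^2)
  rel_se <- 3 / sqrt(2 * iters)
  nz <- exact > 1e-3 * max(exact)
  expect_lt(max(abs(scale * mc[nz] - exact[nz]) / exact[nz]), 5 * rel_se + 0.01)

  # missing low frequencies: DC of the residual spectrum is ~0
  expect_lt(mc[1], 0.02 * max(mc))
  expect_error(residual_streak_kernel(16, mc_iters = 1), "mc_iters")
})

test_that("group_variances agrees with the dense covariance oracle", {
  set.seed(21)
  t2d <- dct_matrix(4)
  for (rep in 1:2) {
    g <- correlation_kernel(matrix(rnorm(6), 2, 3))
    psi <- unclass(psd_from_kernel(g, c(12, 14)))
    pos <- rbind(c(2, 3), c(5, 9), c(8, 2), c(2, 10))
    geom <- group_geometry(4, pos, c(12, 14))
    t1d <- haar_matrix(4)
    vo <- oracle_group_variances(psi, 4, pos, c(12, 14), t2d, t1d)
    vd <- group_variances(psi, geom, t2d, t1d, method = "dense")
    vs <- group_variances(psi, geom, t2d, t1d, method = "spectral")
    expect_lt(max(abs(vd - vo)) / max(vo), 1e-6)
    expect_lt(max(abs(vs - vo)) / max(vo), 1e-6)
  }

  # white noise, disjoint blocks: all variances equal the pixel variance
  geom <- group_geometry(4, rbind(c(1, 1), c(5, 5), c(9, 9), c(1, 9)), c(12, 14))
  vw <- group_variances(matrix(2.5, 12, 14), geom)
  expect_equal(as.vector(vw), rep(2.5, 64), tolerance = 1e-10)

  # M = 1: DC variance equals the mean autocovariance over intra-block offsets
  g <- correlation_kernel(matrix(rnorm(4), 2, 2))
  psi <- unclass(psd_from_kernel(g, c(8, 8)))
  geom1 <- group_geometry(4, matrix(c(3, 3), 1), c(8, 8))
  v1 <- group_variances(psi, geom1, t1d = matrix(1, 1, 1))
  r <- brute_autocov(psi)
  dc <- 0
  for (p in 0:3) for (q in 0:3) for (pp in 0:3) for (qq in 0:3)
    dc <- dc + r[((p - pp) %% 8) + 1, ((q - qq) %% 8) + 1]
  expect_equal(v1[1, 1], dc / 16, tolerance = 1e-10)

  # duplicated positions: the 2-point difference coefficient has variance 0
  geom2 <- group_geometry(4, rbind(c(2, 2), c(2, 2)), c(8, 8))
  v2 <- group_variances(psi, geom2, t1d = haar_matrix(2))
  expect_lt(max(v2[, 2]), 1e-12)

  expect_error(group_variances(matrix(1, 4, 4), geom1), "does not match")
})

test_that("empirical 3-D spectrum variances match group_variances", {
  set.seed(31)
  g <- correlation_kernel(matrix(rnorm(9) / 2, 3, 3))
  psi <- unclass(psd_from_kernel(g, c(16, 16)))
  pos <- rbind(c(2, 2), c(6, 10), c(11, 5), c(12, 12))
  geom <- group_geometry(4, pos, c(16, 16))
  t2d <- dct_matrix(4); t1d <- haar_matrix(4)
  vref <- group_variances(psi, geom, t2d, t1d)
  nrep <- 2000
  acc <- matrix(0, 16, 4)
  for (it in seq_len(nrep)) {
    eta <- generate_noise(g, c(16, 16), seed = 40000 + it)
    blocks <- array(0, c(4, 4, 4))
    for (m in 1:4) blocks[, , m] <- eta[pos[m, 1] + 0:3, pos[m, 2] + 0:3]
    acc <- acc + matrix(group_transform(blocks, t2d, t1d, "forward"), 16, 4)^2
  }
  emp <- acc / nrep
  se <- vref * sqrt(2 / nrep)    # var of a sample variance of a normal
  expect_true(all(abs(emp - vref) <= 3 * se + 1e-12))
})

test_that("block_difference_variances: limits and dense-oracle agreement", {
  # zero offset: identical noise cancels exactly
  psi <- unclass(psd_from_kernel(streak_kernel(16, 0.3), c(16, 20)))
  expect_equal(max(block_difference_variances(psi, 4, c(0, 0))), 0)

  # white noise, disjoint blocks: variance 2 sigma^2 in every coefficient
  vw <- block_difference_variances(matrix(1.5, 16, 20), 4, c(0, 8))
  expect_equal(as.vector(vw), rep(3, 16), tolerance = 1e-10)

  # streak noise: vertical offset cancels, horizontal offset decorrelates
  vvert <- block_difference_variances(psi, 4, c(7, 0))
  vhor <- block_difference_variances(psi, 4, c(0, 7))
  single <- group_variances(psi, group_geometry(4, matrix(c(1, 1), 1), c(16, 20)),
                            t1d = matrix(1, 1, 1))
  expect_lt(max(vvert), 1e-10)
  expect_equal(as.vector(vhor), 2 * single[, 1], tolerance = 1e-8)

  # dense-oracle route: block-pair difference via a 2-block group with the
  # 2-point Haar (difference coefficient variance x 2)
  set.seed(13)
  g <- correlation_kernel(matrix(rnorm(4), 2, 2))
  psir <- unclass(psd_from_kernel(g, c(12, 12)))
  d <- c(3, 5)
  vd <- block_difference_variances(psir, 4, d)
  vo <- oracle_group_variances(psir, 4, rbind(c(2, 2), c(2 + d[1], 2 + d[2])),
                               c(12, 12), dct_matrix(4), haar_matrix(2))
  expect_equal(as.vector(vd), 2 * vo[, 2], tolerance = 1e-8)
})
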