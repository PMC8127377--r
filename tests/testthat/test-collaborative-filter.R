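# Two-stage collaborative filter: transforms, shrinkage, matching,
# aggregation, and the full denoiser.

test_that("group_transform: identity, energy compaction, brute tensor oracle", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  sp <- group_transform(x, direction = "forward")
  xi <- group_transform(sp, direction = "inverse")
  expect_lt(max(abs(xi - x)), 1e-10)

  # constant group: all energy in the (DC, first 1-D basis) coefficient
  cst <- array(3, c(8, 8, 4))
  sp <- group_transform(cst, direction = "forward")
  expect_equal(sp[1, 1, 1], 3 * 8 * 2)     # 3 * sqrt(64) * sqrt(4)
  expect_lt(sum(sp^2) - sp[1, 1, 1]^2, 1e-18)

  # explicit basis double-sum on 2x2 blocks, M = 2
  y <- array(rnorm(8), c(2, 2, 2))
  t2d <- dct_matrix(2); t1d <- haar_matrix(2)
  sp <- group_transform(y, t2d, t1d, "forward")
  for (p in 1:2) for (q in 1:2) for (j in 1:2) {
    s <- 0
    for (u in 1:2) for (v in 1:2) for (m in 1:2)
      s <- s + t2d[p, u] * t2d[q, v] * t1d[j, m] * y[u, v, m]
    expect_equal(sp[p, q, j], s, tolerance = 1e-12)
  }

  expect_error(group_transform(array(0, c(2, 2, 3)), t2d, t1d, "forward"),
               "does not match")
})

test_that("hard_threshold keeps exactly the right coefficients", {
  expect_equal(hard_threshold(matrix(2.0), matrix(1.0), 2.7)$spectrum[1], 2.0)  # DC kept
  sp <- matrix(c(5, 2.0, 3.0, -3.0), 2)
  res <- hard_threshold(sp, matrix(1, 2, 2), 2.7)
  expect_equal(res$spectrum, matrix(c(5, 0, 3, -3), 2))
  expect_equal(res$n_retained, 3)

  # zero variances: nothing thresholded
  res <- hard_threshold(sp, matrix(0, 2, 2), 2.7)
  expect_equal(res$spectrum, sp)
  expect_equal(res$n_retained, 4)

  # loop oracle on a random spectrum + energy never increases
  set.seed(4)
  sp <- matrix(rnorm(64 * 8), 64, 8)
  vv <- matrix(rexp(64 * 8), 64, 8)
  res <- hard_threshold(sp, vv, 2.0)
  nref <- 0
  for (i in seq_along(sp)) {
    keep <- i == 1 || abs(sp[i]) >= 2.0 * sqrt(vv[i])
    nref <- nref + keep
    expect_equal(res$spectrum[i], if (keep) sp[i] else 0)
  }
  expect_equal(res$n_retained, nref)
  expect_lte(sum(res$spectrum^2), sum(sp^2))
})

test_that("wiener_attenuation algebra", {
  expect_equal(wiener_attenuation(0, 2), 0)
  expect_equal(wiener_attenuation(3, 0), 1)
  expect_equal(wiener_attenuation(2, 4, mu2 = 1), 0.5)   # p^2 = mu2 * var
  a <- wiener_attenuation(matrix(rnorm(20), 4), matrix(rexp(20), 4))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("aggregation weights and coverage behave as specified", {
  geom <- group_geometry(4, rbind(c(1, 1), c(1, 5), c(5, 1), c(5, 5)), c(8, 8))
  est <- array(rnorm(64), c(4, 4, 4))
  out <- aggregate_groups(list(list(geometry = geom, estimates = est, weight = 1)),
                          c(8, 8))
  expect_equal(out[1:4, 1:4], est[, , 1])    # single cover: verbatim blocks
  expect_equal(out[5:8, 5:8], est[, , 4])

  # overlapping groups all estimating the same constant preserve it exactly
  g1 <- group_geometry(4, rbind(c(1, 1), c(1, 5), c(5, 1), c(5, 5), c(3, 3)),
                       c(8, 8))
  cst <- array(7, c(4, 4, 5))
  out <- aggregate_groups(list(list(geometry = g1, estimates = cst, weight = 0.2),
                               list(geometry = g1, estimates = cst, weight = 5)),
                          c(8, 8))
  expect_equal(unique(round(as.vector(out), 12)), 7)

  # low-residual-variance group dominates the average
  gA <- group_geometry(4, matrix(c(1, 1), 1), c(4, 4))
  est0 <- array(0, c(4, 4, 1)); est1 <- array(1, c(4, 4, 1))
  out <- aggregate_groups(list(list(geometry = gA, estimates = est0, weight = 10),
                               list(geometry = gA, estimates = est1, weight = 1)),
                          c(4, 4))
  expect_equal(out[1, 1], 1 / 11, tolerance = 1e-12)

  expect_error(aggregate_groups(list(list(geometry = gA, estimates = est0,
                                          weight = 1)), c(8, 8)),
               "uncovered")
})

test_that("match_blocks honors its contract and finds duplicates", {
  set.seed(6)
  img <- matrix(rnorm(40 * 40), 40, 40)
  img[21:28, 21:28] <- img[3:10, 3:10]   # exact duplicate of the reference
  psi <- matrix(0, 40, 40)
  cfg <- filter_config(max_group = 8)
  geom <- match_blocks(img, c(3, 3), psi, cfg, stage = 2)
  d <- attr(geom, "distances")
  M <- nrow(geom$positions)
  expect_equal(M, 8)
  expect_true(bitwAnd(M, M - 1L) == 0)
  expect_false(is.unsorted(d))
  expect_true(any(geom$positions[, 1] == 3 & geom$positions[, 2] == 3))
  expect_true(any(geom$positions[, 1] == 21 & geom$positions[, 2] == 21))
  expect_lt(d[2], 1e-12)   # the duplicate matches exactly
})

test_that("correlation penalty steers matching off the streaks", {
  # on pure streak noise, uncompensated matching rides the streaks (tiny
  # horizontal offsets); the gamma penalty promotes horizontal matches
  g <- streak_kernel(48, 0.2)
  psi <- psd_from_kernel(g, c(48, 48))
  cfg0 <- filter_config(gamma = 0)
  cfg3 <- filter_config(gamma = 3)
  mh0 <- mh3 <- numeric(0)
  for (s in 1:60) {
    eta <- generate_noise(g, c(48, 48), seed = 700 + s)
    g0 <- match_blocks(eta, c(20, 20), psi, cfg0, stage = 1)
    g3 <- match_blocks(eta, c(20, 20), psi, cfg3, stage = 1)
    mh0 <- c(mh0, mean(abs(g0$positions[, 2] - 20)))
    mh3 <- c(mh3, mean(abs(g3$positions[, 2] - 20)))
  }
  expect_lt(mean(mh0), mean(mh3))
})

test_that("denoise: exactness, determinism, and shrinkage limits", {
  set.seed(8)
  z <- matrix(rnorm(24 * 30), 24, 30)
  cfg <- filter_config()

  # zero PSD: filter is the identity (everything kept, alpha = 1)
  expect_lt(max(abs(denoise(z, matrix(0, 24, 30), cfg) - z)), 1e-12)

  # lambda = 0 disables the stage-1 threshold entirely
  psi <- matrix(0.5, 24, 30)
  y1 <- denoise(z, psi, filter_config(lambda = 0), stages = 1)
  expect_lt(max(abs(y1 - z)), 1e-10)

  # determinism: identical inputs give bit-identical output
  e1 <- denoise(z, psi, cfg)
  e2 <- denoise(z, psi, cfg)
  expect_identical(e1, e2)

  expect_error(denoise(matrix(0, 4, 4), matrix(0, 4, 4), cfg), "smaller")
})

test_that("denoise strongly attenuates white noise on a constant image", {
  cfg <- filter_config()
  y <- matrix(5, 64, 64)
  ratios <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    z <- y + matrix(rnorm(64 * 64, sd = 0.1), 64, 64)
    est <- denoise(z, matrix(0.01, 64, 64), cfg)
    ratios[s] <- mean((est - y)^2) / mean((z - y)^2)
  }
  expect_lt(mean(ratios), 0.1)
})

test_that("denoise attenuates streak noise on structured images", {
  x <- outer(1:48, 1:72, function(i, j) sin(i / 6) + 0.5 * cos(j / 9))
  g <- streak_kernel(48, 0.3)
  psi <- psd_from_kernel(g, c(48, 72))
  eta <- generate_noise(g, c(48, 72), seed = 12)
  est <- denoise(x + eta, psi, filter_config())
  expect_lt(mean((est - x)^2), 0.5 * mean(eta^2))
})

test_that("denoise is shift-consistent away from the borders", {
  # a vertical circular shift by one grid step changes the filter only near
  # the top/bottom borders, where window clamping reshuffles the candidate
  # sets; the effect propagates one search radius per stage (the Wiener
  # stage matches on the stage-1 pilot), so rows further than about
  # 2 * (search/2 + block) + shift from either border reproduce exactly
  set.seed(9)
  x <- outer(1:160, 1:80, function(i, j) cos(i / 7) * sin(j / 9))
  g <- streak_kernel(160, 0.15)
  psi <- psd_from_kernel(g, c(160, 80))
  z <- x + generate_noise(g, c(160, 80), seed = 77)
  cfg <- filter_config()
  e <- denoise(z, psi, cfg)
  zs <- rbind(z[4:160, ], z[1:3, ])         # circular shift by one step unit
  es <- denoise(zs, psi, cfg)
  eu <- rbind(es[158:160, ], es[1:157, ])   # unshift
  interior <- 60:100
  expect_lt(max(abs(e[interior, ] - eu[interior, ])), 1e-9)
})
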