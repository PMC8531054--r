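# Correlation surfaces: closed-form cases, FFT vs direct-space oracle,
# structural invariants, checkerboard downsampling.

test_that("closed-form autocorrelations come out exactly", {
  # constant image: zero variance, G identically 0
  g <- acf2d(quics_image(matrix(7, 16, 16), 20), boundary = "circular")
  expect_equal(max(abs(g$values)), 0)

  # single hot pixel on an n-pixel field: G(0,0) = n - 1, G(lag != 0) = -1
  m <- matrix(0, 8, 8); m[3, 5] <- 11
  g <- acf2d(quics_image(m, 20), boundary = "circular")
  expect_equal(corr_at(g, 0, 0), 63)
  expect_equal(corr_at(g, 1, 0), -1)
  expect_equal(corr_at(g, -2, 3), -1)

  # 1-pixel checkerboard of {0, 2}: mean 1, variance 1, anti-correlated
  # nearest neighbours
  cb <- outer(1:8, 1:8, function(i, j) 2 * ((i + j) %% 2))
  g <- acf2d(quics_image(cb, 20), boundary = "circular")
  expect_equal(corr_at(g, 0, 0), 1)
  expect_equal(corr_at(g, 1, 0), -1)
  expect_equal(corr_at(g, 0, 1), -1)
})

test_that("FFT correlation equals the direct-space oracle", {
  masks <- list(NULL, blob_mask(14, 18, radius = 6))
  for (seed in 1:2) {
    img <- random_image(14, 18, seed = seed)
    for (mk in masks) {
      for (bnd in c("circular", "padded")) {
        g <- acf2d(img, mk, boundary = bnd)
        oracle <- direct_corr(img$pixels,
                              mask = if (is.null(mk)) NULL else mk$include,
                              boundary = bnd)
        for (lag in list(c(0, 0), c(1, 0), c(0, 1), c(2, 3), c(-3, 1),
                         c(5, -4), c(-6, -6))) {
          expect_equal(corr_at(g, lag[1], lag[2]),
                       oracle(lag[1], lag[2]), tolerance = 1e-10,
                       info = sprintf("seed %d %s mask=%s lag (%d,%d)",
                                      seed, bnd, !is.null(mk),
                                      lag[1], lag[2]))
        }
      }
    }
  }
})

test_that("autocorrelation surfaces are point symmetric and bounded below", {
  for (seed in 1:3) {
    img <- random_image(16, seed = seed)
    for (bnd in c("circular", "padded")) {
      g <- acf2d(img, boundary = bnd)
      zl <- g$zero_lag_index
      for (lag in list(c(1, 2), c(3, -4), c(0, 5), c(6, 6))) {
        expect_equal(corr_at(g, lag[1], lag[2]),
                     corr_at(g, -lag[1], -lag[2]), tolerance = 1e-9)
      }
      expect_gte(g$values[zl[1], zl[2]], 0)
      expect_true(all(g$values >= -1 - 1e-12, na.rm = TRUE))
    }
  }
})

test_that("zero lag equals population variance over squared mean", {
  img <- random_image(20, seed = 9)
  mk <- blob_mask(20, radius = 8)
  for (bnd in c("circular", "padded")) {
    g <- acf2d(img, mk, boundary = bnd)
    v <- img$pixels[mk$include]
    expected <- mean((v - mean(v))^2) / mean(v)^2
    expect_equal(corr_at(g, 0, 0), expected, tolerance = 1e-10)
  }
})

test_that("padded masked ACF is invariant to embedding in a larger canvas", {
  img <- random_image(16, seed = 5)
  mk <- blob_mask(16, radius = 6)
  big_px <- matrix(0, 32, 32); big_px[9:24, 9:24] <- img$pixels
  big_mk <- matrix(FALSE, 32, 32); big_mk[9:24, 9:24] <- mk$include
  g_small <- acf2d(img, mk, boundary = "padded")
  g_big <- acf2d(quics_image(big_px, 20), quics_mask(big_mk),
                 boundary = "padded")
  for (lag in list(c(0, 0), c(1, 0), c(2, 2), c(-3, 4), c(5, 5))) {
    expect_equal(corr_at(g_big, lag[1], lag[2]),
                 corr_at(g_small, lag[1], lag[2]), tolerance = 1e-10)
  }
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(acf2d(quics_image(matrix(0, 8, 8), 20)), "degenerate")
  expect_error(quics_mask(matrix(FALSE, 8, 8)), "mask too small")
  expect_error(quics_image(matrix(1, 4, 4), 20), "8x8")
  img_a <- random_image(16, seed = 1)
  img_b <- random_image(18, seed = 2)
  expect_error(ccf2d(img_a, img_b), "identical shapes")
})

test_that("downsample_pair follows the checkerboard parity rule", {
  # constant image: both halves constant
  dp <- downsample_pair(quics_image(matrix(3, 8, 8), 20))
  expect_equal(unique(as.vector(dp$even$pixels)), 3)
  expect_equal(unique(as.vector(dp$odd$pixels)), 3)

  # deterministic 8x8: hand-applied block parity averages
  px <- matrix(seq_len(64), 8, 8)
  dp <- downsample_pair(quics_image(px, 20))
  for (a in 1:4) {
    for (b in 1:4) {
      even_expect <- (px[2 * a - 1, 2 * b - 1] + px[2 * a, 2 * b]) / 2
      odd_expect <- (px[2 * a - 1, 2 * b] + px[2 * a, 2 * b - 1]) / 2
      expect_equal(dp$even$pixels[2 * a - 1, 2 * b - 1], even_expect)
      expect_equal(dp$even$pixels[2 * a, 2 * b], even_expect)  # replicated
      expect_equal(dp$odd$pixels[2 * a - 1, 2 * b - 1], odd_expect)
    }
  }

  # odd dimensions: cropped with a warning
  expect_warning(downsample_pair(quics_image(matrix(1:81, 9, 9) + 0, 20)),
                 "cropping")
})

test_that("parity halves carry statistically independent noise", {
  # signal + iid noise: the noise parts of the two halves are uncorrelated
  set.seed(42)
  cors <- replicate(40, {
    signal <- matrix(100, 32, 32)
    noisy <- signal + matrix(rnorm(32 * 32, 0, 10), 32)
    dp <- downsample_pair(quics_image(noisy, 20))
    half <- function(im) im$pixels[seq(1, 32, 2), seq(1, 32, 2)]
    cor(as.vector(half(dp$even)) - 100, as.vector(half(dp$odd)) - 100)
  })
  expect_lt(abs(mean(cors)), 0.02)
})

test_that("cross-correlation agrees with the autocorrelation for equal inputs", {
  img <- random_image(16, seed = 11)
  for (bnd in c("circular", "padded")) {
    ga <- acf2d(img, boundary = bnd)
    gc <- ccf2d(img, img, boundary = bnd)
    expect_equal(gc$values, ga$values, tolerance = 1e-12)
    expect_identical(gc$kind, "cross")
  }
  # constant x anything: zero covariance at every cyclic lag (under padding
  # the long-lag windows see different sub-means, so only circular is exact)
  gc <- ccf2d(quics_image(matrix(4, 16, 16), 20), img,
              boundary = "circular")
  expect_equal(max(abs(gc$values), na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(corr_at(ccf2d(quics_image(matrix(4, 16, 16), 20), img), 0, 0),
               0, tolerance = 1e-12)
})

test_that("radial binning matches cell-by-cell enumeration", {
  img <- random_image(16, seed = 13)
  g <- acf2d(img, boundary = "padded")
  rp <- radial_profile(g, max_lag = 5)
  for (k in 0:5) {
    cells <- direct_radial_bin(g, k)
    row <- rp[rp$rho == k, ]
    expect_equal(row$g, mean(cells), tolerance = 1e-12)
    expect_equal(row$n_pairs, length(cells))
  }
  # bin 0 is exactly the zero-lag cell; bin 1 holds the 4 axis cells plus
  # the 4 diagonal cells (sqrt(2) rounds to 1)
  expect_identical(rp$n_pairs[rp$rho == 0], 1L)
  expect_identical(rp$n_pairs[rp$rho == 1], 8L)
  expect_equal(rp$g[rp$rho == 0], corr_at(g, 0, 0))
  expect_true(all(diff(rp$rho) > 0) && rp$rho[1] == 0)
})

test_that("radial profile reproduces a radially symmetric surface", {
  img <- random_image(32, seed = 1)
  g <- acf2d(img, boundary = "circular")
  zl <- g$zero_lag_index
  d <- dim(g$values)
  f <- function(r) exp(-r^2 / 36)
  rr <- sqrt(outer((seq_len(d[1]) - zl[1])^2, (seq_len(d[2]) - zl[2])^2, "+"))
  g$values <- f(rr)
  rp <- radial_profile(g, max_lag = 10)
  # at integer radii the axis cells are exact; binning mixes nearby radii,
  # so compare loosely away from zero and exactly at zero
  expect_equal(rp$g[rp$rho == 0], 1)
  expect_equal(rp$g[rp$rho == 6], f(6), tolerance = 0.15)
  # on-axis integer radii are represented exactly among the bin's cells
  expect_equal(corr_at(g, 6, 0), f(6))
})
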