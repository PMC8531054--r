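# Independent brute-force oracles, deliberately O(N^4) direct-space, used to
# validate the FFT implementations on small images.

# Direct evaluation of the normalized correlation
#   G(dx, dy) = <A(x, y) B(x + dx, y + dy)> / (<A><B>) - 1
# with averages over in-mask pixels. `boundary = "circular"` wraps indices;
# "padded" keeps only pairs with both pixels in bounds (and in mask).
# Returns a function of (dx, dy).
direct_corr <- function(a, b = a, mask = NULL, boundary = "padded") {
  n1 <- nrow(a); n2 <- ncol(a)
  if (is.null(mask)) mask <- matrix(TRUE, n1, n2)
  mu_a <- mean(a[mask]); mu_b <- mean(b[mask])
  function(dx, dy) {
    s <- 0; cnt <- 0L
    for (i in seq_len(n1)) {
      for (j in seq_len(n2)) {
        if (!mask[i, j]) next
        if (boundary == "circular") {
          ii <- (i - 1 + dx) %% n1 + 1
          jj <- (j - 1 + dy) %% n2 + 1
        } else {
          ii <- i + dx; jj <- j + dy
          if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
        }
        if (!mask[ii, jj]) next
        s <- s + a[i, j] * b[ii, jj]
        cnt <- cnt + 1L
      }
    }
    if (cnt == 0L) return(NA_real_)
    (s / cnt) / (mu_a * mu_b) - 1
  }
}

# Look up a lag cell in a quics_corr2d surface.
corr_at <- function(corr, dx, dy) {
  zl <- corr$zero_lag_index
  corr$values[zl[1] + dx, zl[2] + dy]
}

# Brute-force radial binning: mean of surface cells whose rounded Euclidean
# lag radius is k, enumerated cell by cell.
direct_radial_bin <- function(corr, k) {
  zl <- corr$zero_lag_index
  vals <- c()
  for (i in seq_len(nrow(corr$values))) {
    for (j in seq_len(ncol(corr$values))) {
      if (round(sqrt((i - zl[1])^2 + (j - zl[2])^2)) == k &&
          !is.na(corr$values[i, j]))
        vals <- c(vals, corr$values[i, j])
    }
  }
  vals
}

random_image <- function(n1 = 16, n2 = n1, lambda = 30, pixel_size = 20,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  quics_image(matrix(stats::rpois(n1 * n2, lambda), n1), pixel_size)
}

blob_mask <- function(n1, n2 = n1, radius = min(n1, n2) / 2 - 1) {
  cx <- (n1 + 1) / 2; cy <- (n2 + 1) / 2
  m <- outer(seq_len(n1), seq_len(n2),
             function(i, j) sqrt((i - cx)^2 + (j - cy)^2) <= radius)
  quics_mask(m)
}

# Exact Gaussian radial profile as a quics_racf, for fitter tests.
gaussian_racf <- function(amplitude, w, offset, n_bins = 64,
                          pixel_size = 20, g0_override = NULL) {
  rho <- 0:(n_bins - 1)
  g <- amplitude * exp(-rho^2 / w^2) + offset
  if (!is.null(g0_override)) g[1] <- g0_override
  out <- data.frame(rho = rho, g = g, n_pairs = pmax(1L, 8L * rho))
  attr(out, "pixel_size") <- pixel_size
  attr(out, "kind") <- "auto"
  attr(out, "mean_intensity") <- 100
  class(out) <- c("quics_racf", "data.frame")
  out
}
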