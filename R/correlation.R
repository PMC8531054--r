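# Spatial correlation surfaces computed via 2D FFT.
#
# The normalized correlation of an image I is
#   G(dx, dy) = <I(x, y) I(x + dx, y + dy)> / <I>^2 - 1
# with averages restricted to the ROI mask when one is given. The numerator
# is evaluated by FFT; under the `padded` boundary the image (and mask) are
# zero-padded to at least twice their size and each lag is normalized by the
# number of valid pixel pairs contributing to it, so no wrap-around pairs are
# ever counted. Under `circular` the plain cyclic correlation is used.

# Sum over x of A(x) B(x + delta), cyclic, zero lag at [1, 1].
xcorr_sum <- function(a, b) {
  Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    length(a)
}

# Move zero lag from [1, 1] to the centre cell (floor(n/2) + 1).
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

pad_to <- function(m, d1, d2) {
  out <- matrix(0, d1, d2)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

new_corr2d <- function(values, n_pairs, zero_lag_index, mean_intensity,
                       kind, pixel_size, boundary) {
  structure(list(values = values, n_pairs = n_pairs,
                 zero_lag_index = zero_lag_index,
                 mean_intensity = mean_intensity, kind = kind,
                 pixel_size = pixel_size, boundary = boundary),
            class = "quics_corr2d")
}

#' @export
print.quics_corr2d <- function(x, ...) {
  i0 <- x$zero_lag_index
  cat(sprintf("<quics_corr2d> %s, %s boundary, %d x %d lags, G(0,0) = %.5g\n",
              x$kind, x$boundary, nrow(x$values), ncol(x$values),
              x$values[i0[1], i0[2]]))
  invisible(x)
}

# Shared engine for auto- and cross-correlation. a, b: images (matrices)
# already masked to zero outside the ROI; w: 0/1 support weights.
corr2d_engine <- function(a, b, w, mean_a, mean_b, boundary, kind,
                          pixel_size) {
  if (boundary == "padded") {
    d1 <- 2L * nrow(a); d2 <- 2L * ncol(a)
    a <- pad_to(a, d1, d2); b <- pad_to(b, d1, d2); w <- pad_to(w, d1, d2)
  }
  num <- fftshift2(xcorr_sum(a, b))
  cnt <- round(fftshift2(xcorr_sum(w, w)))
  vals <- matrix(NA_real_, nrow(num), ncol(num))
  ok <- cnt > 0
  vals[ok] <- (num[ok] / cnt[ok]) / (mean_a * mean_b) - 1
  zl <- c(floor(nrow(num) / 2) + 1L, floor(ncol(num) / 2) + 1L)
  new_corr2d(vals, cnt, zl, sqrt(mean_a * mean_b), kind, pixel_size, boundary)
}

#' Masked 2D autocorrelation function of an image
#'
#' Computes the normalized spatial autocorrelation
#' \deqn{G(\delta_x,\delta_y) = \frac{\langle I(x,y)\,I(x+\delta_x,
#'   y+\delta_y)\rangle}{\langle I \rangle^2} - 1}
#' with the numerator evaluated by 2D FFT and all averages restricted to the
#' ROI mask when one is supplied.
#'
#' @param image a [quics_image()].
#' @param mask optional [quics_mask()] (or logical matrix) of the same shape.
#' @param boundary `"padded"` (default) zero-pads to twice the field and
#'   normalizes each lag by its count of valid in-mask pixel pairs, so no
#'   wrap-around pairs contribute; `"circular"` uses the plain cyclic
#'   correlation implied by an unpadded FFT.
#' @return A `quics_corr2d` object: `values` (correlation amplitudes with the
#'   zero lag at `zero_lag_index`, `NA` where no valid pair exists),
#'   `n_pairs`, `mean_intensity` (the masked mean used in the
#'   normalization), `kind = "auto"`.
#' @seealso [radial_profile()], [ccf2d()]
#' @examples
#' img <- quics_image(matrix(rpois(32 * 32, 50), 32), pixel_size = 20)
#' g <- acf2d(img)
#' g$values[g$zero_lag_index[1], g$zero_lag_index[2]]  # = var/mean^2
#' @export
acf2d <- function(image, mask = NULL, boundary = c("padded", "circular")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(image, "quics_image"))
  mask <- check_mask(image, mask)
  w <- if (is.null(mask)) {
    matrix(1, nrow(image$pixels), ncol(image$pixels))
  } else {
    mask$include * 1
  }
  iz <- image$pixels * w
  mu <- sum(iz) / sum(w)
  if (mu <= 0) stop("degenerate image: mean intensity over the mask is zero")
  corr2d_engine(iz, iz, w, mu, mu, boundary, "auto", image$pixel_size)
}

#' 2D cross-correlation of two images
#'
#' Same normalization as [acf2d()] but with the cross-mean denominator
#' \eqn{\langle I' \rangle \langle I'' \rangle}: used to correlate the two
#' noise-independent half-images produced by [downsample_pair()], whose
#' zero-lag amplitude is free of uncorrelated pixel noise.
#'
#' @param image_a,image_b two [quics_image()]s of identical shape and pixel
#'   size.
#' @inheritParams acf2d
#' @return A `quics_corr2d` with `kind = "cross"`.
#' @export
ccf2d <- function(image_a, image_b, mask = NULL,
                  boundary = c("padded", "circular")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(image_a, "quics_image"), inherits(image_b, "quics_image"))
  if (!identical(dim(image_a$pixels), dim(image_b$pixels)))
    stop("images must have identical shapes")
  if (image_a$pixel_size != image_b$pixel_size)
    stop("images must have identical pixel sizes")
  mask <- check_mask(image_a, mask)
  w <- if (is.null(mask)) {
    matrix(1, nrow(image_a$pixels), ncol(image_a$pixels))
  } else {
    mask$include * 1
  }
  az <- image_a$pixels * w; bz <- image_b$pixels * w
  mu_a <- sum(az) / sum(w); mu_b <- sum(bz) / sum(w)
  if (mu_a <= 0 || mu_b <= 0)
    stop("degenerate image: mean intensity over the mask is zero")
  corr2d_engine(az, bz, w, mu_a, mu_b, boundary, "cross", image_a$pixel_size)
}

#' Split an image into two noise-independent half-images
#'
#' Each 2x2 block contributes its two diagonal pixels (even checkerboard
#' parity, i + j even in 0-based indices) averaged into one pixel of the
#' first half-image, and its two anti-diagonal pixels (odd parity) averaged
#' into one pixel of the second. The two outputs therefore draw on disjoint
#' parity classes of original pixels, so for pixel-wise independent noise
#' their noise realizations are statistically independent. Both half-size
#' images are resampled back to the original size by 2x2 nearest-neighbour
#' replication, which preserves counts without re-mixing the parity classes.
#'
#' Odd trailing rows/columns are cropped (with a warning) before splitting.
#'
#' @param image a [quics_image()], at least 8x8.
#' @return list with elements `even` and `odd`, both `quics_image`s of the
#'   (cropped) original size.
#' @export
downsample_pair <- function(image) {
  stopifnot(inherits(image, "quics_image"))
  px <- image$pixels
  if (nrow(px) %% 2L == 1L || ncol(px) %% 2L == 1L) {
    warning("odd image dimension(s): cropping trailing row/column")
    px <- px[seq_len(nrow(px) - nrow(px) %% 2L),
             seq_len(ncol(px) - ncol(px) %% 2L), drop = FALSE]
  }
  ri <- seq(1L, nrow(px), by = 2L); ci <- seq(1L, ncol(px), by = 2L)
  p00 <- px[ri, ci, drop = FALSE]          # (i, j), i + j even
  p11 <- px[ri + 1L, ci + 1L, drop = FALSE] # (i+1, j+1), even
  p01 <- px[ri, ci + 1L, drop = FALSE]     # odd parity
  p10 <- px[ri + 1L, ci, drop = FALSE]     # odd parity
  half_even <- (p00 + p11) / 2
  half_odd <- (p01 + p10) / 2
  upsample2 <- function(h) h[rep(seq_len(nrow(h)), each = 2L),
                             rep(seq_len(ncol(h)), each = 2L), drop = FALSE]
  list(even = quics_image(upsample2(half_even), image$pixel_size,
                          paste0(image$name, "_even")),
       odd = quics_image(upsample2(half_odd), image$pixel_size,
                         paste0(image$name, "_odd")))
}

#' Collapse a 2D correlation surface to a radial profile
#'
#' Converts \eqn{G(\delta_x,\delta_y)} to the angle-averaged
#' \eqn{G(\rho)} by assigning every lag cell to the bin
#' `round(sqrt(dx^2 + dy^2))` (bin width one pixel) and taking the unweighted
#' mean within each bin. Bin 0 contains exactly the zero-lag cell.
#'
#' @param corr a `quics_corr2d` from [acf2d()] or [ccf2d()].
#' @param max_lag largest radial lag (pixels) to report; defaults to half the
#'   smaller original image dimension.
#' @return A `quics_racf`: a data frame with columns `rho` (pixels), `g`, and
#'   `n_pairs` (number of 2D lag cells averaged into the bin), plus a
#'   `pixel_size` attribute.
#' @export
radial_profile <- function(corr, max_lag = NULL) {
  stopifnot(inherits(corr, "quics_corr2d"))
  d <- dim(corr$values)
  half_min <- if (corr$boundary == "padded") {
    floor(min(d) / 4)   # padded surface is twice the image
  } else {
    floor(min(d) / 2)
  }
  if (is.null(max_lag)) max_lag <- half_min
  if (max_lag > half_min)
    stop("max_lag exceeds half the smaller image dimension")
  zl <- corr$zero_lag_index
  dx <- (seq_len(d[1]) - zl[1])
  dy <- (seq_len(d[2]) - zl[2])
  rr <- sqrt(outer(dx^2, dy^2, "+"))
  bin <- as.integer(round(rr))
  keep <- bin <= max_lag & !is.na(corr$values)
  bins <- bin[keep]
  vals <- corr$values[keep]
  g <- tapply(vals, bins, mean)
  n <- tapply(vals, bins, length)
  rho <- as.integer(names(g))
  out <- data.frame(rho = rho, g = as.numeric(g),
                    n_pairs = as.integer(n))
  out <- out[order(out$rho), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pixel_size") <- corr$pixel_size
  attr(out, "kind") <- corr$kind
  attr(out, "mean_intensity") <- corr$mean_intensity
  class(out) <- c("quics_racf", "data.frame")
  out
}
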