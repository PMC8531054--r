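# The three image-quality parameters.
#
# For an image of particles convolved with a Gaussian PSF the noise-free ACF
# is Gaussian; its fitted width, amplitude and the raw zero lag decompose
# into
#   R = sqrt(2 ln 2) w           effective resolution (FWHM of the PSF), nm
#   B = G_NF(0) I_av             brightness = sigma_p^2 / I_av, counts
#   N = (G(0) - G_NF(0))/G_NF(0) relative noise variance sigma_noise^2 /
#                                sigma_p^2
# When the fit has a nonzero offset G_NF(Inf) (large-scale structure), the
# raw zero lag is offset-corrected before forming N so numerator and
# denominator share a baseline; with zero offset this is the plain formula.

#' Effective resolution from a fitted ACF width
#'
#' \eqn{R = \sqrt{2\ln 2}\, w \cdot \mathrm{pixel\_size}}: the FWHM of a
#' Gaussian whose 1/e^2 width is the fitted correlation width. For
#' point-like particles this equals the PSF FWHM; finite-size features can
#' only increase it.
#'
#' @param fit a converged `quics_fit`.
#' @param pixel_size nm per pixel.
#' @return Resolution in nm.
#' @export
quics_resolution <- function(fit, pixel_size) {
  stop_if_unconverged(fit)
  sqrt(2 * log(2)) * fit$width_w * pixel_size
}

#' Brightness from a fitted ACF amplitude
#'
#' \eqn{B = G_{NF}(0)\, I_{av} = \sigma_p^2 / I_{av}} in raw intensity
#' counts. Uniform background dilutes it: with particle and background means
#' \eqn{I_{av} = I_{av,p} + I_{av,bkgd}}, \eqn{B = \sigma_p^2 / (I_{av,p} +
#' I_{av,bkgd})}. Comparable only across identical acquisition settings.
#'
#' @param fit a converged `quics_fit`.
#' @param mean_intensity the (masked) mean image intensity, counts.
#' @return Brightness in counts.
#' @export
quics_brightness <- function(fit, mean_intensity) {
  stop_if_unconverged(fit)
  fit$amplitude * mean_intensity
}

#' Relative noise variance from the raw zero lag and the fitted amplitude
#'
#' \eqn{N = (G(0) - G_{NF}(\infty) - G_{NF}(0)) / G_{NF}(0) =
#' \sigma^2_{noise}/\sigma^2_p}. 0 means no noise; 1 means noise
#' fluctuations as large as the particle fluctuations. Small negative
#' estimates (>= -0.05) are clamped to 0 with a warning flag; lower values
#' are flagged as suspect.
#'
#' @param raw_zero_lag the raw radial ACF value at zero lag, \eqn{G(0)}.
#' @param fit a converged `quics_fit` with positive amplitude.
#' @return list: `N` (dimensionless) and `flags` (character vector).
#' @export
quics_noise <- function(raw_zero_lag, fit) {
  stop_if_unconverged(fit)
  if (!is.finite(fit$amplitude) || fit$amplitude <= 0)
    stop("cannot normalize noise: fitted amplitude is not positive")
  n <- (raw_zero_lag - fit$offset - fit$amplitude) / fit$amplitude
  flags <- character()
  if (n < -0.05) {
    flags <- "noise estimate below -0.05: fit or data suspect"
  } else if (n < 0) {
    flags <- "small negative noise estimate clamped to 0"
    n <- 0
  }
  list(N = n, flags = flags)
}

stop_if_unconverged <- function(fit) {
  stopifnot(inherits(fit, "quics_fit"))
  if (!isTRUE(fit$converged))
    stop("fit did not converge: ", paste(fit$flags, collapse = "; "))
  invisible(fit)
}

#' Photobleaching as percentage intensity loss per frame
#'
#' Given the ordered per-frame mean intensities of a series, returns
#' \eqn{100\,(1 - I_k / I_0)} per frame; the first entry is 0 by definition.
#'
#' @param mean_intensities numeric vector, length >= 2, first element > 0.
#' @return Percentage series of the same length.
#' @examples
#' photobleaching(c(100, 60))  # 0 40
#' @export
photobleaching <- function(mean_intensities) {
  if (length(mean_intensities) < 2L)
    stop("need at least two frames")
  if (!is.finite(mean_intensities[1L]) || mean_intensities[1L] <= 0)
    stop("first frame mean intensity must be positive")
  100 * (1 - mean_intensities / mean_intensities[1L])
}

#' Analyze a single image: Resolution, Brightness, Noise
#'
#' The full pipeline: masked 2D ACF, angular average, noise-free amplitude
#' estimation (skip-zero fit or downsampled cross-correlation), then the
#' three quality parameters. Deterministic for fixed input and
#' configuration.
#'
#' @inheritParams estimate_noise_free
#' @return A `quics_result` list: `resolution_R` (nm), `brightness_B`
#'   (counts), `noise_N`, `mean_intensity_Iav`, `raw_zero_lag_G0`, `fit`,
#'   `acf` (raw radial profile), `acf_fitted`, `method`, `name`, `warnings`
#'   (character; any fit flag voids headline metrics into `NA` rather than
#'   reporting silently — the raw fit is always attached).
#' @examples
#' sim <- simulate_image(shape = c(96, 96), n_particles = 30, seed = 1)
#' res <- quics_analyze(sim$image)
#' res$resolution_R  # nm, close to the 240 nm PSF FWHM
#' @export
quics_analyze <- function(image, mask = NULL,
                          method = c("skip_zero", "downsample_cc"),
                          boundary = c("padded", "circular"),
                          range = NULL, max_lag = NULL,
                          weight_by_npairs = FALSE) {
  method <- match.arg(method)
  boundary <- match.arg(boundary)
  est <- estimate_noise_free(image, mask, method, boundary, range, max_lag,
                             weight_by_npairs)
  ft <- est$fit
  g0 <- est$acf$g[est$acf$rho == 0]
  i_av <- attr(est$acf, "mean_intensity")
  warnings <- ft$flags
  if (isTRUE(ft$converged) && !length(ft$flags)) {
    r <- quics_resolution(ft, image$pixel_size)
    b <- quics_brightness(ft, i_av)
    nz <- quics_noise(g0, ft)
    n <- nz$N
    warnings <- c(warnings, nz$flags)
  } else {
    r <- b <- n <- NA_real_
    warnings <- c(warnings,
                  "headline metrics withheld: fit not converged or flagged")
  }
  structure(list(resolution_R = r, brightness_B = b, noise_N = n,
                 mean_intensity_Iav = i_av, raw_zero_lag_G0 = g0,
                 fit = ft, acf = est$acf, acf_fitted = est$acf_fitted,
                 method = method, name = image$name, warnings = warnings),
            class = "quics_result")
}

#' @export
print.quics_result <- function(x, ...) {
  cat(sprintf("<quics_result> '%s' (%s)\n", x$name, x$method))
  cat(sprintf("  Resolution R : %.4g nm\n", x$resolution_R))
  cat(sprintf("  Brightness B : %.4g counts\n", x$brightness_B))
  cat(sprintf("  Noise N      : %.4g\n", x$noise_N))
  cat(sprintf("  I_av %.4g, raw G(0) %.5g, w %.4g px, rho [%g, %g]\n",
              x$mean_intensity_Iav, x$raw_zero_lag_G0, x$fit$width_w,
              x$fit$range$rho_min, x$fit$range$rho_max))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @describeIn quics_analyze one-row data frame of the result (the CSV
#'   schema used by [run_batch()]).
#' @param x a `quics_result`.
#' @param ... unused.
#' @export
as.data.frame.quics_result <- function(x, ...) {
  data.frame(name = x$name, method = x$method,
             R_nm = x$resolution_R, B_counts = x$brightness_B, N = x$noise_N,
             I_av = x$mean_intensity_Iav, G0_raw = x$raw_zero_lag_G0,
             w_px = x$fit$width_w, amplitude = x$fit$amplitude,
             offset = x$fit$offset, rho_min = x$fit$range$rho_min,
             rho_max = x$fit$range$rho_max, converged = x$fit$converged,
             warnings = paste(x$warnings, collapse = "; "),
             stringsAsFactors = FALSE)
}
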