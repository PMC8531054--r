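# Gaussian fitting of radial correlation profiles.
#
# The noise-free correlation function is modeled as
#   G_NF(rho) = G_NF(0) * exp(-rho^2 / w^2) + G_NF(Inf)
# where w is the 1/e^2 width in pixels. Uncorrelated pixel noise contributes
# only to the zero-lag point, so fitting from rho_min = 1 (skip-zero route)
# or fitting the downsampled cross-correlation from rho_min = 0 both recover
# the noise-free amplitude.

#' Define a radial fitting range
#'
#' @param rho_min lower radial lag bound in pixels (inclusive); 1 to skip the
#'   noise-bearing zero-lag point, 0 to include it.
#' @param rho_max upper bound in pixels (inclusive).
#' @param policy `"fixed"` for user-chosen bounds, `"auto"` when produced by
#'   [auto_fit_range()].
#' @return A `quics_fit_range` list.
#' @export
fit_range <- function(rho_min, rho_max, policy = "fixed") {
  if (!(rho_min >= 0 && rho_min < rho_max))
    stop("need 0 <= rho_min < rho_max")
  structure(list(rho_min = rho_min, rho_max = rho_max, policy = policy),
            class = "quics_fit_range")
}

# Initial guesses: amplitude from the first fitted bin above a tail-median
# offset; width from the lag where the decay first crosses amplitude/e^2.
fit_start_values <- function(rho, g, cap) {
  tail_q <- g[rho >= stats::quantile(rho, 0.75)]
  offset0 <- stats::median(tail_q)
  amp0 <- max(g[1L] - offset0, 1e-12)
  below <- which((g - offset0) < amp0 / exp(2))
  w0 <- if (length(below)) max(rho[below[1L]], 0.5) else cap / 6
  list(amplitude = amp0, w = w0, offset = offset0)
}

#' Fit a Gaussian model to a radial correlation profile
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' \eqn{G(\rho) = A e^{-\rho^2/w^2} + C} over the bins inside `range`.
#' Unweighted by default; set `weight_by_npairs = TRUE` to weight bins by
#' their 2D cell counts.
#'
#' @param acf a `quics_racf` from [radial_profile()].
#' @param range a [fit_range()]; at least 5 bins must fall inside it.
#' @param weight_by_npairs logical; weight residuals by `n_pairs`.
#' @return A `quics_fit` list: `amplitude` (\eqn{G_{NF}(0)}), `width_w`
#'   (pixels), `offset` (\eqn{G_{NF}(\infty)}), `stderr` (named vector),
#'   `residual_rms`, `converged`, `flags` (character; e.g. amplitude not
#'   significant at 2 standard errors), `range`, `method` (filled by
#'   callers).
#' @export
fit_acf <- function(acf, range, weight_by_npairs = FALSE) {
  stopifnot(inherits(acf, "quics_racf"), inherits(range, "quics_fit_range"))
  sel <- acf$rho >= range$rho_min & acf$rho <= range$rho_max &
    is.finite(acf$g)
  if (sum(sel) < 5L)
    stop("insufficient range: fewer than 5 bins inside the fitting range")
  rho <- acf$rho[sel]; g <- acf$g[sel]
  cap <- max(acf$rho)
  st <- fit_start_values(rho, g, cap)
  wts <- if (weight_by_npairs) acf$n_pairs[sel] else rep(1, length(rho))
  start <- list(amplitude = st$amplitude, w = st$w, offset = st$offset)
  lower <- c(amplitude = 0, w = 0.1, offset = -Inf)
  upper <- c(amplitude = Inf, w = 2 * cap, offset = Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ amplitude * exp(-rho^2 / w^2) + offset,
      start = start, lower = lower, upper = upper, weights = wts,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # Levenberg-Marquardt can fail while assembling the model object even
    # when the optimum is fine; a bounded Gauss-Newton retry covers that
    fit <- tryCatch(
      stats::nls(g ~ amplitude * exp(-rho^2 / w^2) + offset,
                 start = start, lower = lower, upper = upper,
                 weights = wts, algorithm = "port",
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) e)
  }
  out <- list(amplitude = NA_real_, width_w = NA_real_, offset = NA_real_,
              stderr = c(amplitude = NA_real_, w = NA_real_,
                         offset = NA_real_),
              residual_rms = NA_real_, converged = FALSE,
              flags = character(), range = range, method = NA_character_,
              n_bins = sum(sel))
  if (inherits(fit, "error")) {
    out$flags <- paste("fit failed:", conditionMessage(fit))
    class(out) <- "quics_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(amplitude = NA_real_, w = NA_real_, offset = NA_real_))
  out$amplitude <- unname(cf["amplitude"])
  out$width_w <- unname(cf["w"])
  out$offset <- unname(cf["offset"])
  out$stderr <- c(amplitude = unname(se["amplitude"]), w = unname(se["w"]),
                  offset = unname(se["offset"]))
  out$residual_rms <- sqrt(mean(stats::residuals(fit)^2))
  out$converged <- isTRUE(fit$convInfo$isConv) || is.null(fit$convInfo)
  if (is.finite(out$stderr["amplitude"]) &&
      out$amplitude <= 2 * out$stderr["amplitude"])
    out$flags <- c(out$flags, "amplitude not significant (<= 2 SE)")
  if (!is.finite(out$residual_rms)) out$converged <- FALSE
  class(out) <- "quics_fit"
  out
}

#' @export
print.quics_fit <- function(x, ...) {
  cat(sprintf(
    "<quics_fit> %s: amplitude %.5g, w %.4g px, offset %.3g, rho [%g, %g]%s\n",
    ifelse(is.na(x$method), "gaussian", x$method), x$amplitude, x$width_w,
    x$offset, x$range$rho_min, x$range$rho_max,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]")
    else ""))
  invisible(x)
}

#' Choose the upper fitting bound automatically
#'
#' Stands in for choosing \eqn{\rho_{max}} by eye so that a single Gaussian
#' component is fitted: fit over the full available range, set
#' `rho_max = max(8, round(3 * w_hat))` (3 widths cover > 99.98% of a
#' Gaussian), capped at one quarter of the smaller image dimension, refit,
#' and iterate until the bound moves by at most one bin (at most 10 rounds).
#'
#' @param acf a `quics_racf` with at least 16 bins.
#' @param skip_zero logical; `TRUE` starts the range at 1 pixel, `FALSE`
#'   at 0.
#' @return A [fit_range()] with `policy = "auto"`.
#' @export
auto_fit_range <- function(acf, skip_zero = TRUE) {
  stopifnot(inherits(acf, "quics_racf"))
  if (nrow(acf) < 16L) stop("auto range needs at least 16 bins")
  # profile spans at most half the smaller image dimension, so half of the
  # largest bin is the quarter-dimension cap
  cap <- max(8L, floor(max(acf$rho) / 2))
  rho_min <- if (skip_zero) 1 else 0
  rho_max <- cap
  for (i in seq_len(10L)) {
    ft <- fit_acf(acf, fit_range(rho_min, rho_max, "auto"))
    if (!ft$converged || !is.finite(ft$width_w)) break
    new_max <- min(max(8, round(3 * ft$width_w)), cap)
    if (abs(new_max - rho_max) <= 1) {
      rho_max <- new_max
      return(fit_range(rho_min, rho_max, "auto"))
    }
    rho_max <- new_max
  }
  warning("auto fitting range did not stabilize; using the cap")
  fit_range(rho_min, cap, "auto")
}

#' Estimate the noise-free correlation amplitude of an image
#'
#' Two interchangeable estimators of the noise-free radial ACF:
#' \describe{
#'   \item{`skip_zero`}{fit the image's own radial ACF with the zero-lag
#'     point excluded (`rho_min = 1`); uncorrelated noise lives only in that
#'     point.}
#'   \item{`downsample_cc`}{cross-correlate the two parity half-images from
#'     [downsample_pair()], whose noise is independent, and fit from
#'     `rho_min = 0`.}
#' }
#' Both return the raw radial ACF of the original image alongside the fit,
#' since the raw zero lag \eqn{G(0)} is needed for the noise metric.
#'
#' @param image a [quics_image()].
#' @param mask optional [quics_mask()].
#' @param method `"skip_zero"` (default) or `"downsample_cc"`.
#' @param boundary passed to [acf2d()]/[ccf2d()].
#' @param range a [fit_range()] or `NULL` for [auto_fit_range()].
#' @param max_lag passed to [radial_profile()].
#' @param weight_by_npairs passed to [fit_acf()].
#' @return list with `fit` (a `quics_fit` with `method` set), `acf` (raw
#'   radial ACF of the original image) and `acf_fitted` (the profile the fit
#'   ran on; differs from `acf` only for `downsample_cc`).
#' @export
estimate_noise_free <- function(image, mask = NULL,
                                method = c("skip_zero", "downsample_cc"),
                                boundary = c("padded", "circular"),
                                range = NULL, max_lag = NULL,
                                weight_by_npairs = FALSE) {
  method <- match.arg(method)
  boundary <- match.arg(boundary)
  acf_raw <- radial_profile(acf2d(image, mask, boundary), max_lag)
  if (method == "skip_zero") {
    acf_fit_on <- acf_raw
    skip <- TRUE
  } else {
    halves <- downsample_pair(image)
    acf_fit_on <- radial_profile(
      ccf2d(halves$even, halves$odd, mask, boundary), max_lag)
    skip <- FALSE
  }
  rg <- if (is.null(range)) auto_fit_range(acf_fit_on, skip_zero = skip)
        else range
  ft <- fit_acf(acf_fit_on, rg, weight_by_npairs)
  ft$method <- method
  list(fit = ft, acf = acf_raw, acf_fitted = acf_fit_on)
}
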