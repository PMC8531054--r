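#' Construct a 2D fluorescence image
#'
#' The basic unit of analysis: a single-channel grid of non-negative
#' intensities (photon counts or detector units) together with the physical
#' pixel size. All computations are carried out in double precision
#' regardless of the bit depth of the source file.
#'
#' @param pixels numeric matrix of intensities, at least 8 x 8, all finite.
#' @param pixel_size physical edge length of one pixel, in nm (> 0).
#' @param name free-text identifier carried through to results.
#' @return An object of class `quics_image` (a list with elements `pixels`,
#'   `pixel_size`, `name`).
#' @examples
#' img <- quics_image(matrix(runif(64 * 64), 64), pixel_size = 20)
#' dim(img$pixels)
#' @export
quics_image <- function(pixels, pixel_size, name = "image") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("image must be at least 8x8 pixels")
  if (!all(is.finite(pixels)))
    stop("image contains non-finite values")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (nm)")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size),
                 name = as.character(name)[1L]),
            class = "quics_image")
}

#' @export
print.quics_image <- function(x, ...) {
  cat(sprintf("<quics_image> '%s': %d x %d px, %.4g nm/px, mean %.4g\n",
              x$name, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              mean(x$pixels)))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' A binary inclusion mask with the same shape as the image it applies to,
#' typically delimiting a nucleus so that borders do not distort the
#' correlation function. At least 64 pixels must be included for the
#' downstream Gaussian fit to have any statistics.
#'
#' @param include logical (or 0/1 numeric) matrix; `TRUE` pixels take part in
#'   all averages and correlations.
#' @return An object of class `quics_mask`.
#' @export
quics_mask <- function(include) {
  include <- as.matrix(include)
  if (is.numeric(include)) include <- include != 0
  if (!is.logical(include)) stop("mask must be logical or numeric")
  include[is.na(include)] <- FALSE
  if (sum(include) < 64L) stop("mask too small: fewer than 64 included pixels")
  structure(list(include = include), class = "quics_mask")
}

check_mask <- function(image, mask) {
  if (is.null(mask)) return(NULL)
  if (!inherits(mask, "quics_mask")) mask <- quics_mask(mask)
  if (!identical(dim(mask$include), dim(image$pixels)))
    stop("mask shape does not match image shape")
  mask
}
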