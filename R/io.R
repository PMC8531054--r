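# File input/output and batch orchestration.
#
# Images are read from single-channel TIFF (a plane of a multi-page stack
# can be selected); masks from TIFF or PNG, nonzero = include. Pixel size
# comes from the caller (TIFF tags rarely carry a trustworthy one). Results
# serialize to a one-row CSV schema and JSON.

#' Read a TIFF image
#'
#' Loads a single-channel plane as doubles, preserving the stored integer
#' values (no 0-1 rescaling).
#'
#' @param path TIFF file.
#' @param pixel_size physical pixel size in nm (required; TIFF metadata is
#'   not trusted).
#' @param plane 1-based page index for multi-page stacks; mandatory when the
#'   file holds more than one plane.
#' @return A [quics_image()] named after the file.
#' @export
read_image <- function(path, pixel_size, plane = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) > 1L && is.null(plane))
    stop("multi-page TIFF: select a plane with `plane = <index>`")
  if (is.null(plane)) plane <- 1L
  if (plane < 1L || plane > length(pages))
    stop("plane index out of range: ", plane)
  px <- pages[[plane]]
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] == 1L) {
      px <- px[, , 1L]
    } else {
      stop("multi-channel image: supply a single-channel TIFF ",
           "(or select a plane with `plane`)")
    }
  }
  quics_image(px, pixel_size,
              name = tools::file_path_sans_ext(basename(path)))
}

#' Read a binary ROI mask from TIFF or PNG
#'
#' Nonzero pixels are included. Multi-channel masks use the first channel.
#'
#' @param path TIFF or PNG file.
#' @return A [quics_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") png::readPNG(path) else
    tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  quics_mask(m != 0)
}

#' Write an image to TIFF
#'
#' Stores the intensity grid as a 16-bit unsigned integer TIFF, the native
#' format of photon-counting acquisitions: integer counts in [0, 65535]
#' round-trip exactly through [read_image()]. Non-integer intensities are
#' rounded and negatives clipped to 0, with a warning.
#'
#' @param image a [quics_image()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "quics_image"))
  px <- image$pixels
  if (any(px != round(px)) || any(px < 0))
    warning("non-integer or negative intensities rounded/clipped for ",
            "16-bit TIFF storage")
  px <- pmin(pmax(round(px), 0), 65535)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Serialize an analysis result
#'
#' `write_result_csv()` writes the one-row schema (`name, method, R_nm,
#' B_counts, N, I_av, G0_raw, w_px, amplitude, offset, rho_min, rho_max,
#' converged, warnings`); `write_result_json()` adds the fit diagnostics;
#' `write_acf_csv()` dumps the radial profile plus the fitted curve
#' (`rho_px, rho_nm, g, n_pairs, fit_value`) for plotting.
#'
#' @param result a `quics_result` from [quics_analyze()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_csv
#' @export
write_result_json <- function(result, path) {
  ft <- result$fit
  payload <- list(
    name = result$name, method = result$method,
    R_nm = result$resolution_R, B_counts = result$brightness_B,
    N = result$noise_N, I_av = result$mean_intensity_Iav,
    G0_raw = result$raw_zero_lag_G0,
    fit = list(amplitude = ft$amplitude, width_w_px = ft$width_w,
               offset = ft$offset, stderr = as.list(ft$stderr),
               residual_rms = ft$residual_rms, converged = ft$converged,
               rho_min = ft$range$rho_min, rho_max = ft$range$rho_max,
               flags = ft$flags),
    warnings = result$warnings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_result_csv
#' @export
write_acf_csv <- function(result, path) {
  acf <- result$acf
  ft <- result$fit
  px <- attr(acf, "pixel_size")
  fit_value <- if (isTRUE(ft$converged)) {
    ft$amplitude * exp(-acf$rho^2 / ft$width_w^2) + ft$offset
  } else {
    rep(NA_real_, nrow(acf))
  }
  utils::write.csv(
    data.frame(rho_px = acf$rho, rho_nm = acf$rho * px, g = acf$g,
               n_pairs = acf$n_pairs, fit_value = fit_value),
    path, row.names = FALSE)
  invisible(path)
}

config_fingerprint <- function(config) {
  canonical <- jsonlite::toJSON(config[order(names(config))],
                                auto_unbox = TRUE, digits = NA)
  # small stable hash; enough to detect any option change
  sum(utf8ToInt(as.character(canonical)) *
        (seq_len(nchar(canonical)) %% 97 + 1)) %% 1e9
}

#' Analyze a batch of images and summarize
#'
#' Runs [quics_analyze()] on every image; per-image failures are recorded
#' without aborting the batch. The summary reports mean, standard deviation
#' and standard error of the mean (sample sd / sqrt(n), requiring n >= 2)
#' for R, B and N over the successfully analyzed images.
#'
#' @param images list of [quics_image()]s, or a character vector of TIFF
#'   paths (then `pixel_size` is required).
#' @param masks optional list of [quics_mask()]s (or mask file paths) paired
#'   by position; `NULL` entries allowed.
#' @param pixel_size nm per pixel, used when `images` are paths.
#' @param ... passed to [quics_analyze()] (`method`, `boundary`, `range`,
#'   `max_lag`, ...).
#' @return A `quics_batch` list: `results` (per-image `quics_result` or
#'   `NULL`), `table` (row-per-image data frame with a `failure` column),
#'   `summary` (data frame metric/mean/sd/sem/n), `n_failed`, `fingerprint`.
#' @export
run_batch <- function(images, masks = NULL, pixel_size = NULL, ...) {
  if (is.character(images)) {
    if (is.null(pixel_size)) stop("pixel_size is required for file paths")
    paths <- images
    images <- lapply(paths, function(p)
      tryCatch(read_image(p, pixel_size), error = function(e) e))
  }
  if (!length(images)) stop("empty batch")
  if (!is.null(masks) && is.character(masks))
    masks <- lapply(masks, function(p)
      tryCatch(read_mask(p), error = function(e) e))
  rows <- list(); results <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    msk <- if (is.null(masks)) NULL else masks[[i]]
    res <- if (inherits(img, "error")) img
           else if (inherits(msk, "error")) msk
           else tryCatch(quics_analyze(img, msk, ...), error = function(e) e)
    if (inherits(res, "error")) {
      results[i] <- list(NULL)
      rows[[i]] <- data.frame(
        name = if (inherits(img, "quics_image")) img$name
               else sprintf("image_%d", i),
        method = NA, R_nm = NA_real_, B_counts = NA_real_, N = NA_real_,
        I_av = NA_real_, G0_raw = NA_real_, w_px = NA_real_,
        amplitude = NA_real_, offset = NA_real_, rho_min = NA_real_,
        rho_max = NA_real_, converged = FALSE, warnings = "",
        failure = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      results[[i]] <- res
      rw <- as.data.frame(res)
      rw$failure <- ""
      rows[[i]] <- rw
    }
  }
  tab <- do.call(rbind, rows)
  ok <- tab$failure == "" & is.finite(tab$R_nm)
  if (!any(ok)) stop("batch failed: no image analyzed successfully")
  summarize_metric <- function(v) {
    v <- v[ok]
    n <- sum(is.finite(v))
    c(mean = mean(v, na.rm = TRUE),
      sd = if (n >= 2) stats::sd(v, na.rm = TRUE) else NA_real_,
      sem = if (n >= 2) stats::sd(v, na.rm = TRUE) / sqrt(n) else NA_real_,
      n = n)
  }
  sm <- rbind(R_nm = summarize_metric(tab$R_nm),
              B_counts = summarize_metric(tab$B_counts),
              N = summarize_metric(tab$N))
  summary <- data.frame(metric = rownames(sm), sm, row.names = NULL)
  if (sum(ok) < 2L)
    warning("fewer than two successful images: SEM not reported")
  dots <- list(...)
  structure(list(results = results, table = tab, summary = summary,
                 n_failed = sum(!ok),
                 fingerprint = config_fingerprint(
                   c(dots, list(pixel_size = pixel_size)))),
            class = "quics_batch")
}

#' @export
print.quics_batch <- function(x, ...) {
  cat(sprintf("<quics_batch> %d image(s), %d failed\n",
              nrow(x$table), x$n_failed))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write a batch summary
#'
#' Writes the per-image table as CSV and the summary (with config
#' fingerprint) as JSON next to it.
#'
#' @param batch a `quics_batch`.
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_batch <- function(batch, dir, stem = "quics_batch") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  js <- file.path(dir, paste0(stem, "_summary.json"))
  utils::write.csv(batch$table, csv, row.names = FALSE)
  jsonlite::write_json(
    list(summary = batch$summary, n_images = nrow(batch$table),
         n_failed = batch$n_failed, fingerprint = batch$fingerprint),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv = csv, json = js))
}

#' Run a simulation scenario described in YAML
#'
#' The YAML file holds any subset of [simulate_image()] arguments plus
#' optional `n_images`; frames are written as 32-bit float TIFFs with a JSON
#' truth sidecar each.
#'
#' @param scenario path to a YAML scenario file, or an equivalent named
#'   list.
#' @param out_dir output directory.
#' @return Data frame listing written image and sidecar paths, invisibly.
#' @export
simulate_scenario <- function(scenario, out_dir) {
  sc <- if (is.character(scenario)) yaml::read_yaml(scenario) else scenario
  n_images <- sc$n_images %||% 1L
  sc$n_images <- NULL
  base_seed <- sc$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vector("list", n_images)
  for (k in seq_len(n_images)) {
    sc$seed <- base_seed + k - 1L
    sc$name <- sprintf("sim_%03d", k)
    sim <- do.call(simulate_image, sc)
    img_path <- file.path(out_dir, paste0(sc$name, ".tif"))
    truth_path <- file.path(out_dir, paste0(sc$name, "_truth.json"))
    write_image(sim$image, img_path)
    tr <- sim$truth
    tr$noiseless_frame <- NULL
    tr$particle_positions <- NULL
    jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA)
    paths[[k]] <- data.frame(image = img_path, truth = truth_path)
  }
  invisible(do.call(rbind, paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
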