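#' Construct a mass spectrum
#'
#' A centroided mass spectrum: paired m/z and intensity arrays with m/z
#' strictly increasing and intensities non-negative.
#'
#' @param mz numeric vector of m/z values (Th), strictly increasing.
#' @param intensity numeric vector of intensities (counts), same length.
#' @param centroided logical flag, default \code{TRUE}.
#' @return A \code{mass_spectrum} object.
#' @export
mass_spectrum <- function(mz, intensity, centroided = TRUE) {
  if (length(mz) != length(intensity)) {
    stop("'mz' and 'intensity' must have equal length", call. = FALSE)
  }
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop("'mz' must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 centroided = isTRUE(centroided)),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("mass_spectrum: %d peaks, m/z %.4f-%.4f, TIC %.3g\n",
              length(x$mz), min(x$mz), max(x$mz), sum(x$intensity)))
  invisible(x)
}

#' Construct a line-scan run
#'
#' An ordered sequence of pixels along one raster line.  Each pixel pairs
#' a physical distance (µm, measured at the pixel start) with a mass
#' spectrum.  Distances must increase with uniform spacing equal to the
#' pixel size within 1%.
#'
#' @param spectra list of [mass_spectrum()] objects, one per pixel, in
#'   scan order.
#' @param distances numeric vector of pixel-start distances in µm.
#' @param raster_rate stage translation speed in µm/s (> 0).
#' @param pixel_size along-scan pixel size in µm (the transverse pixel
#'   dimension does not enter a 1-D model and is carried as metadata
#'   only).
#' @param polarity \code{"positive"} or \code{"negative"}.
#' @param scan_length total scan length in µm; default
#'   \code{max(distances) + pixel_size}.
#' @return A \code{line_scan_run} object.
#' @export
line_scan_run <- function(spectra, distances, raster_rate, pixel_size,
                          polarity = c("positive", "negative"),
                          scan_length = NULL) {
  polarity <- match.arg(polarity)
  if (length(spectra) == 0L) stop("a run needs at least one pixel", call. = FALSE)
  if (length(spectra) != length(distances)) {
    stop("'spectra' and 'distances' must have equal length", call. = FALSE)
  }
  if (raster_rate <= 0) stop("'raster_rate' must be > 0", call. = FALSE)
  if (pixel_size <= 0) stop("'pixel_size' must be > 0", call. = FALSE)
  distances <- as.numeric(distances)
  if (length(distances) > 1L) {
    d <- diff(distances)
    if (any(d <= 0)) stop("pixel distances must be strictly increasing", call. = FALSE)
    if (any(abs(d - pixel_size) > 0.01 * pixel_size)) {
      stop("pixel spacing must equal 'pixel_size' within 1%", call. = FALSE)
    }
  }
  if (is.null(scan_length)) scan_length <- max(distances) + pixel_size
  if (scan_length < max(distances)) {
    stop("'scan_length' must cover the last pixel", call. = FALSE)
  }
  structure(list(spectra = spectra, distances = distances,
                 raster_rate = as.numeric(raster_rate),
                 pixel_size = as.numeric(pixel_size),
                 polarity = polarity, scan_length = as.numeric(scan_length)),
            class = "line_scan_run")
}

#' @export
print.line_scan_run <- function(x, ...) {
  cat(sprintf(paste0("line_scan_run: %d pixels, %.0f um scan, %.0f um pixels, ",
                     "%.0f um/s, %s mode\n"),
              length(x$spectra), x$scan_length, x$pixel_size, x$raster_rate,
              x$polarity))
  invisible(x)
}

#' @export
length.line_scan_run <- function(x) length(x$spectra)
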