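#' Construct an XIC trace
#'
#' Per-pixel intensity of one m/z window along the scan distance.
#'
#' @param distances pixel distances in µm.
#' @param intensity per-pixel intensities (>= 0).
#' @param target_mz window center in Th (\code{NA} for a TIC).
#' @param tol_ppm window half-width in ppm.
#' @param normalized whether intensities have been spatially normalized.
#' @return An \code{xic_trace} object.
#' @export
xic_trace <- function(distances, intensity, target_mz = NA_real_,
                      tol_ppm = 10, normalized = FALSE) {
  if (length(distances) != length(intensity)) {
    stop("'distances' and 'intensity' must have equal length", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (!is.na(tol_ppm) && tol_ppm <= 0) stop("'tol_ppm' must be > 0", call. = FALSE)
  structure(list(distances = as.numeric(distances),
                 intensity = as.numeric(intensity),
                 target_mz = target_mz, tol_ppm = tol_ppm,
                 normalized = isTRUE(normalized)),
            class = "xic_trace")
}

#' @export
print.xic_trace <- function(x, ...) {
  lab <- if (is.na(x$target_mz)) "TIC" else sprintf("m/z %.4f +/- %g ppm",
                                                    x$target_mz, x$tol_ppm)
  cat(sprintf("xic_trace (%s): %d pixels, max %.3g%s\n", lab,
              length(x$intensity), max(x$intensity),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
as.data.frame.xic_trace <- function(x, ...) {
  data.frame(distance_um = x$distances, intensity = x$intensity)
}

#' Extract an ion chromatogram in the distance domain
#'
#' For each pixel, sums the intensities of all peaks with
#' \code{|mz - target_mz| <= target_mz * tol_ppm * 1e-6}.  Isolating the
#' trace of a single m/z value gives an analyte-specific, location-resolved
#' readout over the spot array.
#'
#' @param run a [line_scan_run()].
#' @param target_mz window center in Th.
#' @param tol_ppm window half-width in ppm.
#' @return An [xic_trace()].
#' @export
extract_xic <- function(run, target_mz, tol_ppm = 10) {
  stopifnot(inherits(run, "line_scan_run"))
  if (tol_ppm <= 0) stop("'tol_ppm' must be > 0", call. = FALSE)
  halfwin <- target_mz * tol_ppm * 1e-6
  lo <- target_mz - halfwin; hi <- target_mz + halfwin
  intensity <- vapply(run$spectra, function(s) {
    i1 <- findInterval(lo, s$mz) + 1L
    i2 <- findInterval(hi, s$mz)
    if (i2 < i1) 0 else sum(s$intensity[i1:i2])
  }, numeric(1L))
  hits <- vapply(run$spectra, function(s) {
    findInterval(hi, s$mz) >= findInterval(lo, s$mz) + 1L
  }, logical(1L))
  if (!any(hits)) {
    warning(sprintf("no recorded m/z within %g ppm of %.4f in any pixel; ",
                    tol_ppm, target_mz), "returning an all-zero trace",
            call. = FALSE)
  }
  xic_trace(run$distances, intensity, target_mz, tol_ppm)
}

#' Total ion chromatogram of a run
#'
#' Line-scan runs are projected like an LC chromatogram with the
#' retention-time axis replaced by scan distance; the TIC is the per-pixel
#' sum of all recorded intensities.
#'
#' @param run a [line_scan_run()].
#' @return An [xic_trace()] with \code{target_mz = NA}.
#' @export
total_ion_trace <- function(run) {
  stopifnot(inherits(run, "line_scan_run"))
  xic_trace(run$distances,
            vapply(run$spectra, function(s) sum(s$intensity), numeric(1L)),
            target_mz = NA_real_, tol_ppm = NA_real_)
}

#' Lock-mass correction
#'
#' Aligns each pixel's m/z axis to a continuously sprayed reference
#' compound (leucine enkephalin by default, via [lockmass_mz()]).  Per
#' pixel, the most intense peak within \code{search_ppm} of the reference
#' is located and a single multiplicative correction factor
#' \code{reference_mz / observed_mz} is applied to the whole m/z array —
#' adequate for the small (few-ppm) drifts of a calibrated instrument.
#' Pixels where no lock peak is found inherit the nearest pixel's factor.
#'
#' @param run a [line_scan_run()].
#' @param reference_mz reference m/z; default from the run polarity.
#' @param search_ppm search window half-width in ppm.
#' @param min_coverage minimum fraction of pixels in which the lock peak
#'   must be found (default 0.9); below this the run is rejected with a
#'   per-pixel diagnostic.
#' @return The corrected [line_scan_run()], with attribute
#'   \code{"lockmass_residual_ppm"} holding the per-pixel residual error.
#' @export
lockmass_correct <- function(run, reference_mz = NULL, search_ppm = 20,
                             min_coverage = 0.9) {
  stopifnot(inherits(run, "line_scan_run"))
  if (is.null(reference_mz)) reference_mz <- lockmass_mz(run$polarity)
  halfwin <- reference_mz * search_ppm * 1e-6
  obs <- vapply(run$spectra, function(s) {
    i1 <- findInterval(reference_mz - halfwin, s$mz) + 1L
    i2 <- findInterval(reference_mz + halfwin, s$mz)
    if (i2 < i1) return(NA_real_)
    idx <- i1:i2
    s$mz[idx[which.max(s$intensity[idx])]]
  }, numeric(1L))
  found <- !is.na(obs)
  coverage <- mean(found)
  if (coverage < min_coverage) {
    diag <- data.frame(pixel = seq_along(obs), distance_um = run$distances,
                       lock_found = found)
    cond <- simpleError(sprintf(
      "lock-mass peak found in only %.1f%% of pixels (need >= %.0f%%)",
      100 * coverage, 100 * min_coverage))
    cond$diagnostic <- diag
    stop(cond)
  }
  factor <- reference_mz / obs
  if (any(!found)) {
    idx_found <- which(found)
    for (j in which(!found)) {
      factor[j] <- factor[idx_found[which.min(abs(idx_found - j))]]
    }
  }
  spectra <- mapply(function(s, f) {
    mass_spectrum(s$mz * f, s$intensity, s$centroided)
  }, run$spectra, factor, SIMPLIFY = FALSE)
  out <- line_scan_run(spectra, run$distances, run$raster_rate,
                       run$pixel_size, run$polarity, run$scan_length)
  attr(out, "lockmass_residual_ppm") <- ifelse(found,
    (obs * factor - reference_mz) / reference_mz * 1e6, NA_real_)
  out
}

#' Spatial normalization to the lock-mass channel
#'
#' Divides per-pixel intensities by the (moving-median smoothed) lock-mass
#' trace scaled to unit mean, adjusting for ionization, sample and spray
#' inconsistencies along the raster while preserving the overall intensity
#' scale.  Works on either an [xic_trace()] or a whole [line_scan_run()].
#'
#' @param x an [xic_trace()] or [line_scan_run()].
#' @param lock_xic the lock-mass [xic_trace()] of the same run.
#' @param smooth odd moving-median window in pixels applied to the lock
#'   trace before division (default 5), so single-pixel dropouts are not
#'   amplified; 1 disables smoothing.
#' @return Object of the same class, normalized.
#' @export
spatial_normalize <- function(x, lock_xic, smooth = 5L) {
  stopifnot(inherits(lock_xic, "xic_trace"))
  lock <- lock_xic$intensity
  if (smooth > 1L) lock <- stats::runmed(lock, smooth, endrule = "median")
  if (any(lock <= 0)) {
    stop("lock-mass trace is non-positive after smoothing at pixel(s): ",
         paste(utils::head(which(lock <= 0), 10L), collapse = ", "),
         call. = FALSE)
  }
  scale <- lock / mean(lock)
  if (inherits(x, "xic_trace")) {
    if (length(x$intensity) != length(scale)) {
      stop("trace and lock trace have different pixel counts", call. = FALSE)
    }
    out <- xic_trace(x$distances, x$intensity / scale, x$target_mz,
                     x$tol_ppm, normalized = TRUE)
    return(out)
  }
  if (inherits(x, "line_scan_run")) {
    if (length(x$spectra) != length(scale)) {
      stop("run and lock trace have different pixel counts", call. = FALSE)
    }
    spectra <- mapply(function(s, f) {
      mass_spectrum(s$mz, s$intensity / f, s$centroided)
    }, x$spectra, scale, SIMPLIFY = FALSE)
    out <- line_scan_run(spectra, x$distances, x$raster_rate, x$pixel_size,
                         x$polarity, x$scan_length)
    attr(out, "normalized") <- TRUE
    return(out)
  }
  stop("'x' must be an xic_trace or line_scan_run", call. = FALSE)
}

#' Write a trace as TSV
#'
#' Two columns: \code{distance_um}, \code{intensity}.
#'
#' @param trace an [xic_trace()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
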