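#' Acquisition timing arithmetic
#'
#' The raster rate does not change the number of pixels recorded — that
#' is fixed by scan length and pixel size — but it sets the wall-clock
#' acquisition time and the dwell (spectral scan) time per pixel.
#'
#' @param scan_length scan length in mm.
#' @param rate raster rate in µm/s.
#' @return [acquisition_time()]: seconds for the full line.
#' @examples
#' acquisition_time(55, 125)      # 440 s
#' per_sample_time(440, 11)       # 40 s per sample
#' acquisition_time(50, 50) / 60  # 16.67 min
#' @export
acquisition_time <- function(scan_length, rate) {
  if (any(scan_length <= 0) || any(rate <= 0)) {
    stop("'scan_length' and 'rate' must be > 0", call. = FALSE)
  }
  scan_length * 1000 / rate
}

#' @param total_time total acquisition time in seconds.
#' @param n_samples number of samples on the line (>= 1).
#' @return [per_sample_time()]: seconds per sample.
#' @rdname acquisition_time
#' @export
per_sample_time <- function(total_time, n_samples) {
  if (any(n_samples < 1)) stop("'n_samples' must be >= 1", call. = FALSE)
  if (any(total_time < 0)) stop("'total_time' must be >= 0", call. = FALSE)
  total_time / n_samples
}

#' @param pixel_size pixel size in µm.
#' @return [pixel_dwell_time()]: seconds spent collecting one pixel frame.
#' @rdname acquisition_time
#' @export
pixel_dwell_time <- function(pixel_size, rate) {
  if (any(pixel_size <= 0) || any(rate <= 0)) {
    stop("'pixel_size' and 'rate' must be > 0", call. = FALSE)
  }
  pixel_size / rate
}

#' @return [rate_mm_per_min()]: the same rate expressed in mm/min
#'   (125 µm/s = 7.5 mm/min).
#' @rdname acquisition_time
#' @export
rate_mm_per_min <- function(rate) rate * 60 / 1000

#' Default raster-rate sweep configuration
#'
#' The optimization experiment: a 55 mm line carrying an 11-spot array
#' (3 mm spots spanning 50 mm edge-to-edge, centered on the line), with
#' six sample-spot replicates of a fatty-acid standard and five
#' solvent-blank spots, scanned at 50 µm pixels.  Eight rates from 50 to
#' 225 µm/s in 25 µm/s steps cover acquisition times from 16.67 down to
#' 3.70 min over the 50 mm spot span.
#'
#' @param target_name,target_formula,target_adduct the analyte whose XIC
#'   drives the ratio; default dodecanoic acid (C12:0) as \code{[M-H]-}.
#' @param base_intensity deposited per-pixel intensity at the reference
#'   rate, counts.
#' @param rate_model a [rate_response_model()].
#' @param noise a [noise_model()] (its seed is overridden per sweep).
#' @param n_replicates number of sample-spot replicates (default 6).
#' @return List with \code{layout}, \code{panel}, \code{target_mz},
#'   \code{rate_model}, \code{noise}, \code{pixel_size},
#'   \code{sample_spots}.
#' @export
sweep_config <- function(target_name = "C12:0", target_formula = "C12H24O2",
                         target_adduct = "[M-H]-", base_intensity = 5e4,
                         rate_model = rate_response_model(),
                         noise = noise_model(), n_replicates = 6L) {
  n_spots <- 11L
  if (n_replicates >= n_spots) stop("need at least one blank spot", call. = FALSE)
  roles <- c(rep("sample", n_replicates),
             rep("solvent_blank", n_spots - n_replicates))
  layout <- default_layout(n_spots, 3000, 50000, role = roles, offset = 2500,
                           scan_length = 55000)
  target <- analyte(target_name, target_formula, target_adduct,
                    base_intensity = base_intensity,
                    spatial_profile = "uniform",
                    spot_labels = layout$spots$label[roles == "sample"])
  list(layout = layout, panel = list(target),
       target_mz = adduct_mz(target_formula, target_adduct),
       polarity = adduct_polarity(target_adduct),
       rate_model = rate_model, noise = noise, pixel_size = 50,
       sample_spots = layout$spots$label[roles == "sample"])
}

#' Construct a signal-ratio curve
#'
#' @param rates strictly increasing rates in µm/s.
#' @param mean_ratio mean spot-to-blank ratio per rate.
#' @param sd_ratio standard deviation across spot replicates.
#' @param n_replicates replicate count.
#' @return A \code{signal_ratio_curve} object.
#' @export
signal_ratio_curve <- function(rates, mean_ratio, sd_ratio, n_replicates) {
  if (length(rates) != length(mean_ratio) ||
      length(rates) != length(sd_ratio)) {
    stop("curve arrays must have equal length", call. = FALSE)
  }
  if (length(rates) > 1L && any(diff(rates) <= 0)) {
    stop("'rates' must be strictly increasing", call. = FALSE)
  }
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1", call. = FALSE)
  structure(list(rates = as.numeric(rates), mean_ratio = as.numeric(mean_ratio),
                 sd_ratio = as.numeric(sd_ratio),
                 n_replicates = as.integer(n_replicates)),
            class = "signal_ratio_curve")
}

#' @export
print.signal_ratio_curve <- function(x, ...) {
  cat(sprintf("signal_ratio_curve: %d rates, n = %d replicates\n",
              length(x$rates), x$n_replicates))
  print(data.frame(rate_um_s = x$rates, mean_ratio = x$mean_ratio,
                   sd_ratio = x$sd_ratio))
  invisible(x)
}

#' @export
as.data.frame.signal_ratio_curve <- function(x, ...) {
  data.frame(rate_um_s = x$rates, mean_ratio = x$mean_ratio,
             sd_ratio = x$sd_ratio, n = x$n_replicates)
}

#' Raster-rate sweep
#'
#' Simulates one line-scan acquisition per rate, extracts the target
#' analyte's XIC, computes the spot-to-blank [signal_ratio()] for every
#' sample-spot replicate, and records the mean and standard deviation
#' across replicates at each rate.
#'
#' @param rates rates to evaluate, µm/s (>= 2 values); default the
#'   eight-rate grid 50–225 µm/s in 25 µm/s steps.
#' @param config a [sweep_config()].
#' @param seed integer seed; each rate's run uses \code{seed + index}.
#' @param reference reference region passed to [signal_ratio()].
#' @param tol_ppm XIC window, ppm.
#' @return A [signal_ratio_curve()].
#' @export
rate_sweep <- function(rates = seq(50, 225, by = 25), config = sweep_config(),
                       seed = 1L, reference = "solvent_blank", tol_ppm = 10) {
  if (length(rates) < 2L) stop("need >= 2 rates", call. = FALSE)
  rates <- sort(rates)
  mean_ratio <- sd_ratio <- numeric(length(rates))
  for (i in seq_along(rates)) {
    noise_i <- config$noise
    noise_i$seed <- as.integer(seed) + i
    run <- tryCatch(
      simulate_run(config$layout, config$panel, rate = rates[i],
                   pixel_size = config$pixel_size,
                   rate_model = config$rate_model, noise = noise_i,
                   polarity = config$polarity),
      error = function(e) {
        stop(sprintf("simulation failed at rate %g um/s: %s", rates[i],
                     conditionMessage(e)), call. = FALSE)
      })
    trace <- extract_xic(run, config$target_mz, tol_ppm = tol_ppm)
    ratios <- vapply(config$sample_spots, function(lab) {
      signal_ratio(trace, config$layout, lab, reference = reference)
    }, numeric(1L))
    mean_ratio[i] <- mean(ratios)
    sd_ratio[i] <- stats::sd(ratios)
  }
  signal_ratio_curve(rates, mean_ratio, sd_ratio,
                     length(config$sample_spots))
}

#' Closed-form expected signal ratio
#'
#' Deterministic evaluation of the sweep statistic from the model alone,
#' with no simulation: the expected per-pixel sample-spot intensity is
#' \code{base * signal_factor * mean_profile_weight + baseline}, and the
#' expected reference-region intensity is \code{base * level *
#' signal_factor * delocalization_factor + baseline} (Gaussian clipping
#' at zero is neglected, valid when the baseline level is several
#' dispersions above zero).  Used to cross-check the stochastic sweep.
#'
#' @param rates rates in µm/s.
#' @param rate_model a [rate_response_model()].
#' @param base_intensity analyte base intensity, counts.
#' @param baseline_level channel background mean, counts.
#' @param mean_profile_weight mean intra-spot profile weight (0.5 for the
#'   uniform profile).
#' @return Numeric vector of expected mean ratios, one per rate.
#' @export
signal_ratio_theory <- function(rates, rate_model = rate_response_model(),
                                base_intensity = 5e4, baseline_level = 20,
                                mean_profile_weight = 0.5) {
  sc <- rate_scaling(rate_model, rates)
  num <- base_intensity * sc$signal_factor * mean_profile_weight + baseline_level
  den <- base_intensity * rate_model$delocalization_level * sc$signal_factor *
    sc$delocalization_factor + baseline_level
  num / den
}

#' Optimal raster rate from a signal-ratio curve
#'
#' The rate with the maximal mean ratio; exact ties are broken toward
#' the faster rate, since throughput is the secondary objective.
#'
#' @param curve a [signal_ratio_curve()].
#' @return Rate in µm/s.
#' @export
optimal_rate <- function(curve) {
  stopifnot(inherits(curve, "signal_ratio_curve"))
  if (!length(curve$rates)) stop("empty curve", call. = FALSE)
  best <- max(curve$mean_ratio)
  ties <- which(curve$mean_ratio >= best * (1 - 1e-12))
  max(curve$rates[ties])
}
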