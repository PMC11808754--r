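#' Intra-spot spatial profile weight
#'
#' Deposited analytes partition heterogeneously inside a dried droplet:
#' peptides enrich at the spot margins (the "coffee ring" effect),
#' carbohydrates concentrate at the center, and small exogenous
#' compounds spread roughly evenly.  The three profile kinds model these
#' shapes as densities over the normalized intra-spot coordinate
#' \code{u} in \code{[-1, 1]}:
#' \itemize{
#'   \item \code{ring}: a symmetric pair of truncated Gaussians at
#'     \code{|u| = 0.85} with sigma 0.1;
#'   \item \code{center}: a truncated Gaussian at \code{u = 0} with
#'     sigma 0.35;
#'   \item \code{uniform}: constant.
#' }
#' Each profile is normalized to integrate to 1 over \code{[-1, 1]};
#' positions outside the spot (\code{|u| > 1}) get weight 0.
#'
#' @param kind one of \code{"ring"}, \code{"uniform"}, \code{"center"}.
#' @param u normalized position(s) across the spot, \code{-1} at the left
#'   edge, \code{0} at the center, \code{1} at the right edge.
#' @return Numeric weight(s).
#' @export
spatial_profile_weight <- function(kind = c("ring", "uniform", "center"), u) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("ring", "uniform", "center")) {
    stop("unknown spatial profile kind: ",
         if (is.character(kind)) paste0("'", kind[1L], "'") else "<non-character>",
         call. = FALSE)
  }
  w <- switch(kind,
    uniform = rep(0.5, length(u)),
    center = {
      s <- 0.35
      z <- stats::pnorm(1, 0, s) - stats::pnorm(-1, 0, s)
      stats::dnorm(u, 0, s) / z
    },
    ring = {
      s <- 0.1; mu <- 0.85
      z <- (stats::pnorm(1, mu, s) - stats::pnorm(-1, mu, s) +
            stats::pnorm(1, -mu, s) - stats::pnorm(-1, -mu, s)) / 2
      (stats::dnorm(u, mu, s) + stats::dnorm(u, -mu, s)) / (2 * z)
    })
  w[abs(u) > 1] <- 0
  w
}

#' Rate-response model
#'
#' Describes how per-pixel signal and analyte delocalization respond to
#' the raster rate.  DESI is continuously ablative, so the dwell time per
#' pixel is \code{pixel_size / rate} and measured signal falls as the
#' stage moves faster: \code{signal_factor = (reference_rate /
#' rate)^signal_exponent}, with the default exponent 1 (signal inversely
#' proportional to rate).
#'
#' Delocalized signal — analyte carried outside its deposition spot by
#' the ablating spray — does not fall off in lockstep.  Its
#' dwell-normalized intensity decreases linearly by
#' \code{delocalization_drop} between \code{slowest_rate} and the knee
#' rate, and is constant beyond the knee (the defaults encode a 60%
#' decrease between 50 and 125 µm/s with a plateau from 150 µm/s on).
#' \code{delocalization_level} sets the amplitude of the spread: the
#' fraction of an analyte's in-spot per-pixel signal that appears per
#' out-of-spot pixel before the knee factor is applied.
#'
#' @param reference_rate rate at which \code{signal_factor = 1}, µm/s.
#' @param signal_exponent exponent of the inverse signal-rate law.
#' @param delocalization_knee knee rate in µm/s.
#' @param delocalization_drop fractional drop in \code{[0, 1)} of the
#'   dwell-normalized delocalized intensity between the slowest rate and
#'   the knee.
#' @param slowest_rate rate at which the delocalization factor is 1, µm/s.
#' @param delocalization_level amplitude of the delocalized spread
#'   (fraction, >= 0); 0 disables delocalization entirely.
#' @return A \code{rate_response_model} object.
#' @export
rate_response_model <- function(reference_rate = 50, signal_exponent = 1,
                                delocalization_knee = 125,
                                delocalization_drop = 0.60,
                                slowest_rate = 50,
                                delocalization_level = 0.05) {
  if (reference_rate <= 0) stop("'reference_rate' must be > 0", call. = FALSE)
  if (delocalization_knee <= 0) stop("'delocalization_knee' must be > 0", call. = FALSE)
  if (delocalization_drop < 0 || delocalization_drop >= 1) {
    stop("'delocalization_drop' must be in [0, 1)", call. = FALSE)
  }
  if (slowest_rate <= 0 || slowest_rate > delocalization_knee) {
    stop("'slowest_rate' must be in (0, delocalization_knee]", call. = FALSE)
  }
  if (delocalization_level < 0) stop("'delocalization_level' must be >= 0", call. = FALSE)
  structure(list(reference_rate = reference_rate,
                 signal_exponent = signal_exponent,
                 delocalization_knee = delocalization_knee,
                 delocalization_drop = delocalization_drop,
                 slowest_rate = slowest_rate,
                 delocalization_level = delocalization_level),
            class = "rate_response_model")
}

#' Signal and delocalization scaling at a raster rate
#'
#' @param model a [rate_response_model()].
#' @param rate raster rate in µm/s (> 0).
#' @return List with \code{signal_factor} and \code{delocalization_factor}.
#' @examples
#' m <- rate_response_model()
#' rate_scaling(m, 125)$delocalization_factor  # 0.40
#' @export
rate_scaling <- function(model, rate) {
  stopifnot(inherits(model, "rate_response_model"))
  if (any(rate <= 0)) stop("'rate' must be > 0", call. = FALSE)
  signal_factor <- (model$reference_rate / rate)^model$signal_exponent
  frac <- pmin(pmax((rate - model$slowest_rate) /
                    (model$delocalization_knee - model$slowest_rate), 0), 1)
  delocalization_factor <- 1 - model$delocalization_drop * frac
  list(signal_factor = signal_factor,
       delocalization_factor = delocalization_factor)
}

#' Noise model for simulated runs
#'
#' Additive Gaussian channel noise on a non-negative floor: each recorded
#' m/z channel of each pixel receives a draw from
#' \code{N(baseline_level, baseline_dispersion)} added to the deposited
#' intensity, with the total clipped at 0.  Optional multiplicative mass
#' jitter perturbs every recorded m/z by \code{N(0, mz_jitter_ppm)} ppm.
#' Identical seeds reproduce identical runs bit-for-bit.
#'
#' @param baseline_level mean channel background in counts (>= 0).
#' @param baseline_dispersion standard deviation in counts (>= 0).
#' @param seed integer RNG seed for the run.
#' @param mz_jitter_ppm per-peak mass jitter, ppm (>= 0).
#' @return A \code{noise_model} object.
#' @export
noise_model <- function(baseline_level = 20, baseline_dispersion = 5,
                        seed = 1L, mz_jitter_ppm = 0) {
  if (baseline_level < 0) stop("'baseline_level' must be >= 0", call. = FALSE)
  if (baseline_dispersion < 0) stop("'baseline_dispersion' must be >= 0", call. = FALSE)
  if (mz_jitter_ppm < 0) stop("'mz_jitter_ppm' must be >= 0", call. = FALSE)
  structure(list(baseline_level = baseline_level,
                 baseline_dispersion = baseline_dispersion,
                 seed = as.integer(seed), mz_jitter_ppm = mz_jitter_ppm),
            class = "noise_model")
}

#' Declare a panel analyte for simulation
#'
#' @param name compound name.
#' @param formula molecular formula.
#' @param adduct adduct label under which the compound is observed.
#' @param base_intensity per-pixel deposited intensity (counts) at the
#'   reference rate, before profile weighting (>= 0).
#' @param spatial_profile intra-spot distribution kind; see
#'   [spatial_profile_weight()].
#' @param spot_labels labels of the layout spots containing the analyte.
#' @return An \code{analyte} object.
#' @export
analyte <- function(name, formula, adduct, base_intensity = 1e4,
                    spatial_profile = c("uniform", "ring", "center"),
                    spot_labels = character()) {
  spatial_profile <- match.arg(spatial_profile)
  if (base_intensity < 0) stop("'base_intensity' must be >= 0", call. = FALSE)
  parse_formula(formula)  # validate early
  structure(list(name = name, formula = formula, adduct = adduct,
                 base_intensity = base_intensity,
                 spatial_profile = spatial_profile,
                 spot_labels = as.character(spot_labels)),
            class = "analyte")
}

#' Simulate a line-scan DESI acquisition
#'
#' Generates a synthetic [line_scan_run()] over a [spot_layout()].  For
#' every panel analyte, intensity is deposited in its declared spots
#' shaped by its intra-spot profile and scaled by the rate model's
#' \code{signal_factor}; a delocalized fraction
#' (\code{delocalization_level * signal_factor * delocalization_factor}
#' of the base intensity) is spread uniformly over every pixel outside
#' sample spots (gaps and blank spots).  The lock-mass species is present
#' at every pixel.  Every species is recorded as its theoretical isotopic
#' envelope, and channel noise is added per [noise_model()].  The RNG is
#' seeded once per run and draws occur in pixel order.
#'
#' @param layout a [spot_layout()].
#' @param panel list of [analyte()] entries.
#' @param rate raster rate in µm/s.
#' @param pixel_size pixel size in µm.
#' @param rate_model a [rate_response_model()].
#' @param noise a [noise_model()].
#' @param lockmass an [analyte()] present at every pixel; default
#'   leucine enkephalin at 5000 counts.
#' @param polarity run polarity; default inferred from the lock-mass
#'   adduct.
#' @param n_isotopologues isotopologue peaks recorded per species.
#' @return A [line_scan_run()] with \code{ceiling(scan_length /
#'   pixel_size)} pixels.
#' @export
simulate_run <- function(layout, panel, rate = 125, pixel_size = 50,
                         rate_model = rate_response_model(),
                         noise = noise_model(),
                         lockmass = NULL, polarity = NULL,
                         n_isotopologues = 3L) {
  stopifnot(inherits(layout, "spot_layout"))
  if (layout$scan_length <= 0) stop("layout must span a positive scan length", call. = FALSE)
  if (pixel_size <= 0) stop("'pixel_size' must be > 0", call. = FALSE)
  if (rate <= 0) stop("'rate' must be > 0", call. = FALSE)
  if (inherits(panel, "analyte")) panel <- list(panel)
  if (is.null(lockmass)) {
    lk_adduct <- if (!is.null(polarity) && polarity == "negative") "[M-H]-" else "[M+H]+"
    lockmass <- analyte("leucine enkephalin", "C28H37N5O7", lk_adduct,
                        base_intensity = 5000, spatial_profile = "uniform")
  }
  if (is.null(polarity)) polarity <- adduct_polarity(lockmass$adduct)

  known <- layout$spots$label
  for (a in panel) {
    missing <- setdiff(a$spot_labels, known)
    if (length(missing)) {
      stop("panel analyte '", a$name, "' references spot label(s) absent ",
           "from the layout: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  n_pix <- ceiling(layout$scan_length / pixel_size)
  x <- (seq_len(n_pix) - 1L) * pixel_size
  sc <- rate_scaling(rate_model, rate)
  sample_labels <- layout$spots$label[layout$spots$role == "sample"]
  in_sample <- .in_spots(x, layout, sample_labels)

  entries <- c(panel, list(lockmass))
  mz_rows <- numeric(0)
  dep <- NULL  # K x n_pix deposited intensity matrix
  for (k in seq_along(entries)) {
    a <- entries[[k]]
    env <- theoretical_envelope(a$formula, a$adduct, n_isotopologues)
    base <- numeric(n_pix)
    if (k == length(entries)) {          # lock mass: sprayed, every pixel
      base[] <- a$base_intensity * sc$signal_factor
    } else {
      for (lab in a$spot_labels) {
        iv <- .spot_interval(layout, lab)
        inside <- x >= iv["left"] & x < iv["right"]
        u <- (x[inside] - (iv["left"] + iv["right"]) / 2) / ((iv["right"] - iv["left"]) / 2)
        base[inside] <- base[inside] + a$base_intensity * sc$signal_factor *
          spatial_profile_weight(a$spatial_profile, u)
      }
      if (rate_model$delocalization_level > 0) {
        base[!in_sample] <- base[!in_sample] + a$base_intensity *
          rate_model$delocalization_level * sc$signal_factor *
          sc$delocalization_factor
      }
    }
    block <- outer(env$abundance, base)      # isotopologues x pixels
    dep <- if (is.null(dep)) block else rbind(dep, block)
    mz_rows <- c(mz_rows, env$mz)
  }
  K <- length(mz_rows)

  set.seed(noise$seed)
  if (noise$baseline_level > 0 || noise$baseline_dispersion > 0) {
    # column-major fill = draws in pixel order
    eps <- matrix(stats::rnorm(K * n_pix, noise$baseline_level,
                               noise$baseline_dispersion), nrow = K)
    dep <- pmax(dep + eps, 0)
  }
  if (noise$mz_jitter_ppm > 0) {
    jit <- matrix(stats::rnorm(K * n_pix, 0, noise$mz_jitter_ppm * 1e-6), nrow = K)
    mz_mat <- mz_rows * (1 + jit)
  } else {
    mz_mat <- NULL
  }

  if (is.null(mz_mat)) {
    ord <- order(mz_rows)
    mz_sorted <- mz_rows[ord]
    # collapse exact m/z collisions between species into one channel
    if (anyDuplicated(mz_sorted)) {
      grp <- cumsum(!duplicated(mz_sorted))
      spectra <- lapply(seq_len(n_pix), function(i) {
        mass_spectrum(mz_sorted[!duplicated(mz_sorted)],
                      as.numeric(rowsum(dep[ord, i], grp)))
      })
    } else {
      spectra <- lapply(seq_len(n_pix), function(i) {
        mass_spectrum(mz_sorted, dep[ord, i])
      })
    }
  } else {
    spectra <- lapply(seq_len(n_pix), function(i) {
      mzi <- mz_mat[, i]
      ord <- order(mzi)
      mzi <- mzi[ord]; ii <- dep[ord, i]
      if (any(diff(mzi) <= 0)) {            # jitter-induced collision
        keep <- c(TRUE, diff(mzi) > 0)
        grp <- cumsum(keep)
        mzi <- mzi[keep]; ii <- as.numeric(rowsum(ii, grp))
      }
      mass_spectrum(mzi, ii)
    })
  }

  line_scan_run(spectra, x, raster_rate = rate, pixel_size = pixel_size,
                polarity = polarity, scan_length = layout$scan_length)
}
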