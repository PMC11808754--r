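# Shared fixtures and independent brute-force oracles.

# a small 5-spot layout over 20 mm: 3 samples, 1 solvent blank, 1 media blank
tiny_layout <- function() {
  default_layout(5, 3000, 20000,
                 role = c("sample", "sample", "sample", "solvent_blank",
                          "media_blank"),
                 labels = c("S1", "S2", "S3", "SB", "MB"))
}

quiet_noise <- function(seed = 1L) {
  noise_model(baseline_level = 0, baseline_dispersion = 0, seed = seed)
}

no_deloc_model <- function() {
  rate_response_model(delocalization_level = 0)
}

# one analyte confined to chosen spots, zero noise, zero delocalization
tiny_run <- function(spots = "S2", base = 1e4, profile = "uniform",
                     rate = 125, noise = quiet_noise(),
                     rate_model = no_deloc_model()) {
  lay <- tiny_layout()
  pan <- list(analyte("C12:0", "C12H24O2", "[M-H]-", base, profile, spots))
  list(layout = lay,
       run = simulate_run(lay, pan, rate = rate, rate_model = rate_model,
                          noise = noise, polarity = "negative"),
       target_mz = adduct_mz("C12H24O2", "[M-H]-"))
}

# brute-force spot integration: explicit loop over pixels
bf_integrate <- function(trace, left, right) {
  total <- 0
  for (i in seq_along(trace$distances)) {
    d <- trace$distances[i]
    if (d >= left && d < right) total <- total + trace$intensity[i]
  }
  total
}

# brute-force per-pixel-mean ratio
bf_ratio <- function(trace, lay, sample_label, ref_labels) {
  iv <- c(lay$spots$center[lay$spots$label == sample_label] -
            lay$spots$width[lay$spots$label == sample_label] / 2,
          lay$spots$center[lay$spots$label == sample_label] +
            lay$spots$width[lay$spots$label == sample_label] / 2)
  num <- c(); den <- c()
  for (i in seq_along(trace$distances)) {
    d <- trace$distances[i]
    if (d >= iv[1] && d < iv[2]) num <- c(num, trace$intensity[i])
    for (lab in ref_labels) {
      c0 <- lay$spots$center[lay$spots$label == lab]
      w0 <- lay$spots$width[lay$spots$label == lab]
      if (d >= c0 - w0 / 2 && d < c0 + w0 / 2) {
        den <- c(den, trace$intensity[i])
      }
    }
  }
  mean(num) / mean(den)
}

random_trace <- function(n = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xic_trace(distances = (seq_len(n) - 1) * 50,
            intensity = stats::runif(n, 0, 100))
}

# multi-species run for feature-detection tests
small_species_run <- function(n_species = 30, seed = 21) {
  lay <- tiny_layout()
  set.seed(seed)
  fms <- unique(paste0("C", sample(10:50, n_species * 2, TRUE),
                       "H", sample(20:100, n_species * 2, TRUE),
                       "O", sample(1:9, n_species * 2, TRUE)))[1:n_species]
  pan <- lapply(seq_along(fms), function(i) {
    analyte(paste0("sp", i), fms[i], "[M-H]-",
            base_intensity = runif(1, 1e3, 1e5), spatial_profile = "uniform",
            spot_labels = c("S1", "S2", "S3")[(i %% 3) + 1])
  })
  list(layout = lay, formulas = fms,
       run = simulate_run(lay, pan, rate = 125,
                          rate_model = no_deloc_model(),
                          noise = quiet_noise(seed), polarity = "negative"))
}
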