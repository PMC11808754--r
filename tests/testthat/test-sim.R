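# Synthetic line-scan generator: profiles, rate response, deposition.

test_that("spatial profiles have the declared shapes and unit integrals", {
  expect_equal(spatial_profile_weight("uniform", 0.0),
               spatial_profile_weight("uniform", 0.9))
  expect_gt(spatial_profile_weight("center", 0.0),
            spatial_profile_weight("center", 0.95))
  expect_gt(spatial_profile_weight("ring", 0.85),
            spatial_profile_weight("ring", 0.0))
  # trapezoidal numerical integration oracle on a 1001-point grid
  u <- seq(-1, 1, length.out = 1001)
  h <- 2 / 1000
  for (kind in c("ring", "uniform", "center")) {
    w <- spatial_profile_weight(kind, u)
    integral <- sum((w[-1] + w[-length(w)]) / 2) * h
    expect_equal(integral, 1.0, tolerance = 1e-3)
  }
  expect_equal(spatial_profile_weight("center", 1.5), 0)
  expect_error(spatial_profile_weight("spiral", 0), "unknown spatial profile")
})

test_that("rate scaling reproduces the inverse-signal law and the knee", {
  m <- rate_response_model(reference_rate = 50, signal_exponent = 1,
                           delocalization_knee = 125,
                           delocalization_drop = 0.60, slowest_rate = 50)
  expect_equal(rate_scaling(m, 50)$signal_factor, 1.0)
  expect_equal(rate_scaling(m, 100)$signal_factor, 0.5)
  # constant delocalized signal beyond the knee
  expect_equal(rate_scaling(m, 150)$delocalization_factor,
               rate_scaling(m, 225)$delocalization_factor)
  # 60% decrease between the slowest rate and the knee
  expect_equal(rate_scaling(m, 125)$delocalization_factor /
                 rate_scaling(m, 50)$delocalization_factor, 0.40)
  expect_error(rate_scaling(m, 0), "> 0")
  expect_error(rate_scaling(m, -10), "> 0")
})

test_that("pixel count is ceiling(scan_length / pixel_size)", {
  lay <- default_layout(11, 3000, 50000, offset = 2500, scan_length = 55000)
  pan <- list(analyte("C12:0", "C12H24O2", "[M-H]-", 1e3, "uniform", "Spot 1"))
  run <- simulate_run(lay, pan, rate = 125, pixel_size = 50,
                      noise = quiet_noise(), polarity = "negative")
  expect_equal(length(run), 1100L)
  expect_equal(run$distances[1100], 54950)
})

test_that("with zero noise and delocalization, signal stays inside the spot", {
  fx <- tiny_run(spots = "S2")
  tr <- extract_xic(fx$run, fx$target_mz, 10)
  iv <- c(fx$layout$spots$center[2] - 1500, fx$layout$spots$center[2] + 1500)
  inside <- tr$distances >= iv[1] & tr$distances < iv[2]
  expect_true(all(tr$intensity[!inside] == 0))
  expect_gt(sum(tr$intensity[inside]), 0)
  # 100% of the integral within the declared bounds
  expect_equal(sum(tr$intensity[inside]), sum(tr$intensity))
})

test_that("total deposited intensity is conserved for every profile", {
  # oracle: each profile integrates to 1 over u in [-1,1], so the pixel
  # sum approximates base * n_pixels_in_spot / 2
  for (profile in c("uniform", "ring", "center")) {
    fx <- tiny_run(spots = "S2", base = 1e4, profile = profile, rate = 50)
    tr <- extract_xic(fx$run, fx$target_mz, 10)
    n_in <- sum(tr$distances >= fx$layout$spots$center[2] - 1500 &
                  tr$distances < fx$layout$spots$center[2] + 1500)
    expect_equal(sum(tr$intensity), 1e4 * n_in / 2,
                 tolerance = 0.005)
  }
})

test_that("per-pixel signal never increases with rate", {
  rates <- c(50, 75, 100, 150, 225)
  peaks <- vapply(rates, function(r) {
    fx <- tiny_run(spots = "S2", rate = r)
    max(extract_xic(fx$run, fx$target_mz, 10)$intensity)
  }, numeric(1L))
  expect_true(all(diff(peaks) <= 0))
})

test_that("identical seeds reproduce identical runs bit-for-bit", {
  lay <- tiny_layout()
  pan <- list(analyte("C12:0", "C12H24O2", "[M-H]-", 1e4, "ring", "S1"))
  mk <- function() simulate_run(lay, pan, rate = 125,
                                noise = noise_model(20, 5, seed = 77,
                                                    mz_jitter_ppm = 1),
                                polarity = "negative")
  r1 <- mk(); r2 <- mk()
  expect_identical(lapply(r1$spectra, `[[`, "intensity"),
                   lapply(r2$spectra, `[[`, "intensity"))
  expect_identical(lapply(r1$spectra, `[[`, "mz"),
                   lapply(r2$spectra, `[[`, "mz"))
  # and a different seed changes the noise
  r3 <- simulate_run(lay, pan, rate = 125,
                     noise = noise_model(20, 5, seed = 78),
                     polarity = "negative")
  expect_false(identical(lapply(r1$spectra, `[[`, "intensity"),
                         lapply(r3$spectra, `[[`, "intensity")))
})

test_that("unknown spot labels and invalid geometry are rejected", {
  lay <- tiny_layout()
  ghost <- list(analyte("x", "C6H12O6", "[M-H]-", 10, "uniform", "S9"))
  expect_error(simulate_run(lay, ghost, noise = quiet_noise()),
               "absent")
  expect_error(simulate_run(lay, list(), rate = -5, noise = quiet_noise()),
               "'rate'")
  expect_error(analyte("x", "C6H12O6", "[M-H]-", -1), ">= 0")
  expect_error(rate_response_model(delocalization_drop = 1.2), "\\[0, 1\\)")
  expect_error(noise_model(baseline_level = -1), ">= 0")
})

test_that("the lock-mass species is present at every pixel", {
  fx <- tiny_run(spots = "S3")
  lk <- extract_xic(fx$run, lockmass_mz("negative"), 10)
  expect_true(all(lk$intensity > 0))
  # constant across the scan in the absence of noise
  expect_equal(max(lk$intensity), min(lk$intensity))
})
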