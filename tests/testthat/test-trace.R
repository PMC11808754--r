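# Distance-domain traces, lock-mass correction, spatial normalization.

test_that("XICs over a disjoint window partition add up to the TIC", {
  fx <- tiny_run(spots = c("S1", "S3"), noise = noise_model(15, 4, seed = 8))
  run <- fx$run
  tic <- total_ion_trace(run)
  # partition the full mass range into disjoint fixed-width windows
  all_mz <- sort(unique(unlist(lapply(run$spectra, `[[`, "mz"))))
  edges <- seq(min(all_mz) - 1, max(all_mz) + 1, length.out = 12)
  summed <- numeric(length(run))
  for (k in seq_len(length(edges) - 1)) {
    lo <- edges[k]; hi <- edges[k + 1]
    part <- vapply(run$spectra, function(s) {
      sum(s$intensity[s$mz >= lo & s$mz < hi])
    }, numeric(1L))
    summed <- summed + part
  }
  expect_equal(summed, tic$intensity, tolerance = 1e-12)
  # TIC dominates any single XIC pointwise
  xic <- extract_xic(run, fx$target_mz, 10)
  expect_true(all(tic$intensity - xic$intensity >= -1e-9))
})

test_that("an empty window yields an all-zero trace with a warning", {
  fx <- tiny_run()
  expect_warning(tr <- extract_xic(fx$run, 999.9, 5), "all-zero")
  expect_true(all(tr$intensity == 0))
})

test_that("an all-zero run yields an all-zero TIC", {
  s <- lapply(1:4, function(i) mass_spectrum(c(100, 200), c(0, 0)))
  run <- line_scan_run(s, (0:3) * 50, 125, 50, polarity = "negative")
  expect_true(all(total_ion_trace(run)$intensity == 0))
})

test_that("lock-mass correction recovers planted multiplicative shifts", {
  fx <- tiny_run(spots = "S2", noise = quiet_noise(3))
  ref <- lockmass_mz("negative")
  for (shift_ppm in c(10, 20, -15)) {
    shifted <- lapply(fx$run$spectra, function(s) {
      mass_spectrum(s$mz * (1 + shift_ppm * 1e-6), s$intensity)
    })
    runS <- line_scan_run(shifted, fx$run$distances, 125, 50, "negative",
                          fx$run$scan_length)
    runC <- lockmass_correct(runS, ref)
    resid <- attr(runC, "lockmass_residual_ppm")
    expect_lte(max(abs(resid), na.rm = TRUE), 0.5)
    err <- abs(runC$spectra[[7]]$mz - fx$run$spectra[[7]]$mz) /
      fx$run$spectra[[7]]$mz * 1e6
    expect_lte(max(err), 0.1)
  }
  # already calibrated: near-identity
  runC0 <- lockmass_correct(fx$run, ref)
  err0 <- abs(runC0$spectra[[1]]$mz - fx$run$spectra[[1]]$mz) /
    fx$run$spectra[[1]]$mz * 1e6
  expect_lte(max(err0), 0.1)
})

test_that("a missing lock peak rejects with a per-pixel diagnostic", {
  s <- lapply(1:10, function(i) mass_spectrum(c(100, 200), c(5, 5)))
  run <- line_scan_run(s, (0:9) * 50, 125, 50, polarity = "negative")
  err <- tryCatch(lockmass_correct(run, lockmass_mz("negative")),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "0.0% of pixels")
  expect_true(is.data.frame(err$diagnostic))
  expect_equal(nrow(err$diagnostic), 10L)
})

test_that("pixels without a lock peak inherit the nearest correction", {
  fx <- tiny_run(spots = "S2", noise = quiet_noise(3))
  ref <- lockmass_mz("negative")
  # drop the lock peak from one pixel, shift everything by 10 ppm
  spectra <- lapply(seq_along(fx$run$spectra), function(i) {
    s <- fx$run$spectra[[i]]
    mz <- s$mz * (1 + 1e-5); ii <- s$intensity
    if (i == 5L) {
      keep <- abs(mz - ref) / ref * 1e6 > 50
      mz <- mz[keep]; ii <- ii[keep]
    }
    mass_spectrum(mz, ii)
  })
  runS <- line_scan_run(spectra, fx$run$distances, 125, 50, "negative",
                        fx$run$scan_length)
  runC <- lockmass_correct(runS, ref)
  # pixel 5 still corrected via its neighbour's factor
  orig <- fx$run$spectra[[5]]$mz
  keep <- abs(orig * (1 + 1e-5) - ref) / ref * 1e6 > 50
  err <- abs(runC$spectra[[5]]$mz - orig[keep]) / orig[keep] * 1e6
  expect_lte(max(err), 0.1)
})

test_that("spatial normalization is identity under a constant lock trace", {
  fx <- tiny_run(spots = "S2")
  lk <- extract_xic(fx$run, lockmass_mz("negative"), 10)
  tr <- extract_xic(fx$run, fx$target_mz, 10)
  nrm <- spatial_normalize(tr, lk)
  expect_equal(nrm$intensity, tr$intensity, tolerance = 1e-12)
  expect_true(nrm$normalized)
})

test_that("co-varying spray drift is flattened by normalization", {
  n <- 100
  d <- (0:(n - 1)) * 50
  drift <- c(rep(1, n / 2), rep(2, n / 2))  # spray doubles mid-scan
  lock <- xic_trace(d, 1000 * drift)
  aly <- xic_trace(d, 80 * drift)
  nrm <- spatial_normalize(aly, lock)
  # flat after normalization (up to the median-smoothing edge of the step)
  expect_lt(diff(range(nrm$intensity[c(1:45, 56:100)])), 1e-9)
  # overall scale preserved: mean intensity unchanged by normalization
  expect_equal(mean(nrm$intensity), mean(aly$intensity), tolerance = 0.05)
  # idempotent
  lock2 <- spatial_normalize(lock, lock)
  nrm2 <- spatial_normalize(nrm, lock2)
  expect_equal(nrm2$intensity, nrm$intensity, tolerance = 1e-9)
})

test_that("spot-to-spot ratios survive normalization with a constant lock", {
  fx <- tiny_run(spots = c("S1", "S3"))
  lk <- extract_xic(fx$run, lockmass_mz("negative"), 10)
  tr <- extract_xic(fx$run, fx$target_mz, 10)
  nrm <- spatial_normalize(tr, lk)
  r_before <- integrate_spot(tr, "S1", fx$layout) /
    integrate_spot(tr, "S3", fx$layout)
  r_after <- integrate_spot(nrm, "S1", fx$layout) /
    integrate_spot(nrm, "S3", fx$layout)
  expect_equal(r_after, r_before, tolerance = 1e-12)
})

test_that("a zero lock trace is rejected with the offending pixels", {
  d <- (0:9) * 50
  lock <- xic_trace(d, c(rep(100, 3), rep(0, 4), rep(100, 3)))
  aly <- xic_trace(d, rep(1, 10))
  expect_error(spatial_normalize(aly, lock, smooth = 1), "pixel")
})
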