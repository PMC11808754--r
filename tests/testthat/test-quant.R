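# Spot integration, signal ratio, blank handling, reproducibility.

test_that("spot integration matches a brute-force loop on random traces", {
  set.seed(101)
  for (i in 1:1000) {
    tr <- random_trace(n = sample(20:80, 1))
    left <- runif(1, 0, max(tr$distances) / 2)
    right <- left + runif(1, 100, 1500)
    got <- tryCatch(integrate_spot(tr, c(left, right)), error = identity)
    if (inherits(got, "error")) {
      expect_equal(bf_integrate(tr, left, right), 0)
    } else {
      expect_equal(got, bf_integrate(tr, left, right), tolerance = 1e-12)
    }
  }
})

test_that("integration partitions: spot + complement = total", {
  tr <- random_trace(400, seed = 7)
  lay <- tiny_layout()
  inside <- integrate_spot(tr, "S2", lay)
  iv <- c(lay$spots$center[2] - 1500, lay$spots$center[2] + 1500)
  outside <- sum(tr$intensity[tr$distances < iv[1] | tr$distances >= iv[2]])
  expect_equal(inside + outside, sum(tr$intensity), tolerance = 1e-12)
  # all-zero trace integrates to 0
  z <- xic_trace(tr$distances, rep(0, length(tr$distances)))
  expect_equal(integrate_spot(z, "S2", lay), 0)
  expect_error(integrate_spot(tr, c(1e6, 1e6 + 10)), "no pixels")
})

test_that("signal ratio equals the per-pixel-mean oracle and basic identities", {
  lay <- tiny_layout()
  set.seed(55)
  for (i in 1:200) {
    tr <- random_trace(n = 400)
    got <- signal_ratio(tr, lay, "S1", reference = "solvent_blank")
    expect_equal(got, bf_ratio(tr, lay, "S1", "SB"), tolerance = 1e-9)
  }
  # self-ratio: reference region = the sample region itself
  tr <- random_trace(400, seed = 9)
  expect_equal(signal_ratio(tr, lay, "S1", reference = "S1"), 1.0)
  # constructed 10x contrast
  d <- (0:399) * 50
  ii <- rep(1, 400)
  iv <- c(lay$spots$center[1] - 1500, lay$spots$center[1] + 1500)
  ii[d >= iv[1] & d < iv[2]] <- 10
  tr10 <- xic_trace(d, ii)
  expect_equal(signal_ratio(tr10, lay, "S1", reference = "SB"), 10.0)
  # invariance under global rescaling
  tr_scaled <- xic_trace(tr$distances, tr$intensity * 1e4)
  expect_equal(signal_ratio(tr_scaled, lay, "S1"),
               signal_ratio(tr, lay, "S1"), tolerance = 1e-9)
  # gaps reference also supported
  expect_gt(signal_ratio(tr10, lay, "S1", reference = "gaps"), 1)
})

test_that("media-blank subtraction floors at zero and keeps the blank row", {
  ft <- feature_table(rbind(c(100, 10), c(50, 80), c(30, 30)),
                      c("S1", "S2", "MB"), c(199.17, 143.11))
  out <- blank_subtract(ft, "MB")
  expect_equal(unname(out$values[1, ]), c(70, 0))
  expect_equal(unname(out$values[2, ]), c(20, 50))
  expect_equal(unname(out$values[3, ]), c(0, 0))
  expect_equal(out$stage, "blank_subtracted")
  expect_true("MB" %in% out$spot_labels)
  # all-zero blank leaves values unchanged (stage updated)
  ft0 <- feature_table(rbind(c(100, 10), c(0, 0)), c("S1", "MB"),
                       c(199.17, 143.11))
  out0 <- blank_subtract(ft0, "MB")
  expect_equal(out0$values[1, ], ft0$values[1, ])
  expect_error(blank_subtract(ft, "nope"), "not present")
})

test_that("analyte normalization is columnwise, idempotent, order-preserving", {
  ft <- feature_table(cbind(c(70, 35, 0), c(5, 10, 2)), c("a", "b", "c"),
                      c(100.1, 200.2), stage = "blank_subtracted")
  out <- analyte_normalize(ft)
  expect_equal(unname(out$values[, 1]), c(1, 0.5, 0))
  expect_equal(unname(out$values[, 2]), c(0.5, 1, 0.2))
  expect_equal(out$feature_mzs, ft$feature_mzs)
  out2 <- analyte_normalize(out)
  expect_equal(out2$values, out$values, tolerance = 1e-12)
  # all-zero column warns and stays zero
  ftz <- feature_table(cbind(c(1, 2), c(0, 0)), c("a", "b"), c(1, 2))
  expect_warning(oz <- analyte_normalize(ftz), "all-zero")
  expect_equal(unname(oz$values[, 2]), c(0, 0))
})

test_that("percent CV matches the n-1 definition and is scale invariant", {
  expect_equal(percent_cv(c(5, 5, 5)), 0)
  expect_equal(percent_cv(c(1, 2, 3)), 50)  # sd = 1, mean = 2
  set.seed(12)
  x <- runif(8, 1, 10)
  for (k in c(0.001, 3, 1e5)) {
    expect_equal(percent_cv(k * x), percent_cv(x), tolerance = 1e-9)
  }
  expect_error(percent_cv(5), ">= 2")
  expect_error(percent_cv(c(-2, 2)), "mean")
})

test_that("aggregate titers match a brute-force group-sum oracle", {
  set.seed(31)
  for (i in 1:50) {
    n_spot <- 6; n_feat <- 8
    vals <- matrix(runif(n_spot * n_feat, 0, 100), n_spot)
    labs <- paste0("s", 1:n_spot)
    ft <- feature_table(vals, labs, seq_len(n_feat))
    gm <- stats::setNames(rep(c("g1", "g2"), each = 3), labs)
    idx <- sample(n_feat, 3)
    got <- aggregate_titer(ft, idx, gm)
    for (g in c("g1", "g2")) {
      rows <- which(gm == g)
      sums <- vapply(rows, function(r) sum(vals[r, idx]), numeric(1))
      expect_equal(got$mean[got$group == g], mean(sums), tolerance = 1e-12)
      expect_equal(got$sd[got$group == g], stats::sd(sums), tolerance = 1e-12)
    }
  }
  # one feature, one replicate: titer equals the cell; identical reps: sd 0
  ft1 <- feature_table(matrix(c(7, 7), 2), c("x", "y"), 1)
  t1 <- aggregate_titer(ft1, 1, c(x = "g", y = "g"))
  expect_equal(t1$mean, 7); expect_equal(t1$sd, 0)
  t2 <- aggregate_titer(ft1, 1, c(x = "g1"))
  expect_equal(t2$mean, 7); expect_true(is.na(t2$sd))
  expect_error(aggregate_titer(ft1, integer(0), c(x = "g")), "empty")
})

test_that("planted relative abundances are recovered after normalization", {
  lay <- tiny_layout()
  rel <- c(S1 = 1.0, S2 = 0.5, S3 = 0.25)
  pan <- lapply(names(rel), function(lab) {
    analyte(paste0("C12:0@", lab), "C12H24O2", "[M-H]-", 2e4 * rel[[lab]],
            "uniform", lab)
  })
  run <- simulate_run(lay, pan, rate = 125, rate_model = no_deloc_model(),
                      noise = quiet_noise(), polarity = "negative")
  tr <- extract_xic(run, adduct_mz("C12H24O2", "[M-H]-"), 10)
  vals <- vapply(names(rel), function(lab) integrate_spot(tr, lab, lay),
                 numeric(1))
  ft <- feature_table(matrix(vals, ncol = 1), names(rel), 199.17)
  nrm <- suppressWarnings(analyte_normalize(ft))
  expect_equal(unname(nrm$values[, 1]), unname(rel), tolerance = 0.01)
})

test_that("replicate %CV stays below 10% at 5% multiplicative noise", {
  # 3 strains x 3 replicates with log-normal 5% replicate variability
  set.seed(77)
  n_feat <- 20
  base <- runif(n_feat, 1e3, 1e5)
  labs <- paste0(rep(c("A", "B", "C"), each = 3), 1:3)
  vals <- t(vapply(labs, function(l) base * rlnorm(n_feat, 0, 0.05),
                   numeric(n_feat)))
  ft <- feature_table(vals, labs, seq_len(n_feat))
  gm <- stats::setNames(substr(labs, 1, 1), labs)
  rep_cv <- cv_report(ft, gm)
  expect_true(all(rep_cv$per_group_cv >= 0))
  expect_lte(rep_cv$overall_mean_cv, 10)
})
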