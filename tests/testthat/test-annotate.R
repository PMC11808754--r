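# Formula parsing, mass arithmetic, envelopes and panel annotation.

test_that("monoisotopic masses match element-sum oracles", {
  # frozen from independent summation of NIST lightest-isotope masses
  expect_equal(monoisotopic_mass("H2O"),
               2 * 1.0078250319 + 15.9949146221, tolerance = 1e-9)
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("C12H24O2"),
               12 * 12 + 24 * 1.0078250319 + 2 * 15.9949146221,
               tolerance = 1e-9)
  expect_equal(monoisotopic_mass("C12H24O2"), 200.1776, tolerance = 1e-4)
  # multiplicity and repeated elements
  expect_equal(monoisotopic_mass("CH3CH3"), monoisotopic_mass("C2H6"))
})

test_that("formula parsing rejects malformed and unknown input", {
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("Xx12"), "unsupported element")
  expect_error(parse_formula("C12#"), "cannot parse")
  expect_error(monoisotopic_mass(""), "non-empty")
})

test_that("adduct m/z arithmetic accounts for proton and electron mass", {
  m <- monoisotopic_mass("C28H37N5O7")
  expect_equal(adduct_mz("C28H37N5O7", "[M+H]+"), m + 1.0072765,
               tolerance = 1e-6)
  expect_equal(adduct_mz("C12H24O2", "[M-H]-"),
               monoisotopic_mass("C12H24O2") - 1.0073, tolerance = 1e-4)
  # charge ordering: doubly protonated sits below singly protonated
  expect_lt(adduct_mz("C50H73N15O11", "[M+2H]2+"),
            adduct_mz("C50H73N15O11", "[M+H]+"))
  expect_error(adduct_mz(100, "[M+Banana]+"), "unsupported adduct")
  # lock-mass defaults come from the formula in both polarities
  expect_equal(lockmass_mz("positive"), adduct_mz("C28H37N5O7", "[M+H]+"))
  expect_equal(lockmass_mz("negative"), adduct_mz("C28H37N5O7", "[M-H]-"))
})

test_that("isotopic envelopes follow natural abundances", {
  env <- theoretical_envelope("C1", n_isotopologues = 2)
  expect_equal(env$abundance[2], 0.0107 / 0.9893, tolerance = 1e-6)
  expect_equal(env$abundance[2], 0.0108, tolerance = 2e-3)
  # max-normalized, non-negative, and M+1 grows with carbon count
  env100 <- theoretical_envelope("C100", n_isotopologues = 3)
  expect_true(all(env100$abundance >= 0))
  expect_equal(max(env100$abundance), 1)
  expect_gt(env100$abundance[2], env$abundance[2])
  # isotopologue spacing ~ 1 neutron; halved for doubly charged ions
  e1 <- theoretical_envelope("C50H73N15O11", "[M+H]+", 3)
  e2 <- theoretical_envelope("C50H73N15O11", "[M+2H]2+", 3)
  expect_equal(diff(e1$mz)[1], 1.0034, tolerance = 1e-3)
  expect_equal(diff(e2$mz)[1], diff(e1$mz)[1] / 2, tolerance = 1e-3)
  expect_error(theoretical_envelope("C6H12O6", n_isotopologues = 1), ">= 2")
})

test_that("ppm error is zero on identity and antisymmetric to first order", {
  for (x in c(100, 554.26, 1200)) expect_identical(ppm_error(x, x), 0)
  a <- 200.1776; b <- a * (1 + 3e-6)
  expect_equal(ppm_error(b, a), -ppm_error(a, b), tolerance = 1e-4)
})

test_that("envelope cosine similarity is scale invariant and bounded", {
  th <- theoretical_envelope("C12H24O2", "[M-H]-", 3)
  expect_equal(envelope_similarity(th, th), 1.0)
  scaled <- th; scaled$abundance <- scaled$abundance * 731
  expect_equal(envelope_similarity(scaled, th), 1.0)
  # orthogonal abundance vectors
  orth <- th; orth$abundance <- c(0, 1, 0); th2 <- th
  th2$abundance <- c(1, 0, 0)
  expect_equal(envelope_similarity(orth, th2), 0)
  # fewer than 2 matched positions -> 0 with a warning
  off <- data.frame(mz = th$mz + 0.5, abundance = th$abundance)
  expect_warning(s <- envelope_similarity(off, th), "fewer than 2")
  expect_equal(s, 0)
})

test_that("annotation applies the 5 ppm / 0.8 similarity thresholds and ranking", {
  panel <- panel_ffa()
  mz <- adduct_mz("C12H24O2", "[M-H]-")
  env <- theoretical_envelope("C12H24O2", "[M-H]-", 3)
  hit <- annotate_feature(mz, env, panel)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$compound, "C12:0")
  expect_equal(hit$ppm_error, 0)
  expect_equal(hit$envelope_similarity, 1)
  # 10 ppm away from the only candidate -> empty
  expect_equal(nrow(annotate_feature(mz * (1 + 10e-6), env, panel)), 0L)
  # poor envelope match is filtered even at perfect mass
  bad_env <- env; bad_env$abundance <- c(0.1, 1, 0.9)
  expect_equal(nrow(annotate_feature(mz, bad_env, panel)), 0L)
})

test_that("planted compounds are recovered with zero decoy hits at 2 ppm jitter", {
  lay <- tiny_layout()
  names5 <- c("C8:0", "C10:0", "C12:0", "C14:0", "C14:1")
  fm5 <- c("C8H16O2", "C10H20O2", "C12H24O2", "C14H28O2", "C14H26O2")
  pan <- lapply(seq_along(names5), function(i) {
    analyte(names5[i], fm5[i], "[M-H]-", 2e4, "uniform",
            c("S1", "S2", "S3"))
  })
  true_mz <- vapply(fm5, adduct_mz, 0, adduct = "[M-H]-")
  run <- simulate_run(lay, pan, rate = 125, rate_model = no_deloc_model(),
                      noise = noise_model(0, 0, seed = 11, mz_jitter_ppm = 2),
                      polarity = "negative")
  search_panel <- c(
    compound_panel(names5, fm5, "[M-H]-"),
    decoy_panel(50, seed = 19, exclude = true_mz, exclude_ppm = 20))
  class(search_panel) <- "compound_panel"
  ft <- detect_features(run, lay, top_n = 500)
  hits <- annotate_features(ft, search_panel, run = run, layout = lay)
  # every planted compound recovered as a hit on its own feature
  for (i in seq_along(names5)) {
    h <- hits[abs(hits$feature_mz - true_mz[i]) / true_mz[i] * 1e6 < 5, ]
    expect_true(names5[i] %in% h$compound)
  }
  # and no decoy passes the joint thresholds anywhere
  expect_equal(sum(grepl("^decoy_", hits$compound)), 0L)
})

test_that("bundled panels compute sensible reference values", {
  pep <- panel_peptides()
  expect_equal(pep[["leucine enkephalin"]]$theoretical_mz[["[M+H]+"]],
               556.2766, tolerance = 1e-4)
  expect_equal(pep[["bradykinin"]]$theoretical_mz[["[M+2H]2+"]],
               530.7879, tolerance = 1e-3)
  carbs <- panel_carbohydrates()
  expect_equal(carbs[["M2"]]$theoretical_mz[["[M+Na]+"]], 365.1054,
               tolerance = 1e-3)
  expect_equal(length(panel_ffa()), 6L)
})
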