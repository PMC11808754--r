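#' Build a compound panel
#'
#' A panel is the local stand-in for an online compound database: for
#' each compound name and formula, every requested adduct's theoretical
#' m/z and isotopic envelope is computed (never hard-coded) and stored
#' for matching against observed features.
#'
#' @param name character vector of compound names.
#' @param formula molecular formulas, same length.
#' @param adducts list of adduct-label vectors (recycled if a single
#'   vector is given).
#' @param n_isotopologues envelope peaks computed per adduct.
#' @return A \code{compound_panel}: list of records with fields
#'   \code{name}, \code{formula}, \code{adducts}, \code{theoretical_mz}
#'   (named by adduct) and \code{envelope} (named list of data.frames).
#' @export
compound_panel <- function(name, formula, adducts, n_isotopologues = 3L) {
  stopifnot(length(name) == length(formula))
  if (!is.list(adducts)) adducts <- rep(list(adducts), length(name))
  stopifnot(length(adducts) == length(name))
  records <- mapply(function(nm, fm, ads) {
    mzs <- vapply(ads, function(a) adduct_mz(fm, a), numeric(1L))
    names(mzs) <- ads
    envs <- lapply(ads, function(a) theoretical_envelope(fm, a, n_isotopologues))
    names(envs) <- ads
    list(name = nm, formula = fm, adducts = ads, theoretical_mz = mzs,
         envelope = envs)
  }, name, formula, adducts, SIMPLIFY = FALSE)
  names(records) <- name
  structure(records, class = "compound_panel")
}

#' @export
print.compound_panel <- function(x, ...) {
  cat(sprintf("compound_panel: %d compounds\n", length(x)))
  for (r in x) {
    cat(sprintf("  %-22s %-14s %s\n", r$name, r$formula,
                paste(sprintf("%s %.4f", r$adducts, r$theoretical_mz),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Bundled standard panels
#'
#' The analytical standard mixes used to validate the line-scan workflow,
#' as formula lists with all theoretical values computed on the fly:
#' \itemize{
#'   \item \code{panel_peptides()}: VTV, bradykinin, angiotensin II,
#'     substance P, leucine enkephalin (\code{[M+H]+} and
#'     \code{[M+2H]2+} where sensible), positive mode;
#'   \item \code{panel_carbohydrates()}: the maltose series M2–M6 as
#'     sodium adducts, positive mode;
#'   \item \code{panel_exogenous()}: caffeine, sulfadimethoxine,
#'     sulfaguanidine, reserpine, \code{[M+H]+};
#'   \item \code{panel_ffa()}: free fatty acids C8:0, C10:0, C12:0,
#'     C12:1, C14:0, C14:1 as \code{[M-H]-}, negative mode.
#' }
#' @return A [compound_panel()].
#' @export
panel_peptides <- function() {
  compound_panel(
    name = c("VTV", "bradykinin", "angiotensin II", "substance P",
             "leucine enkephalin"),
    formula = c("C14H27N3O5", "C50H73N15O11", "C50H71N13O12",
                "C63H98N18O13S", "C28H37N5O7"),
    adducts = list("[M+H]+", c("[M+H]+", "[M+2H]2+"), c("[M+H]+", "[M+2H]2+"),
                   c("[M+H]+", "[M+2H]2+"), "[M+H]+"))
}

#' @rdname panel_peptides
#' @export
panel_carbohydrates <- function() {
  # maltose series: n glucose units minus (n - 1) waters
  glc <- c(C = 6L, H = 12L, O = 6L)
  fm <- vapply(2:6, function(n) {
    counts <- c(C = glc[["C"]] * n, H = glc[["H"]] * n - 2L * (n - 1L),
                O = glc[["O"]] * n - (n - 1L))
    paste0("C", counts[["C"]], "H", counts[["H"]], "O", counts[["O"]])
  }, character(1L))
  compound_panel(paste0("M", 2:6), fm, "[M+Na]+")
}

#' @rdname panel_peptides
#' @export
panel_exogenous <- function() {
  compound_panel(
    name = c("caffeine", "sulfadimethoxine", "sulfaguanidine", "reserpine"),
    formula = c("C8H10N4O2", "C12H14N4O4S", "C7H10N4O2S", "C33H40N2O9"),
    adducts = "[M+H]+")
}

#' @rdname panel_peptides
#' @export
panel_ffa <- function() {
  compound_panel(
    name = c("C8:0", "C10:0", "C12:0", "C12:1", "C14:0", "C14:1"),
    formula = c("C8H16O2", "C10H20O2", "C12H24O2", "C12H22O2",
                "C14H28O2", "C14H26O2"),
    adducts = "[M-H]-")
}

#' Random decoy compound panel
#'
#' Generates plausible but arbitrary CHNO formulas for specificity
#' testing of the annotation thresholds.  Decoys whose adduct m/z falls
#' within \code{exclude_ppm} of any m/z in \code{exclude} are dropped and
#' redrawn, so a decoy can never be a true match by construction.
#'
#' @param n number of decoys.
#' @param adduct adduct label given to every decoy.
#' @param seed RNG seed.
#' @param exclude numeric m/z values decoys must stay away from.
#' @param exclude_ppm exclusion half-width in ppm.
#' @return A [compound_panel()].
#' @export
decoy_panel <- function(n = 50L, adduct = "[M-H]-", seed = 42L,
                        exclude = numeric(0), exclude_ppm = 20) {
  set.seed(seed)
  records <- list()
  tries <- 0L
  while (length(records) < n && tries < 50L * n) {
    tries <- tries + 1L
    nc <- sample(5:40, 1L)
    nh <- sample(max(2L, nc %/% 2L):(2L * nc + 2L), 1L)
    nn <- sample(0:4, 1L)
    no <- sample(1:8, 1L)
    fm <- paste0("C", nc, "H", nh,
                 if (nn > 0L) paste0("N", nn) else "", "O", no)
    mz <- adduct_mz(fm, adduct)
    if (length(exclude) &&
        any(abs(mz - exclude) / exclude * 1e6 <= exclude_ppm)) next
    nm <- paste0("decoy_", length(records) + 1L)
    records[[nm]] <- fm
  }
  compound_panel(names(records), unlist(records), adduct)
}

#' Isotopic-envelope cosine similarity
#'
#' Matches observed envelope peaks to theoretical isotopologue positions
#' by m/z (within \code{match_ppm}) and returns the cosine of the matched
#' abundance vectors — a scale-invariant score in \code{[0, 1]}.  Fewer
#' than 2 matched positions yields 0 with a warning.
#'
#' @param observed data.frame with columns \code{mz}, \code{abundance}.
#' @param theoretical data.frame as from [theoretical_envelope()].
#' @param match_ppm per-isotopologue matching tolerance, ppm.
#' @return Similarity in \code{[0, 1]}.
#' @export
envelope_similarity <- function(observed, theoretical, match_ppm = 10) {
  obs_ab <- rep(0, nrow(theoretical))
  matched <- 0L
  for (i in seq_len(nrow(theoretical))) {
    d_ppm <- abs(observed$mz - theoretical$mz[i]) / theoretical$mz[i] * 1e6
    j <- which.min(d_ppm)
    if (length(j) && d_ppm[j] <= match_ppm) {
      obs_ab[i] <- observed$abundance[j]
      matched <- matched + 1L
    }
  }
  if (matched < 2L) {
    warning("fewer than 2 matched isotopologue positions; similarity 0",
            call. = FALSE)
    return(0)
  }
  th_ab <- theoretical$abundance
  denom <- sqrt(sum(obs_ab^2)) * sqrt(sum(th_ab^2))
  if (denom == 0) return(0)
  sum(obs_ab * th_ab) / denom
}

#' Observed isotopic envelope of a feature
#'
#' Builds the observed envelope at candidate isotopologue positions by
#' integrating the run's XIC at each theoretical m/z over the sample
#' spots (or the whole line when no layout is given).
#'
#' @param run a [line_scan_run()].
#' @param positions theoretical isotopologue m/z values.
#' @param tol_ppm XIC window, ppm.
#' @param layout optional [spot_layout()]; integration is restricted to
#'   its sample spots.
#' @return data.frame with \code{mz}, \code{abundance} (max-normalized
#'   when any signal is present).
#' @export
observed_envelope <- function(run, positions, tol_ppm = 10, layout = NULL) {
  keep <- if (is.null(layout)) {
    rep(TRUE, length(run$distances))
  } else {
    .in_spots(run$distances, layout,
              layout$spots$label[layout$spots$role == "sample"])
  }
  ab <- vapply(positions, function(mz) {
    tr <- suppressWarnings(extract_xic(run, mz, tol_ppm))
    sum(tr$intensity[keep])
  }, numeric(1L))
  if (max(ab) > 0) ab <- ab / max(ab)
  data.frame(mz = positions, abundance = ab)
}

#' Annotate a feature against a compound panel
#'
#' Candidate compounds are those with any adduct m/z within
#' \code{max_ppm} of the feature m/z; candidates are then filtered by
#' isotopic-envelope similarity (cosine, threshold \code{min_similarity})
#' and ranked by similarity (descending) then absolute ppm error
#' (ascending).  Mirrors the screening thresholds of 5 ppm mass accuracy
#' and 80\% envelope similarity.
#'
#' @param feature_mz observed feature m/z.
#' @param observed_envelope data.frame (\code{mz}, \code{abundance}) of
#'   the observed envelope, or \code{NULL} with \code{run} given, in
#'   which case the envelope is measured at each candidate's theoretical
#'   positions via [observed_envelope()].
#' @param panel a [compound_panel()].
#' @param max_ppm mass threshold, ppm.
#' @param min_similarity envelope similarity threshold.
#' @param run,layout optional run (and layout) used to measure observed
#'   envelopes when \code{observed_envelope} is \code{NULL}.
#' @param match_ppm isotopologue matching tolerance, ppm.
#' @return data.frame of hits: \code{feature_mz}, \code{compound},
#'   \code{adduct}, \code{theoretical_mz}, \code{ppm_error},
#'   \code{envelope_similarity}; zero rows when nothing passes.
#' @export
annotate_feature <- function(feature_mz, observed_envelope = NULL, panel,
                             max_ppm = 5, min_similarity = 0.8,
                             run = NULL, layout = NULL, match_ppm = 10) {
  stopifnot(inherits(panel, "compound_panel"))
  if (!length(panel)) stop("panel is empty", call. = FALSE)
  hits <- list()
  for (rec in panel) {
    for (ad in rec$adducts) {
      th_mz <- rec$theoretical_mz[[ad]]
      err <- (feature_mz - th_mz) / th_mz * 1e6
      if (abs(err) > max_ppm) next
      th_env <- rec$envelope[[ad]]
      obs <- observed_envelope
      if (is.null(obs)) {
        if (is.null(run)) {
          stop("provide 'observed_envelope' or 'run'", call. = FALSE)
        }
        obs <- observed_envelope(run, th_env$mz, layout = layout)
      }
      sim <- suppressWarnings(envelope_similarity(obs, th_env, match_ppm))
      if (sim < min_similarity) next
      hits[[length(hits) + 1L]] <- data.frame(
        feature_mz = feature_mz, compound = rec$name, adduct = ad,
        theoretical_mz = th_mz, ppm_error = err,
        envelope_similarity = sim, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(feature_mz = numeric(0), compound = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0),
                      envelope_similarity = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out[order(-out$envelope_similarity, abs(out$ppm_error)), , drop = FALSE]
}

#' Annotate all features of a table
#'
#' Runs [annotate_feature()] for every feature m/z, measuring observed
#' envelopes from the run when given.
#'
#' @param table a [feature_table()].
#' @param panel a [compound_panel()].
#' @param run,layout optional run and layout for envelope measurement.
#' @param ... passed to [annotate_feature()].
#' @return data.frame of all hits (possibly zero rows).
#' @export
annotate_features <- function(table, panel, run = NULL, layout = NULL, ...) {
  stopifnot(inherits(table, "feature_table"))
  out <- lapply(table$feature_mzs, function(mz) {
    annotate_feature(mz, observed_envelope = NULL, panel = panel,
                     run = run, layout = layout, ...)
  })
  do.call(rbind, out)
}

#' Read a compound panel from CSV/TSV
#'
#' Columns: \code{name}, \code{formula}, \code{adducts} (adduct labels
#' separated by \code{;}).
#'
#' @param path file path (TSV when the extension is \code{.tsv},
#'   otherwise CSV).
#' @return A [compound_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  compound_panel(df$name, df$formula, strsplit(df$adducts, ";[ ]*"))
}
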