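#' Strain-screen fixture configuration
#'
#' Builds the screening design used throughout the package's examples
#' and validation: a 10-spot linear array over 50 mm (3 mm wells) holding
#' three engineered strains x three biological replicates plus one media
#' blank, scanned in negative mode at the optimized 125 µm/s rate.
#' Strain A preferentially produces dodecanoic acid (C12:0) with minor
#' C12:1 / C14:0 / C14:1 side products, strain B produces octanoic acid
#' (C8:0) with a minor C10:0 side product, and strain C is a negative
#' control.  A common membrane lipid (PG 36:2) appears in all strains at
#' similar levels, and a C17 ceramide internal standard is spiked into
#' every spot including the media blank.  Replicate-to-replicate
#' variability is multiplicative log-normal with the given coefficient
#' of variation.
#'
#' @param seed RNG seed for replicate variability and channel noise.
#' @param replicate_cv multiplicative replicate variability (sdlog of the
#'   log-normal factor), default 0.05.
#' @param noise a [noise_model()]; its seed is overridden by \code{seed}.
#' @return List with \code{layout}, \code{panel} (simulation analytes),
#'   \code{group_map} (spot -> strain), \code{media_blank},
#'   \code{annotation_panel}, \code{polarity}, \code{raster_rate},
#'   \code{pixel_size}, \code{lockmass}, \code{noise}, \code{rate_model},
#'   \code{seed}.
#' @export
strain_screen_config <- function(seed = 1L, replicate_cv = 0.05,
                                 noise = noise_model(baseline_level = 20,
                                                     baseline_dispersion = 5)) {
  labels <- c(paste0("A", 1:3), paste0("B", 1:3), paste0("C", 1:3), "MB")
  roles <- c(rep("sample", 9L), "media_blank")
  layout <- default_layout(10L, 3000, 50000, role = roles, labels = labels)
  profiles <- list(
    A = c("C12:0" = 4e4, "C12:1" = 8e3, "C14:0" = 6e3, "C14:1" = 1.2e4,
          "PG 36:2" = 1.5e4),
    B = c("C8:0" = 3e4, "C10:0" = 4e3, "PG 36:2" = 1.5e4),
    C = c("PG 36:2" = 1.5e4))
  formulas <- c("C8:0" = "C8H16O2", "C10:0" = "C10H20O2",
                "C12:0" = "C12H24O2", "C12:1" = "C12H22O2",
                "C14:0" = "C14H28O2", "C14:1" = "C14H26O2",
                "PG 36:2" = "C42H79O10P", "C17 ceramide" = "C35H69NO3")
  set.seed(seed)
  panel <- list()
  for (strain in c("A", "B", "C")) {
    for (rep_i in 1:3) {
      lab <- paste0(strain, rep_i)
      jitter <- stats::rlnorm(length(profiles[[strain]]), 0, replicate_cv)
      for (k in seq_along(profiles[[strain]])) {
        cname <- names(profiles[[strain]])[k]
        panel[[length(panel) + 1L]] <- analyte(
          paste0(cname, "@", lab), formulas[[cname]], "[M-H]-",
          base_intensity = profiles[[strain]][[k]] * jitter[k],
          spatial_profile = "uniform", spot_labels = lab)
      }
    }
  }
  for (lab in labels) {  # internal standard everywhere, media blank included
    panel[[length(panel) + 1L]] <- analyte(
      paste0("C17 ceramide@", lab), formulas[["C17 ceramide"]], "[M-H]-",
      base_intensity = 1e4, spatial_profile = "uniform", spot_labels = lab)
  }
  group_map <- stats::setNames(substr(labels[1:9], 1L, 1L), labels[1:9])
  noise$seed <- as.integer(seed)
  ann <- panel_ffa()
  list(layout = layout, panel = panel, group_map = group_map,
       media_blank = "MB", annotation_panel = ann, polarity = "negative",
       raster_rate = 125, pixel_size = 50,
       lockmass = analyte("leucine enkephalin", "C28H37N5O7", "[M-H]-",
                          base_intensity = 5000,
                          spatial_profile = "uniform"),
       noise = noise, rate_model = rate_response_model(), seed = seed,
       thresholds = list(max_ppm = 5, min_similarity = 0.8, p = 0.05,
                         fc = 2, top_n = 500L))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full line-scan screening pipeline
#'
#' Executes simulate/read -> lock-mass correction -> spatial
#' normalization -> feature detection -> media-blank subtraction ->
#' analyte normalization -> annotation -> statistics (PCA, volcano,
#' replicate \%CV), writing every intermediate artifact and a JSON
#' provenance log to \code{output_dir}.  Any stage failure aborts with
#' the stage named; artifacts written before the failure are retained.
#'
#' @param config a configuration list as from [strain_screen_config()].
#' @param input \code{"simulate"} (default) or a path to an imzML file.
#' @param output_dir directory for artifacts (created if needed).
#' @param comparisons list of \code{c(group_a, group_b)} pairs for
#'   volcano screening; default every non-control group against
#'   \code{"C"} when present.
#' @return Invisible list with the main objects: \code{run},
#'   \code{features_raw}, \code{features_subtracted},
#'   \code{features_normalized}, \code{annotations}, \code{pca},
#'   \code{volcano}, \code{cv}, \code{artifacts}.
#' @export
run_fastpass <- function(config, input = "simulate",
                         output_dir = tempfile("fastpass_"),
                         comparisons = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(name, writer) {
    path <- file.path(output_dir, name)
    writer(path)
    artifacts <<- c(artifacts, path)
    path
  }

  run <- .stage("input", {
    if (identical(input, "simulate")) {
      simulate_run(config$layout, config$panel, rate = config$raster_rate,
                   pixel_size = config$pixel_size,
                   rate_model = config$rate_model, noise = config$noise,
                   lockmass = config$lockmass, polarity = config$polarity)
    } else {
      if (!file.exists(input)) stop("input file not found: ", input)
      read_imzml(input, raster_rate = config$raster_rate,
                 pixel_size = config$pixel_size)
    }
  })

  lock_ref <- adduct_mz(config$lockmass$formula, config$lockmass$adduct)
  run <- .stage("lockmass_correct",
                lockmass_correct(run, reference_mz = lock_ref))
  lock_xic <- .stage("lockmass_xic", extract_xic(run, lock_ref, tol_ppm = 10))
  run_n <- .stage("spatial_normalize", spatial_normalize(run, lock_xic))

  features <- .stage("detect_features",
    detect_features(run_n, config$layout, top_n = config$thresholds$top_n))
  emit("features_raw.tsv", function(p) write_feature_table(features, p))

  feat_sub <- if (!is.null(config$media_blank)) {
    .stage("blank_subtract", blank_subtract(features, config$media_blank))
  } else features
  emit("features_blank_subtracted.tsv",
       function(p) write_feature_table(feat_sub, p))

  feat_norm <- .stage("analyte_normalize",
                      suppressWarnings(analyte_normalize(feat_sub)))
  emit("features_normalized.tsv", function(p) write_feature_table(feat_norm, p))

  annotations <- .stage("annotate", annotate_features(
    feat_sub, config$annotation_panel, run = run_n, layout = config$layout,
    max_ppm = config$thresholds$max_ppm,
    min_similarity = config$thresholds$min_similarity))
  emit("annotations.tsv", function(p) {
    utils::write.table(annotations, p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  })

  pca <- .stage("pca", pca_phenotypes(feat_sub))
  emit("pca_scores.tsv", function(p) {
    utils::write.table(data.frame(spot = rownames(pca$scores), pca$scores),
                       p, sep = "\t", row.names = FALSE, quote = FALSE)
  })
  emit("pca_loadings.tsv", function(p) {
    utils::write.table(data.frame(feature = rownames(pca$loadings),
                                  pca$loadings),
                       p, sep = "\t", row.names = FALSE, quote = FALSE)
  })

  # reproducibility is assessed on raw integrated signals: blank
  # subtraction cancels channels shared with the blank (e.g. the spiked
  # internal standard) and would leave only noise there
  cv <- if (!is.null(config$group_map)) {
    .stage("cv_report", cv_report(features, config$group_map))
  } else NULL
  if (!is.null(cv)) {
    emit("cv_report.json", function(p) {
      jsonlite::write_json(cv, p, auto_unbox = TRUE, digits = NA)
    })
  }

  vol <- NULL
  if (!is.null(config$group_map)) {
    groups <- unique(unname(config$group_map))
    if (is.null(comparisons) && "C" %in% groups) {
      comparisons <- lapply(setdiff(groups, "C"), function(g) c(g, "C"))
    }
    if (!is.null(comparisons)) {
      vol <- lapply(comparisons, function(cmp) {
        ga <- names(config$group_map)[config$group_map == cmp[1L]]
        gb <- names(config$group_map)[config$group_map == cmp[2L]]
        .stage(paste0("volcano_", cmp[1L], "_vs_", cmp[2L]),
               volcano(feat_sub, ga, gb,
                       p_threshold = config$thresholds$p,
                       fc_threshold = config$thresholds$fc))
      })
      names(vol) <- vapply(comparisons,
                           function(cmp) paste0(cmp[1L], "_vs_", cmp[2L]), "")
      for (nm in names(vol)) {
        local({
          nm_ <- nm
          emit(paste0("volcano_", nm_, ".tsv"), function(p) {
            utils::write.table(vol[[nm_]], p, sep = "\t", row.names = FALSE,
                               quote = FALSE)
          })
        })
      }
    }
  }

  emit("provenance.json", function(p) {
    jsonlite::write_json(list(
      package = "fastpass",
      version = as.character(utils::packageVersion("fastpass")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      input = input, seed = config$seed,
      raster_rate_um_s = config$raster_rate,
      pixel_size_um = config$pixel_size,
      polarity = config$polarity,
      thresholds = config$thresholds,
      artifacts = basename(artifacts)), p, auto_unbox = TRUE, digits = NA)
  })

  invisible(list(run = run_n, features_raw = features,
                 features_subtracted = feat_sub,
                 features_normalized = feat_norm,
                 annotations = annotations, pca = pca, volcano = vol,
                 cv = cv, artifacts = artifacts, output_dir = output_dir))
}
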