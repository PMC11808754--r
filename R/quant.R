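#' Construct a feature table
#'
#' A spots x features matrix of integrated intensities with processing
#' provenance (\code{raw}, \code{blank_subtracted} or \code{normalized}).
#'
#' @param values numeric matrix, spots in rows, features in columns.
#' @param spot_labels row labels.
#' @param feature_mzs feature m/z values (column order).
#' @param stage provenance stage.
#' @param spot_roles optional roles per spot (from the layout).
#' @return A \code{feature_table} object.
#' @export
feature_table <- function(values, spot_labels, feature_mzs, stage = "raw",
                          spot_roles = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(spot_labels) ||
      ncol(values) != length(feature_mzs)) {
    stop("matrix dimensions must match label and feature counts", call. = FALSE)
  }
  stage <- match.arg(stage, c("raw", "blank_subtracted", "normalized"))
  if (stage != "raw" && any(values < 0)) {
    stop("blank-subtracted / normalized values must be >= 0", call. = FALSE)
  }
  if (stage == "normalized" && any(values > 1 + 1e-9)) {
    stop("normalized values must lie in [0, 1]", call. = FALSE)
  }
  dimnames(values) <- list(spot_labels, sprintf("mz_%.5f", feature_mzs))
  structure(list(values = values, spot_labels = as.character(spot_labels),
                 feature_mzs = as.numeric(feature_mzs), stage = stage,
                 spot_roles = spot_roles),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d spots x %d features [%s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  as.data.frame(x$values)
}

#' Integrate a trace over a spot interval
#'
#' Sums pixel intensities whose distance lies in the spot's half-open
#' interval \code{[center - width/2, center + width/2)}.  Integrating the
#' signal across pre-established distances is what turns the line scan
#' into per-sample spectral readouts.
#'
#' @param trace an [xic_trace()].
#' @param spot either a spot label (with \code{layout} given), or a
#'   numeric \code{c(left, right)} interval in µm.
#' @param layout a [spot_layout()], required when \code{spot} is a label.
#' @return Summed intensity.
#' @export
integrate_spot <- function(trace, spot, layout = NULL) {
  stopifnot(inherits(trace, "xic_trace"))
  iv <- if (is.character(spot)) {
    if (is.null(layout)) stop("'layout' required when 'spot' is a label", call. = FALSE)
    .spot_interval(layout, spot)
  } else {
    c(left = spot[1L], right = spot[2L])
  }
  inside <- trace$distances >= iv["left"] & trace$distances < iv["right"]
  if (!any(inside)) {
    stop(sprintf("no pixels inside spot interval [%.0f, %.0f)",
                 iv["left"], iv["right"]), call. = FALSE)
  }
  sum(trace$intensity[inside])
}

#' Spot-to-blank signal ratio
#'
#' The raster-rate optimization statistic: the per-pixel mean intensity
#' within a sample spot divided by the per-pixel mean intensity in a
#' reference region.  Per-pixel means (rather than raw sums) keep sample
#' and reference regions of different lengths comparable.  Two reference
#' definitions are provided: the solvent-blank spot intervals
#' (\code{"solvent_blank"}, the default) or the inter-spot gap regions
#' (\code{"gaps"}); the instrument noise floor sits in both, convolved
#' with delocalized analyte signal.
#'
#' @param trace an [xic_trace()].
#' @param layout a [spot_layout()].
#' @param sample_spot label of the sample spot.
#' @param reference \code{"solvent_blank"}, \code{"gaps"}, or a character
#'   vector of explicit spot labels to pool as the reference.
#' @param eps denominator floor as a fraction of the trace maximum
#'   (default 1e-9), guarding all-zero references.
#' @return The signal ratio (dimensionless).
#' @export
signal_ratio <- function(trace, layout, sample_spot,
                         reference = c("solvent_blank", "gaps"), eps = 1e-9) {
  stopifnot(inherits(trace, "xic_trace"), inherits(layout, "spot_layout"))
  if (is.character(reference) && all(reference %in% c("solvent_blank", "gaps"))) {
    reference <- match.arg(reference)
  }
  iv <- .spot_interval(layout, sample_spot)
  in_sample <- trace$distances >= iv["left"] & trace$distances < iv["right"]
  if (!any(in_sample)) stop("sample spot contains no pixels", call. = FALSE)
  in_ref <- if (identical(reference, "solvent_blank")) {
    labs <- layout$spots$label[layout$spots$role == "solvent_blank"]
    if (!length(labs)) stop("layout has no solvent_blank spots", call. = FALSE)
    .in_spots(trace$distances, layout, labs)
  } else if (identical(reference, "gaps")) {
    !.in_spots(trace$distances, layout, layout$spots$label)
  } else {
    .in_spots(trace$distances, layout, reference)
  }
  if (!any(in_ref)) stop("reference region contains no pixels", call. = FALSE)
  floor_val <- eps * max(trace$intensity)
  mean(trace$intensity[in_sample]) / max(mean(trace$intensity[in_ref]), floor_val)
}

#' Media-blank subtraction
#'
#' Subtracts the media-blank row from every feature column so signal
#' profiles reflect the biological sample rather than the growth medium;
#' negatives are floored at 0.  The blank row is retained and flagged.
#'
#' @param table a [feature_table()].
#' @param media_blank_label label of the media-blank spot row.
#' @return A \code{blank_subtracted} [feature_table()] with attribute
#'   \code{"blank_label"}.
#' @export
blank_subtract <- function(table, media_blank_label) {
  stopifnot(inherits(table, "feature_table"))
  i <- match(media_blank_label, table$spot_labels)
  if (is.na(i)) {
    stop("media blank label '", media_blank_label, "' not present in table",
         call. = FALSE)
  }
  blank <- table$values[i, ]
  values <- pmax(sweep(table$values, 2L, blank, "-"), 0)
  out <- feature_table(values, table$spot_labels, table$feature_mzs,
                       stage = "blank_subtracted", spot_roles = table$spot_roles)
  attr(out, "blank_label") <- media_blank_label
  out
}

#' Analyte-by-analyte normalization
#'
#' Divides every feature column by its own maximum, putting each analyte
#' on a relative \code{[0, 1]} scale for cross-sample comparison.
#' All-zero columns are left at zero with a warning.
#'
#' @param table a [feature_table()].
#' @return A \code{normalized} [feature_table()].
#' @export
analyte_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  maxes <- apply(table$values, 2L, max)
  zero <- maxes <= 0
  if (any(zero)) {
    warning(sum(zero), " all-zero feature column(s) left unnormalized",
            call. = FALSE)
    maxes[zero] <- 1
  }
  out <- feature_table(sweep(table$values, 2L, maxes, "/"),
                       table$spot_labels, table$feature_mzs,
                       stage = "normalized", spot_roles = table$spot_roles)
  attr(out, "blank_label") <- attr(table, "blank_label")
  out
}

#' Percent coefficient of variation
#'
#' \code{100 * sd / mean} with the sample (n - 1) standard deviation; the
#' reproducibility metric for replicate spot measurements.
#'
#' @param values numeric vector of replicate intensities (n >= 2, mean > 0).
#' @return \%CV.
#' @examples
#' percent_cv(c(1, 2, 3))  # 50
#' @export
percent_cv <- function(values) {
  if (length(values) < 2L) stop("need >= 2 replicates", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("mean must be > 0 for %CV", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Replicate reproducibility report
#'
#' Per replicate group, the \%CV of each feature across the group's spots,
#' averaged over features; plus the overall mean across groups.  A \%CV
#' only measures reproducibility where the analyte is actually detected,
#' so features whose group mean falls below \code{min_signal_fraction}
#' of that feature's maximum group mean (background-only channels for
#' that group) are skipped, as are features with non-positive group mean.
#'
#' @param table a [feature_table()].
#' @param group_map named character vector mapping spot label to group.
#' @param min_signal_fraction detection floor for including a feature in
#'   a group's \%CV (default 0.05).
#' @return List with \code{per_group_cv} (named numeric) and
#'   \code{overall_mean_cv}.
#' @export
cv_report <- function(table, group_map, min_signal_fraction = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  groups <- unique(unname(group_map))
  rows_of <- lapply(groups, function(g) {
    rows <- match(names(group_map)[group_map == g], table$spot_labels)
    if (any(is.na(rows))) stop("group_map names must be spot labels", call. = FALSE)
    rows
  })
  group_means <- do.call(rbind, lapply(rows_of, function(rows) {
    colMeans(table$values[rows, , drop = FALSE])
  }))
  max_mean <- apply(group_means, 2L, max)
  per_group <- vapply(seq_along(groups), function(gi) {
    rows <- rows_of[[gi]]
    if (length(rows) < 2L) return(NA_real_)
    present <- group_means[gi, ] >= min_signal_fraction * max_mean &
      group_means[gi, ] > 0
    if (!any(present)) return(NA_real_)
    cvs <- apply(table$values[rows, present, drop = FALSE], 2L, function(v) {
      100 * stats::sd(v) / mean(v)
    })
    mean(cvs)
  }, numeric(1L))
  names(per_group) <- groups
  list(per_group_cv = per_group,
       overall_mean_cv = mean(per_group, na.rm = TRUE))
}

#' Aggregate titer comparison
#'
#' Sums a subset of feature columns per spot (e.g. all target fatty
#' acids) and reports the per-group mean and sample standard deviation
#' over replicates — the relative production titer of each strain.
#'
#' @param table a [feature_table()].
#' @param feature_idx integer or logical index of feature columns to sum.
#' @param group_map named character vector mapping spot label to group.
#' @return data.frame with \code{group}, \code{mean}, \code{sd}, \code{n}.
#' @export
aggregate_titer <- function(table, feature_idx, group_map) {
  stopifnot(inherits(table, "feature_table"))
  sub <- table$values[, feature_idx, drop = FALSE]
  if (ncol(sub) == 0L) stop("empty feature subset", call. = FALSE)
  totals <- rowSums(sub)
  names(totals) <- table$spot_labels
  groups <- unique(unname(group_map))
  out <- do.call(rbind, lapply(groups, function(g) {
    labs <- names(group_map)[group_map == g]
    rows <- match(labs, table$spot_labels)
    if (any(is.na(rows))) stop("group_map names must be spot labels", call. = FALSE)
    v <- totals[rows]
    data.frame(group = g, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read / write a feature table
#'
#' TSV round-trip: a header row of feature m/z values, one row per spot,
#' and a \code{# stage:} comment line carrying provenance.
#'
#' @param table a [feature_table()].
#' @param path file path.
#' @return [write_feature_table()] returns \code{path} invisibly;
#'   [read_feature_table()] returns a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stage: ", table$stage), con)
  df <- data.frame(spot = table$spot_labels,
                   role = if (is.null(table$spot_roles)) NA else table$spot_roles,
                   table$values, check.names = FALSE)
  colnames(df) <- c("spot", "role", sprintf("%.6f", table$feature_mzs))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1L)
  stage <- sub("^# stage: *", "", first)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE, comment.char = "")
  mzs <- as.numeric(colnames(df)[-(1:2)])
  roles <- if (all(is.na(df$role))) NULL else as.character(df$role)
  feature_table(as.matrix(df[, -(1:2), drop = FALSE]), df$spot, mzs,
                stage = stage, spot_roles = roles)
}
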