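#' Untargeted feature detection over a spot array
#'
#' Pools every recorded peak of every pixel, clusters m/z values by
#' single-linkage along the sorted m/z axis (adjacent values joined when
#' they differ by less than \code{cluster_ppm}), integrates each cluster
#' per spot, and retains the \code{top_n} features ranked by total
#' integrated intensity across the sample spots — the "most abundant
#' features prioritized for statistical screening" filter, with a default
#' of 500.  When fewer features are detected than \code{top_n}, all are
#' retained with a note.
#'
#' @param run a [line_scan_run()].
#' @param layout a [spot_layout()] sharing the run's extent.
#' @param top_n number of features to retain (default 500).
#' @param cluster_ppm single-linkage clustering tolerance in ppm
#'   (default 10).
#' @return A \code{raw}-stage [feature_table()] with one row per layout
#'   spot (all roles, so media blanks are available for subtraction) and
#'   the feature m/z as the intensity-weighted cluster mean.
#' @export
detect_features <- function(run, layout, top_n = 500L, cluster_ppm = 10) {
  stopifnot(inherits(run, "line_scan_run"), inherits(layout, "spot_layout"))
  if (max(run$distances) > layout$scan_length + 1e-6) {
    stop("run extends beyond the layout's scan length", call. = FALSE)
  }
  n_pix <- length(run$spectra)
  lens <- vapply(run$spectra, function(s) length(s$mz), integer(1L))
  mz <- unlist(lapply(run$spectra, `[[`, "mz"), use.names = FALSE)
  ii <- unlist(lapply(run$spectra, `[[`, "intensity"), use.names = FALSE)
  pix <- rep.int(seq_len(n_pix), lens)

  ord <- order(mz)
  mz <- mz[ord]; ii <- ii[ord]; pix <- pix[ord]
  new_cluster <- c(TRUE, diff(mz) > mz[-length(mz)] * cluster_ppm * 1e-6)
  cl <- cumsum(new_cluster)

  # feature m/z: intensity-weighted mean (fallback plain mean for
  # all-zero clusters)
  wsum <- rowsum(ii, cl)
  mzw <- rowsum(mz * ii, cl)
  mzm <- rowsum(mz, cl) / as.numeric(table(cl))
  feat_mz <- ifelse(wsum > 0, mzw / pmax(wsum, .Machine$double.xmin), mzm)
  feat_mz <- as.numeric(feat_mz)
  n_feat <- length(feat_mz)

  # spot membership per pixel (0 = outside every spot)
  spot_idx <- integer(n_pix)
  for (i in seq_len(nrow(layout$spots))) {
    iv <- .spot_interval(layout, layout$spots$label[i])
    spot_idx[run$distances >= iv["left"] & run$distances < iv["right"]] <- i
  }
  spot_of_peak <- spot_idx[pix]
  keep <- spot_of_peak > 0L
  n_spots <- nrow(layout$spots)
  mat <- matrix(0, nrow = n_spots, ncol = n_feat)
  if (any(keep)) {
    key <- (cl[keep] - 1) * n_spots + spot_of_peak[keep]
    agg <- rowsum(ii[keep], key)
    k <- as.numeric(rownames(agg))
    cs <- (k - 1) %/% n_spots + 1
    rs <- k - (cs - 1) * n_spots
    mat[cbind(rs, cs)] <- agg[, 1L]
  }

  sample_rows <- which(layout$spots$role == "sample")
  totals <- colSums(mat[sample_rows, , drop = FALSE])
  if (n_feat > top_n) {
    sel <- order(totals, decreasing = TRUE)[seq_len(top_n)]
    sel <- sort(sel)
  } else {
    if (n_feat < top_n) {
      message("only ", n_feat, " features detected (top_n = ", top_n,
              "); retaining all")
    }
    sel <- seq_len(n_feat)
  }
  feature_table(mat[, sel, drop = FALSE], layout$spots$label,
                feat_mz[sel], stage = "raw", spot_roles = layout$spots$role)
}
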