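#' PCA phenotyping of per-spot profiles
#'
#' Principal component analysis of the sample-spot rows of a feature
#' table (mean-centered, optionally unit-variance scaled) to assess
#' global molecular differences between strains.  Loadings expose which
#' features drive each component — e.g. a dominant product peak loading
#' on PC1 separates the high-producer strain from the rest.
#'
#' @param table a [feature_table()].
#' @param n_components number of components returned (default 2).
#' @param scale. unit-variance scaling; default \code{FALSE}
#'   (constant-zero columns are dropped before scaling when \code{TRUE}).
#' @param sample_only restrict rows to \code{sample}-role spots when
#'   roles are present (default \code{TRUE}).
#' @return List with \code{scores} (spots x components),
#'   \code{loadings} (features x components), \code{explained_variance}
#'   (component variances), \code{proportion} (fraction of total
#'   variance).
#' @export
pca_phenotypes <- function(table, n_components = 2L, scale. = FALSE,
                           sample_only = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  values <- table$values
  if (sample_only && !is.null(table$spot_roles)) {
    values <- values[table$spot_roles == "sample", , drop = FALSE]
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("need >= 2 spots and >= 2 features", call. = FALSE)
  }
  vars <- apply(values, 2L, stats::var)
  if (all(vars == 0)) stop("constant table: no variance to decompose", call. = FALSE)
  if (scale.) values <- values[, vars > 0, drop = FALSE]
  fit <- stats::prcomp(values, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(fit$x))
  ev <- fit$sdev^2
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       loadings = fit$rotation[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)],
       proportion = ev[seq_len(k)] / sum(ev))
}

#' Volcano differential screening
#'
#' Per-feature comparison of two replicate groups on blank-subtracted
#' intensities: fold change as the ratio of group means (with a
#' pseudocount guarding zero means), a Welch two-sample t-test on
#' log2-transformed values, and the joint significance rule
#' \code{p <= p_threshold} and \code{|fold change| >= fc_threshold}.
#' No multiple-testing correction is applied by default — the screening
#' thresholds are on raw p-values — but Benjamini-Hochberg adjusted
#' p-values are available via \code{adjust}.
#'
#' @param table a [feature_table()] (typically \code{blank_subtracted}).
#' @param group_a,group_b character vectors of spot labels; each group
#'   needs >= 2 replicates.
#' @param p_threshold raw p-value threshold (default 0.05).
#' @param fc_threshold fold-change threshold (default 2; applied as
#'   \code{|log2 FC| >= log2(fc_threshold)}).
#' @param eps pseudocount added before ratios and logs; default 1e-6 of
#'   the table maximum.
#' @param adjust \code{"none"} (default) or \code{"BH"}; when
#'   \code{"BH"}, significance is called on adjusted p-values.
#' @return data.frame with one row per feature: \code{feature_mz},
#'   \code{log2_fold_change}, \code{p_value}, \code{significant},
#'   \code{direction} (\code{up} / \code{down} / \code{none}).
#' @export
volcano <- function(table, group_a, group_b, p_threshold = 0.05,
                    fc_threshold = 2, eps = NULL, adjust = c("none", "BH")) {
  stopifnot(inherits(table, "feature_table"))
  adjust <- match.arg(adjust)
  ra <- match(group_a, table$spot_labels)
  rb <- match(group_b, table$spot_labels)
  if (any(is.na(ra)) || any(is.na(rb))) {
    stop("group labels must be spot labels of the table", call. = FALSE)
  }
  if (length(ra) < 2L || length(rb) < 2L) {
    stop("each group needs >= 2 replicates", call. = FALSE)
  }
  if (is.null(eps)) eps <- 1e-6 * max(table$values)
  if (eps <= 0) eps <- .Machine$double.eps
  A <- table$values[ra, , drop = FALSE]
  B <- table$values[rb, , drop = FALSE]
  log2fc <- log2((colMeans(A) + eps) / (colMeans(B) + eps))
  p <- vapply(seq_len(ncol(A)), function(j) {
    la <- log2(A[, j] + eps); lb <- log2(B[, j] + eps)
    if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
      return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
    }
    stats::t.test(la, lb)$p.value
  }, numeric(1L))
  p_used <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  sig <- p_used <= p_threshold & abs(log2fc) >= log2(fc_threshold)
  direction <- ifelse(!sig, "none", ifelse(log2fc > 0, "up", "down"))
  data.frame(feature_mz = table$feature_mzs, log2_fold_change = log2fc,
             p_value = p, significant = sig, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}
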