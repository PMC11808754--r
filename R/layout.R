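#' Declare a spot layout
#'
#' A spot layout declares the linear array of labeled spot intervals a
#' line-scan passes over.  Each spot has a physical center and width (µm)
#' and a role: \code{sample}, \code{solvent_blank} or \code{media_blank}.
#' Spot intervals are closed on the left and open on the right,
#' \code{[center - width/2, center + width/2)}, so adjacent integration
#' windows never overlap.
#'
#' @param label character vector of unique spot labels.
#' @param center spot centers in µm along the scan axis.
#' @param width spot widths in µm.
#' @param role spot roles, recycled; one of \code{"sample"},
#'   \code{"solvent_blank"}, \code{"media_blank"}.
#' @param scan_length total scan length in µm; defaults to the right edge
#'   of the last spot.
#' @return A \code{spot_layout} object (data.frame of spots plus the scan
#'   length).
#' @seealso [default_layout()]
#' @export
spot_layout <- function(label, center, width, role = "sample",
                        scan_length = NULL) {
  n <- length(label)
  stopifnot(length(center) == n, length(width) %in% c(1L, n))
  width <- rep_len(width, n)
  role <- rep_len(role, n)
  bad <- setdiff(role, c("sample", "solvent_blank", "media_blank"))
  if (length(bad)) stop("unknown spot role(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (anyDuplicated(label)) stop("spot labels must be unique", call. = FALSE)
  ord <- order(center)
  spots <- data.frame(label = as.character(label), center = as.numeric(center),
                      width = as.numeric(width), role = role,
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(spots) <- NULL
  left <- spots$center - spots$width / 2
  right <- spots$center + spots$width / 2
  if (is.null(scan_length)) scan_length <- max(right)
  if (any(left < 0) || any(right > scan_length + 1e-9)) {
    stop("spot intervals must lie within [0, scan_length]", call. = FALSE)
  }
  if (n > 1L && any(right[-n] > left[-1L] + 1e-9)) {
    stop("spot intervals must be pairwise disjoint", call. = FALSE)
  }
  structure(list(spots = spots, scan_length = as.numeric(scan_length)),
            class = "spot_layout")
}

#' Evenly spaced default layout
#'
#' Builds the standard linear array used by the spotted-slide format:
#' \code{n_spots} equal-width spots whose outer edges touch 0 and
#' \code{span}, with equal gaps between adjacent spot edges.  The
#' screening slide uses 11 spots of 3 mm diameter spanning 50 mm
#' edge-to-edge.
#'
#' @param n_spots number of spots (>= 2).
#' @param spot_width spot width (diameter) in µm.
#' @param span edge-to-edge total length in µm.
#' @param role roles, recycled over spots.
#' @param offset shift applied to all centers, µm (e.g. to center the
#'   array on a longer scan line).
#' @param scan_length scan length in µm; default \code{span + offset}.
#' @param labels spot labels; default \code{"Spot 1"} ... \code{"Spot n"}.
#' @return A [spot_layout()].
#' @examples
#' lay <- default_layout(11, 3000, 50000)
#' lay$spots$center[1]  # 1500
#' @export
default_layout <- function(n_spots, spot_width, span, role = "sample",
                           offset = 0, scan_length = NULL, labels = NULL) {
  if (n_spots < 2L) stop("'n_spots' must be >= 2", call. = FALSE)
  if (spot_width <= 0 || span <= 0) stop("geometry must be positive", call. = FALSE)
  if (n_spots * spot_width > span) {
    stop("infeasible geometry: n_spots * spot_width exceeds span", call. = FALSE)
  }
  gap <- (span - n_spots * spot_width) / (n_spots - 1L)
  centers <- spot_width / 2 + (seq_len(n_spots) - 1L) * (spot_width + gap) + offset
  if (is.null(labels)) labels <- paste("Spot", seq_len(n_spots))
  if (is.null(scan_length)) scan_length <- span + offset
  spot_layout(labels, centers, spot_width, role, scan_length = scan_length)
}

# interval [left, right) of one spot row
.spot_interval <- function(layout, label) {
  i <- match(label, layout$spots$label)
  if (is.na(i)) stop("spot label '", label, "' not found in layout", call. = FALSE)
  c(left = layout$spots$center[i] - layout$spots$width[i] / 2,
    right = layout$spots$center[i] + layout$spots$width[i] / 2)
}

# logical vector: which distances fall inside the given spot labels
.in_spots <- function(distances, layout, labels) {
  inside <- rep(FALSE, length(distances))
  for (lab in labels) {
    iv <- .spot_interval(layout, lab)
    inside <- inside | (distances >= iv["left"] & distances < iv["right"])
  }
  inside
}

#' @export
print.spot_layout <- function(x, ...) {
  cat(sprintf("spot_layout: %d spots over %.0f um\n", nrow(x$spots),
              x$scan_length))
  print(x$spots)
  invisible(x)
}

#' Read / write a spot layout
#'
#' Layouts are stored as YAML or JSON with the schema
#' \code{{scan_length_um, spots: [{label, center_um, width_um, role}]}}.
#'
#' @param path file path; format chosen by extension (\code{.yaml},
#'   \code{.yml} or \code{.json}).
#' @return [read_layout()] returns a [spot_layout()];
#'   [write_layout()] returns \code{path} invisibly.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  spots <- obj$spots
  if (is.data.frame(spots)) {
    spot_layout(spots$label, spots$center_um, spots$width_um, spots$role,
                scan_length = obj$scan_length_um)
  } else {
    spot_layout(vapply(spots, `[[`, "", "label"),
                vapply(spots, function(s) as.numeric(s$center_um), 0),
                vapply(spots, function(s) as.numeric(s$width_um), 0),
                vapply(spots, `[[`, "", "role"),
                scan_length = obj$scan_length_um)
  }
}

#' @param layout a [spot_layout()].
#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  obj <- list(scan_length_um = layout$scan_length,
              spots = lapply(seq_len(nrow(layout$spots)), function(i) {
                s <- layout$spots[i, ]
                list(label = s$label, center_um = s$center, width_um = s$width,
                     role = s$role)
              }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}
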