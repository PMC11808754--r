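# Minimal processed-mode imzML support for 1-D line scans: an .imzML XML
# index plus an .ibd binary file holding 64-bit little-endian m/z and
# intensity arrays, one spectrum per pixel at (x = pixel index, y = 1).

.ims_cv <- c(processed = "IMS:1000031", continuous = "IMS:1000030",
             uuid = "IMS:1000080", md5 = "IMS:1000090",
             x = "IMS:1000050", y = "IMS:1000051",
             offset = "IMS:1000102", length = "IMS:1000103",
             enc_length = "IMS:1000104")

#' Write a line-scan run as imzML
#'
#' Writes processed-mode imzML (one independent m/z axis per pixel) with
#' 64-bit float arrays.  The pixel's x-coordinate is its 1-based index
#' along the scan; y is always 1.  Raster rate and pixel size are stored
#' as userParams so a round-trip preserves the run geometry.
#'
#' @param run a [line_scan_run()].
#' @param path output path for the \code{.imzML} file; the \code{.ibd}
#'   binary is written alongside with the same stem.
#' @return \code{path}, invisibly.
#' @export
write_imzml <- function(run, path) {
  stopifnot(inherits(run, "line_scan_run"))
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")

  uuid <- paste(sprintf("%02x", as.integer(sample.int(256, 16, replace = TRUE) - 1L)),
                collapse = "")
  con <- file(ibd_path, "wb")
  writeBin(as.raw(strtoi(substring(uuid, seq(1, 31, 2), seq(2, 32, 2)), 16L)), con)
  offsets <- integer(0)
  lengths <- integer(0)
  pos <- 16
  for (s in run$spectra) {
    n <- length(s$mz)
    offsets <- c(offsets, pos, pos + 8 * n)
    lengths <- c(lengths, n, n)
    writeBin(as.numeric(s$mz), con, size = 8, endian = "little")
    writeBin(as.numeric(s$intensity), con, size = 8, endian = "little")
    pos <- pos + 16 * n
  }
  close(con)
  md5 <- unname(tools::md5sum(ibd_path))

  doc <- xml2::xml_new_root("mzML",
    xmlns = "http://psi.hupo.org/ms/mzml", version = "1.1")
  fd <- xml2::xml_add_child(doc, "fileDescription")
  fc <- xml2::xml_add_child(fd, "fileContent")
  .cv <- function(node, acc, name, value = "") {
    xml2::xml_add_child(node, "cvParam", cvRef = strsplit(acc, ":")[[1L]][1L],
                        accession = acc, name = name, value = value)
  }
  .cv(fc, .ims_cv[["processed"]], "processed")
  .cv(fc, .ims_cv[["uuid"]], "universally unique identifier",
      paste0("{", uuid, "}"))
  .cv(fc, .ims_cv[["md5"]], "ibd MD5", md5)
  .cv(fc, if (run$polarity == "positive") "MS:1000130" else "MS:1000129",
      paste(run$polarity, "scan"))
  ss <- xml2::xml_add_child(doc, "scanSettingsList", count = "1")
  sset <- xml2::xml_add_child(ss, "scanSettings", id = "scan1")
  .cv(sset, "IMS:1000042", "max count of pixels x", length(run$spectra))
  .cv(sset, "IMS:1000043", "max count of pixels y", 1L)
  .cv(sset, "IMS:1000046", "pixel size (x)", run$pixel_size)
  xml2::xml_add_child(sset, "userParam", name = "raster rate (um/s)",
                      value = as.character(run$raster_rate))
  xml2::xml_add_child(sset, "userParam", name = "scan length (um)",
                      value = as.character(run$scan_length))
  rn <- xml2::xml_add_child(doc, "run", id = "linescan")
  sl <- xml2::xml_add_child(rn, "spectrumList",
                            count = as.character(length(run$spectra)))
  for (i in seq_along(run$spectra)) {
    sp <- xml2::xml_add_child(sl, "spectrum", index = as.character(i - 1L),
                              id = sprintf("spectrum=%d", i),
                              defaultArrayLength = as.character(lengths[2L * i - 1L]))
    scl <- xml2::xml_add_child(sp, "scanList", count = "1")
    scan <- xml2::xml_add_child(scl, "scan")
    .cv(scan, .ims_cv[["x"]], "position x", i)
    .cv(scan, .ims_cv[["y"]], "position y", 1L)
    bal <- xml2::xml_add_child(sp, "binaryDataArrayList", count = "2")
    for (kind in c("mz", "intensity")) {
      k <- if (kind == "mz") 2L * i - 1L else 2L * i
      ba <- xml2::xml_add_child(bal, "binaryDataArray", encodedLength = "0")
      .cv(ba, if (kind == "mz") "MS:1000514" else "MS:1000515",
          paste(if (kind == "mz") "m/z" else "intensity", "array"))
      .cv(ba, "MS:1000523", "64-bit float")
      .cv(ba, .ims_cv[["offset"]], "external offset", offsets[k])
      .cv(ba, .ims_cv[["length"]], "external array length", lengths[k])
      .cv(ba, .ims_cv[["enc_length"]], "external encoded length", 8L * lengths[k])
      xml2::xml_add_child(ba, "binary")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read line-scan imzML
#'
#' Reads processed-mode imzML written by [write_imzml()] or compatible
#' single-line exports.  Pixels are ordered by their x position and the
#' distance coordinate is \code{(x_index - 1) * pixel_size}.  Multi-row
#' images (any y > 1) are rejected: this pipeline operates on single
#' raster lines.  Spectra with unsorted m/z arrays are repaired (sorted)
#' with a warning.
#'
#' @param path path to the \code{.imzML} file.
#' @param raster_rate raster rate in µm/s; when \code{NULL}, taken from
#'   the file's userParam if present (required otherwise).
#' @param pixel_size pixel size in µm; when \code{NULL}, taken from the
#'   file's scan settings.
#' @return A [line_scan_run()].
#' @export
read_imzml <- function(path, raster_rate = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("imzML file not found: ", path, call. = FALSE)
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("ibd file not found: ", ibd_path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  getp <- function(node, acc) {
    xml2::xml_attr(xml2::xml_find_first(node,
      sprintf(".//cvParam[@accession='%s']", acc)), "value")
  }
  if (is.null(pixel_size)) {
    v <- getp(doc, "IMS:1000046")
    if (is.na(v)) stop("pixel size not in file; pass 'pixel_size'", call. = FALSE)
    pixel_size <- as.numeric(v)
  }
  if (is.null(raster_rate)) {
    v <- xml2::xml_attr(xml2::xml_find_first(doc,
      ".//userParam[@name='raster rate (um/s)']"), "value")
    if (is.na(v)) stop("raster rate not in file; pass 'raster_rate'", call. = FALSE)
    raster_rate <- as.numeric(v)
  }
  polarity <- if (!is.null(xml2::xml_find_first(doc,
    ".//cvParam[@accession='MS:1000129']")) &&
    !inherits(xml2::xml_find_first(doc,
      ".//cvParam[@accession='MS:1000129']"), "xml_missing")) {
    "negative"
  } else "positive"

  specs <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (!length(specs)) stop("imzML contains no spectra", call. = FALSE)
  xs <- as.integer(vapply(specs, getp, "", .ims_cv[["x"]]))
  ys <- as.integer(vapply(specs, getp, "", .ims_cv[["y"]]))
  if (any(ys != 1L, na.rm = TRUE)) {
    stop("multi-row image (y > 1): this pipeline operates on single ",
         "raster lines; extract one row before reading", call. = FALSE)
  }
  ord <- order(xs)

  con <- file(ibd_path, "rb")
  on.exit(close(con))
  unsorted <- 0L
  spectra <- lapply(specs[ord], function(sp) {
    bas <- xml2::xml_find_all(sp, ".//binaryDataArray")
    read_arr <- function(ba) {
      off <- as.numeric(getp(ba, .ims_cv[["offset"]]))
      len <- as.integer(getp(ba, .ims_cv[["length"]]))
      seek(con, off)
      readBin(con, "numeric", n = len, size = 8, endian = "little")
    }
    is_mz <- vapply(bas, function(ba) {
      !is.na(xml2::xml_attr(xml2::xml_find_first(ba,
        ".//cvParam[@accession='MS:1000514']"), "accession"))
    }, logical(1L))
    mz <- read_arr(bas[is_mz][[1L]])
    ii <- read_arr(bas[!is_mz][[1L]])
    if (length(mz) > 1L && any(diff(mz) <= 0)) {
      unsorted <<- unsorted + 1L
      o <- order(mz)
      mz <- mz[o]; ii <- ii[o]
      if (any(diff(mz) <= 0)) {
        keep <- c(TRUE, diff(mz) > 0)
        ii <- as.numeric(rowsum(ii, cumsum(keep)))
        mz <- mz[keep]
      }
    }
    mass_spectrum(mz, ii)
  })
  if (unsorted > 0L) {
    warning(unsorted, " spectrum/spectra had unsorted m/z arrays; repaired",
            call. = FALSE)
  }
  scan_length <- {
    v <- xml2::xml_attr(xml2::xml_find_first(doc,
      ".//userParam[@name='scan length (um)']"), "value")
    if (is.na(v)) NULL else as.numeric(v)
  }
  line_scan_run(spectra, (xs[ord] - 1L) * pixel_size, raster_rate,
                pixel_size, polarity, scan_length)
}

#' Read line-scan mzML
#'
#' Reads an mzML file via the \pkg{mzR} backend, interpreting scan
#' (acquisition) order as distance along the raster: pixel i sits at
#' \code{(i - 1) * pixel_size}.
#'
#' @param path path to the mzML file.
#' @param raster_rate raster rate in µm/s.
#' @param pixel_size pixel size in µm.
#' @return A [line_scan_run()].
#' @export
read_mzml <- function(path, raster_rate, pixel_size) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  }
  if (!file.exists(path)) stop("mzML file not found: ", path, call. = FALSE)
  h <- mzR::openMSfile(path)
  on.exit(try(mzR::close(h), silent = TRUE))
  hdr <- mzR::header(h)
  n <- nrow(hdr)
  if (n == 0L) stop("mzML contains no spectra", call. = FALSE)
  polarity <- if (!is.null(hdr$polarity) && any(hdr$polarity == 0, na.rm = TRUE)) {
    "negative"
  } else "positive"
  spectra <- lapply(seq_len(n), function(i) {
    p <- mzR::peaks(h, i)
    o <- order(p[, 1L])
    mass_spectrum(p[o, 1L], p[o, 2L])
  })
  line_scan_run(spectra, (seq_len(n) - 1L) * pixel_size, raster_rate,
                pixel_size, polarity)
}
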