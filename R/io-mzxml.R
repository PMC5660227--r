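#' Read spectra from an mzXML file
#'
#' Parses an mzXML file (the export format of CompassXport and similar
#' converters) into a list of [raw_spectrum()] objects, one per scan, in
#' file order. Both 32- and 64-bit, plain and zlib-compressed base64 peak
#' arrays are supported through the mzR backend. If a scan's m/z values
#' are not ascending they are sorted, with intensities permuted
#' consistently.
#'
#' Sample ids are taken as `<file stem>` for a single-scan file and
#' `<file stem>_sNNN` otherwise; group labels are attached later from the
#' manifest, never from file names.
#'
#' @param path path to an mzXML file with at least one scan.
#' @return A list of `raw_spectrum` objects.
#' @export
read_mzxml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # surface XML syntax errors with position info before handing to mzR
  parsed <- tryCatch(xml2::read_xml(path), error = function(e) e)
  if (inherits(parsed, "error"))
    stop("malformed mzXML '", path, "': ", conditionMessage(parsed),
         call. = FALSE)
  fh <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(fh), add = TRUE)
  n <- nrow(mzR::header(fh))
  if (n < 1L) stop("mzXML file contains no scans: ", path, call. = FALSE)
  stem <- sub("\\.[^.]*$", "", basename(path))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pk <- mzR::peaks(fh, i)
    if (is.null(dim(pk)) || nrow(pk) < 2L)
      stop("scan ", i, " in '", path, "' has fewer than 2 points",
           call. = FALSE)
    ord <- order(pk[, 1L])
    sid <- if (n == 1L) stem else sprintf("%s_s%03d", stem, i)
    out[[i]] <- raw_spectrum(
      sample_id = sid, mz = pk[ord, 1L], intensity = pmax(pk[ord, 2L], 0),
      provenance = list(file = path, scan = i))
  }
  out
}

#' Write spectra to an mzXML file
#'
#' Serializes one or more spectra as a minimal, standard-conforming mzXML
#' 3.2 document with base64-encoded network-byte-order peak arrays
#' (32- or 64-bit, optionally zlib-compressed). Files written here
#' round-trip through [read_mzxml()].
#'
#' @param spectra a `raw_spectrum` or list of them.
#' @param path output file path.
#' @param precision 32 or 64 (bits per float).
#' @param compress logical; zlib-compress the peak arrays.
#' @return The path, invisibly.
#' @export
write_mzxml <- function(spectra, path, precision = 32L, compress = FALSE) {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  if (!length(spectra)) stop("no spectra to write", call. = FALSE)
  precision <- as.integer(precision)
  if (!precision %in% c(32L, 64L)) stop("precision must be 32 or 64",
                                        call. = FALSE)
  scans <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    validate_spectrum(s)
    interleaved <- as.numeric(rbind(s$mz, s$intensity))
    bytes <- writeBin(interleaved, raw(), size = precision / 8L,
                      endian = "big")
    ctype <- "none"
    clen <- 0L
    if (compress) {
      bytes <- memCompress(bytes, type = "gzip")
      ctype <- "zlib"
      clen <- length(bytes)
    }
    b64 <- gsub("\n", "", jsonlite::base64_enc(bytes), fixed = TRUE)
    apex <- which.max(s$intensity)
    paste0(
      sprintf(paste0('  <scan num="%d" msLevel="1" peaksCount="%d" ',
                     'polarity="+" retentionTime="PT%.2fS" lowMz="%g" ',
                     'highMz="%g" basePeakMz="%g" basePeakIntensity="%g" ',
                     'totIonCurrent="%g">\n'),
              i, length(s$mz), i * 0.1, min(s$mz), max(s$mz),
              s$mz[apex], s$intensity[apex], sum(s$intensity)),
      sprintf(paste0('   <peaks precision="%d" byteOrder="network" ',
                     'contentType="m/z-int" compressionType="%s" ',
                     'compressedLen="%d">%s</peaks>\n'),
              precision, ctype, clen, b64),
      "  </scan>")
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">\n',
    sprintf(' <msRun scanCount="%d">\n', length(spectra)),
    paste(scans, collapse = "\n"), "\n",
    ' </msRun>\n</mzXML>\n')
  writeLines(doc, path, sep = "")
  invisible(path)
}

#' Read a single spectrum from a two-column CSV
#'
#' @param path CSV with two numeric columns (m/z in Daltons, intensity);
#'   a header line is detected and skipped automatically.
#' @param sample_id sample identifier to attach.
#' @param group optional group label.
#' @return A `raw_spectrum`.
#' @export
read_csv_spectrum <- function(path, sample_id, group = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(trimws(first)))
    stop("empty spectrum file: ", path, call. = FALSE)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, ",")[[1]][1])))
  d <- utils::read.csv(path, header = has_header,
                       colClasses = c("character", "character"))
  if (!nrow(d)) stop("empty spectrum file: ", path, call. = FALSE)
  if (ncol(d) < 2L) stop("expected two columns (mz, intensity) in ", path,
                         call. = FALSE)
  mz <- suppressWarnings(as.numeric(d[[1]]))
  it <- suppressWarnings(as.numeric(d[[2]]))
  bad <- which(is.na(mz) | is.na(it))
  if (length(bad))
    stop("non-numeric value in '", path, "' at data row ", bad[1],
         call. = FALSE)
  if (anyDuplicated(mz)) {
    dup <- mz[duplicated(mz)][1]
    stop("duplicate m/z value ", dup, " in ", path, call. = FALSE)
  }
  ord <- order(mz)
  raw_spectrum(sample_id, mz[ord], it[ord], group = group,
               provenance = list(file = path))
}

#' Write a spectrum as a two-column CSV
#'
#' @param s a spectrum object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_csv_spectrum <- function(s, path) {
  validate_spectrum(s)
  utils::write.csv(data.frame(mz = s$mz, intensity = s$intensity), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
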