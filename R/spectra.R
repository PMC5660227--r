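#' Construct a raw mass spectrum
#'
#' The elementary data object of the pipeline: one sample's profile-mode
#' MALDI-TOF spectrum as paired m/z (Daltons) and intensity (arbitrary
#' units) vectors, with sample identity, an optional group label and
#' free-form provenance metadata.
#'
#' @param sample_id character scalar identifying the sample.
#' @param mz numeric vector of m/z values in Daltons, strictly increasing.
#' @param intensity numeric vector of non-negative intensities, same
#'   length as `mz`.
#' @param group optional group label, one of `"HC"`, `"CRC"` or
#'   `"unknown"`.
#' @param provenance named list of free-form metadata (instrument, file
#'   of origin, ...).
#'
#' @return An object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(sample_id, mz, intensity, group = "unknown",
                         provenance = list()) {
  s <- structure(
    list(sample_id = as.character(sample_id)[1],
         mz = as.numeric(mz),
         intensity = as.numeric(intensity),
         group = as.character(group)[1],
         provenance = provenance),
    class = "raw_spectrum")
  validate_spectrum(s)
  s
}

validate_spectrum <- function(s) {
  if (length(s$mz) != length(s$intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (length(s$mz) < 2L)
    stop("spectrum must contain at least 2 points", call. = FALSE)
  if (!all(is.finite(s$mz)) || !all(is.finite(s$intensity)))
    stop("mz and intensity must be finite", call. = FALSE)
  if (any(diff(s$mz) <= 0))
    stop("mz must be strictly increasing", call. = FALSE)
  if (any(s$intensity < 0))
    stop("intensity must be non-negative", call. = FALSE)
  if (!s$group %in% c("HC", "CRC", "unknown"))
    stop("group must be one of 'HC', 'CRC', 'unknown'", call. = FALSE)
  invisible(s)
}

is_spectrum <- function(x) inherits(x, c("raw_spectrum", "processed_spectrum"))

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("<%s> sample '%s' (%s): %d points, m/z %.1f-%.1f Da\n",
              class(x)[1], x$sample_id, x$group, length(x$mz),
              min(x$mz), max(x$mz)))
  if (!is.null(x$processing_log) && length(x$processing_log))
    cat("  processing:", paste(vapply(x$processing_log, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' @export
print.processed_spectrum <- print.raw_spectrum

# Promote a raw spectrum to a processed one (adds processing log slot).
as_processed <- function(s) {
  if (inherits(s, "processed_spectrum")) return(s)
  s$processing_log <- list()
  s$noise_scale <- NA_real_
  class(s) <- c("processed_spectrum", "raw_spectrum")
  s
}

log_step <- function(s, step, params = list()) {
  s$processing_log <- c(s$processing_log, list(c(list(step = step), params)))
  s
}

#' Read a sample manifest
#'
#' Reads the cohort manifest CSV linking sample ids to group labels and
#' optional clinical columns. Sample-to-group assignment in this pipeline
#' happens only through the manifest, never by parsing file names. Row
#' order is preserved exactly as in the file.
#'
#' @param path path to a CSV file with columns `sample_id,group` and
#'   optionally `stage`, `cea` (ug/l), `fobt` (0/1), `surv_months`,
#'   `surv_event`.
#'
#' @return A data.frame with one row per sample, in file order.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("manifest is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(m$sample_id))
    stop("manifest sample_id values must be unique", call. = FALSE)
  if (!all(m$group %in% c("HC", "CRC")))
    stop("manifest group must be 'HC' or 'CRC'", call. = FALSE)
  if ("stage" %in% names(m)) {
    bad <- !is.na(m$stage) & m$stage != "" & m$group != "CRC"
    if (any(bad))
      stop("stage may be present only for CRC samples", call. = FALSE)
  }
  m
}

#' Write a sample manifest
#'
#' @param manifest data.frame as returned by [read_manifest()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
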