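#' Construct a sample-by-peak-cluster intensity matrix
#'
#' The pipeline's central exchange object: rows are samples, columns are
#' peak clusters identified by their centroid m/z (Daltons). A zero cell
#' means the sample had no detected peak in that cluster.
#'
#' @param values numeric matrix, samples x clusters, non-negative.
#' @param cluster_mz numeric vector of strictly increasing cluster
#'   centroid m/z values, one per column.
#' @param samples character vector of sample ids, one per row.
#' @param groups group label per sample (`"HC"`/`"CRC"`/`"unknown"`).
#'
#' @return An object of class `peak_matrix` with fields `values`,
#'   `cluster_mz`, `samples`, `groups`.
#' @export
peak_matrix <- function(values, cluster_mz, samples, groups) {
  values <- as.matrix(values)
  if (nrow(values) != length(samples))
    stop("values must have one row per sample", call. = FALSE)
  if (ncol(values) != length(cluster_mz))
    stop("values must have one column per cluster", call. = FALSE)
  if (length(groups) != length(samples))
    stop("groups must have one entry per sample", call. = FALSE)
  if (length(cluster_mz) > 1L && any(diff(cluster_mz) <= 0))
    stop("cluster_mz must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("matrix values must be >= 0", call. = FALSE)
  if (anyDuplicated(samples))
    stop("sample ids must be unique", call. = FALSE)
  dimnames(values) <- NULL
  structure(list(values = values,
                 cluster_mz = as.numeric(cluster_mz),
                 samples = as.character(samples),
                 groups = as.character(groups)),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d samples x %d clusters (%s)\n",
              length(x$samples), length(x$cluster_mz),
              paste(sprintf("%s=%d", names(table(x$groups)),
                            as.integer(table(x$groups))), collapse = ", ")))
  invisible(x)
}

# Column labels: integer-rounded Da (peaks are conventionally reported as
# e.g. "2084 Da"); colliding labels are disambiguated with one decimal.
cluster_labels <- function(cluster_mz) {
  lab <- sprintf("%.0f", cluster_mz)
  dup <- lab %in% lab[duplicated(lab)]
  if (any(dup)) {
    warning("rounded cluster labels collide at ",
            paste(unique(lab[dup]), collapse = ", "),
            " Da; using one decimal", call. = FALSE)
    lab[dup] <- sprintf("%.1f", cluster_mz[dup])
  }
  lab
}

#' Write a peak matrix to CSV
#'
#' One row per sample; columns `sample_id`, `group`, then one column per
#' cluster labelled `mz_<Da>` with the cluster m/z rounded to the nearest
#' Dalton (one decimal where rounded labels would collide). Full-precision
#' centroids are kept on a `#cluster_mz` comment line so that
#' `read_peak_matrix(write_peak_matrix(m))` reproduces `m` exactly.
#'
#' @param matrix a [peak_matrix()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_peak_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "peak_matrix"))
  if (!length(matrix$samples) || !length(matrix$cluster_mz))
    stop("peak matrix is empty", call. = FALSE)
  lab <- cluster_labels(matrix$cluster_mz)
  con <- file(path, "w")
  on.exit(close(con))
  # full-precision centroids on a comment line so round-trips are exact
  writeLines(paste0("#cluster_mz,", paste(sprintf("%.10g", matrix$cluster_mz),
                                          collapse = ",")), con)
  d <- data.frame(sample_id = matrix$samples, group = matrix$groups,
                  matrix$values, check.names = FALSE)
  names(d) <- c("sample_id", "group", paste0("mz_", lab))
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak matrix written by [write_peak_matrix()]
#'
#' @param path CSV path.
#' @return A [peak_matrix()].
#' @export
read_peak_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  cmz <- NULL
  if (startsWith(first, "#cluster_mz")) {
    cmz <- as.numeric(strsplit(first, ",")[[1]][-1])
    skip <- 1L
  }
  d <- utils::read.csv(path, skip = skip, check.names = FALSE,
                       stringsAsFactors = FALSE)
  mzcols <- grep("^mz_", names(d))
  if (!length(mzcols)) stop("no cluster columns in ", path, call. = FALSE)
  if (is.null(cmz))
    cmz <- as.numeric(sub("^mz_", "", names(d)[mzcols]))
  peak_matrix(as.matrix(d[, mzcols, drop = FALSE]), cmz,
              d$sample_id, d$group)
}

# Restrict a peak matrix to a subset of samples (order preserved as given)
subset_samples <- function(m, ids) {
  idx <- match(ids, m$samples)
  if (anyNA(idx))
    stop("unknown sample ids: ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  peak_matrix(m$values[idx, , drop = FALSE], m$cluster_mz,
              m$samples[idx], m$groups[idx])
}
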