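#' Detect peaks in a processed spectrum
#'
#' Finds local maxima whose height exceeds `snr_min` times the spectrum's
#' robust noise scale (set by [denoise_udwt()] and rescaled by
#' [normalize_tic()]). Among maxima closer than `min_sep_da` the taller
#' one is kept. Each peak's centroid is the intensity-weighted mean m/z of
#' the three points around the apex.
#'
#' @param s a fully preprocessed spectrum (the processing log must
#'   contain a `normalize_tic` step).
#' @param snr_min minimum signal-to-noise ratio (default 3).
#' @param min_sep_da minimum separation between reported peaks, in
#'   Daltons; `NULL` (default) uses 0.3% of each peak's m/z.
#'
#' @return A data.frame with columns `mz_centroid`, `height`, `snr`,
#'   `sample_id`, one row per peak, ascending m/z.
#' @export
detect_peaks <- function(s, snr_min = 3, min_sep_da = NULL) {
  steps <- vapply(s$processing_log, `[[`, "", "step")
  if (!"normalize_tic" %in% steps)
    stop("spectrum is not fully preprocessed (no normalize_tic step)",
         call. = FALSE)
  if (!is.finite(s$noise_scale))
    stop("spectrum has no noise_scale; run denoise_udwt first",
         call. = FALSE)
  y <- s$intensity
  n <- length(y)
  apex <- which(diff(sign(diff(y))) < 0) + 1L
  apex <- apex[y[apex] / s$noise_scale >= snr_min & y[apex] > 0]
  if (!length(apex))
    return(data.frame(mz_centroid = numeric(0), height = numeric(0),
                      snr = numeric(0), sample_id = character(0)))
  # enforce minimum separation, keeping the taller of any close pair
  ord <- apex[order(-y[apex])]
  kept <- integer(0)
  for (i in ord) {
    sep <- if (is.null(min_sep_da)) 0.003 * s$mz[i] else min_sep_da
    if (!length(kept) || all(abs(s$mz[kept] - s$mz[i]) >= sep))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  centroid <- vapply(kept, function(i) {
    idx <- max(1L, i - 1L):min(n, i + 1L)
    sum(s$mz[idx] * y[idx]) / sum(y[idx])
  }, 0)
  data.frame(mz_centroid = centroid, height = y[kept],
             snr = y[kept] / s$noise_scale,
             sample_id = rep(s$sample_id, length(kept)))
}

#' Cluster peaks across samples into a peak matrix
#'
#' Aligns per-sample peak lists along m/z by single-linkage clustering
#' with centroid recompute: peaks are processed in ascending m/z and a
#' new cluster starts whenever a peak lies farther than
#' `tol_rel * centroid` from the running centroid of the open cluster.
#' Clusters detected in fewer than `min_prevalence` of the samples are
#' dropped. A cell holds the sample's peak height in that cluster (the
#' maximum if a sample contributed several peaks), or 0 if the sample has
#' no peak there.
#'
#' The result is invariant to the order in which samples contributed
#' peaks: peaks are canonically sorted before clustering.
#'
#' @param peaks data.frame of peaks from [detect_peaks()] over all
#'   samples (row-bound).
#' @param samples character vector of all sample ids, defining the row
#'   order of the matrix (include samples with no peaks).
#' @param groups group label per sample.
#' @param tol_rel clustering tolerance as a fraction of m/z
#'   (default 0.003 = 0.3%).
#' @param min_prevalence minimum fraction of samples with a peak for a
#'   cluster to be kept (default 0.1).
#'
#' @return A [peak_matrix()].
#' @export
cluster_peaks <- function(peaks, samples, groups, tol_rel = 0.003,
                          min_prevalence = 0.1) {
  if (tol_rel <= 0) stop("tol_rel must be > 0", call. = FALSE)
  if (length(unique(peaks$sample_id)) < 2L)
    stop("need peaks from at least 2 samples", call. = FALSE)
  unknown <- setdiff(peaks$sample_id, samples)
  if (length(unknown))
    stop("peaks from samples not in sample list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  # canonical order makes the clustering independent of input order
  ord <- order(peaks$mz_centroid, peaks$sample_id, -peaks$height)
  p <- peaks[ord, , drop = FALSE]
  cl <- integer(nrow(p))
  centroid <- 0
  csum <- 0
  k <- 0L
  cn <- 0L
  for (i in seq_len(nrow(p))) {
    if (k == 0L || p$mz_centroid[i] - centroid > tol_rel * centroid) {
      k <- k + 1L
      csum <- 0
      cn <- 0L
    }
    cl[i] <- k
    csum <- csum + p$mz_centroid[i]
    cn <- cn + 1L
    centroid <- csum / cn
  }
  cmz <- vapply(split(p$mz_centroid, cl), mean, 0)
  prevalence <- vapply(split(p$sample_id, cl),
                       function(x) length(unique(x)), 0L) / length(samples)
  keep <- which(prevalence >= min_prevalence)
  n_dropped <- nrow(p) - sum(cl %in% keep)
  values <- matrix(0, nrow = length(samples), ncol = length(keep))
  n_multi <- 0L
  for (jj in seq_along(keep)) {
    rows <- which(cl == keep[jj])
    si <- match(p$sample_id[rows], samples)
    if (anyDuplicated(si)) {
      n_multi <- n_multi + sum(duplicated(si))
      agg <- tapply(p$height[rows], si, max)
      values[as.integer(names(agg)), jj] <- agg
    } else {
      values[si, jj] <- p$height[rows]
    }
  }
  m <- peak_matrix(values, cmz[keep], samples, groups)
  m$log <- list(n_clusters_raw = k, n_dropped_peaks = n_dropped,
                n_multi_peak_cells = n_multi, tol_rel = tol_rel,
                min_prevalence = min_prevalence)
  m
}

#' Build a peak matrix for a cohort of processed spectra
#'
#' Convenience wrapper: [detect_peaks()] on every spectrum, then
#' [cluster_peaks()] with the manifest's sample order and group labels.
#'
#' @param spectra list of fully preprocessed spectra.
#' @param manifest data.frame from [read_manifest()] covering every
#'   spectrum's sample id.
#' @param snr_min,min_sep_da,tol_rel,min_prevalence see [detect_peaks()]
#'   and [cluster_peaks()].
#' @return A [peak_matrix()].
#' @export
call_peak_matrix <- function(spectra, manifest, snr_min = 3,
                             min_sep_da = NULL, tol_rel = 0.003,
                             min_prevalence = 0.1) {
  ids <- vapply(spectra, `[[`, "", "sample_id")
  missing <- setdiff(ids, manifest$sample_id)
  if (length(missing))
    stop("spectra without manifest entry: ",
         paste(missing, collapse = ", "), call. = FALSE)
  keep <- manifest$sample_id %in% ids
  peaks <- do.call(rbind, lapply(spectra, detect_peaks, snr_min = snr_min,
                                 min_sep_da = min_sep_da))
  cluster_peaks(peaks, manifest$sample_id[keep], manifest$group[keep],
                tol_rel = tol_rel, min_prevalence = min_prevalence)
}
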