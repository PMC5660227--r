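# Mann-Whitney U of x (group 1) vs y (group 2), ties counted 0.5;
# AUC = U / (n1 * n2) is the probability a random group-1 value exceeds
# a random group-2 value.
mann_whitney_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Rank peak clusters by two-group Wilcoxon rank-sum tests
#'
#' For every peak cluster, tests CRC against HC intensities with the
#' two-sided Wilcoxon rank-sum test (exact distribution when the smaller
#' group has at most 8 samples and there are no ties, normal
#' approximation with tie and continuity correction otherwise) and
#' computes the per-marker ROC AUC (`U/(n1*n2)`, ties 0.5, oriented so
#' AUC >= 0.5) and the direction of change in CRC. A Benjamini-Hochberg
#' adjusted p-value column is included for information; ranking uses the
#' raw p.
#'
#' @param m a [peak_matrix()] with both HC and CRC samples.
#' @return A data.frame sorted by ascending p (ties broken by larger
#'   AUC, then lower cluster m/z) with columns `cluster_mz`, `p_value`,
#'   `auc`, `direction`, `mean_HC`, `mean_CRC`, `p_bh`.
#' @export
wilcoxon_rank_markers <- function(m) {
  stopifnot(inherits(m, "peak_matrix"))
  hc <- m$groups == "HC"
  crc <- m$groups == "CRC"
  if (sum(hc) < 2L || sum(crc) < 2L)
    stop("both groups need at least 2 samples", call. = FALSE)
  res <- lapply(seq_along(m$cluster_mz), function(j) {
    x <- m$values[crc, j]  # CRC
    y <- m$values[hc, j]   # HC
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- min(length(x), length(y)) <= 8L && !ties
    p <- if (all(c(x, y) == c(x, y)[1])) 1 else
      suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                          correct = TRUE)$p.value)
    u <- mann_whitney_u(x, y)
    auc_crc <- u / (length(x) * length(y))
    data.frame(cluster_mz = m$cluster_mz[j], p_value = p,
               auc = max(auc_crc, 1 - auc_crc),
               direction = if (mean(x) >= mean(y)) "up_in_CRC"
                           else "down_in_CRC",
               mean_HC = mean(y), mean_CRC = mean(x))
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, -out$auc, out$cluster_mz), , drop = FALSE]
}

#' Filter ranked markers to the candidate shortlist
#'
#' Retains markers with `p_value < p_max` and `auc > auc_min`, then
#' truncates to the `top_k` smallest p-values. The discovery screen uses
#' `p_max = 0.01`; the candidate-shortlist preset
#' (`filter_candidates(stats)` with `preset = "shortlist"`) uses
#' `(1e-5, 0.78, 10)`, the thresholds under which ten candidate peaks
#' survive in a typical serum profiling cohort.
#'
#' @param stats data.frame from [wilcoxon_rank_markers()] (sorted by p).
#' @param p_max maximum p-value (exclusive).
#' @param auc_min minimum AUC (exclusive).
#' @param top_k keep at most this many markers.
#' @param preset `"discovery"` (p < 0.01, no AUC/top-k limit) or
#'   `"shortlist"` (p < 1e-5, AUC > 0.78, top 10); explicit arguments
#'   override the preset.
#' @return The filtered data.frame (possibly empty, with a warning).
#' @export
filter_candidates <- function(stats, p_max = NULL, auc_min = NULL,
                              top_k = NULL,
                              preset = c("discovery", "shortlist")) {
  preset <- match.arg(preset)
  def <- if (preset == "discovery") list(p_max = 0.01, auc_min = 0,
                                         top_k = Inf)
         else list(p_max = 1e-5, auc_min = 0.78, top_k = 10L)
  if (is.null(p_max)) p_max <- def$p_max
  if (is.null(auc_min)) auc_min <- def$auc_min
  if (is.null(top_k)) top_k <- def$top_k
  keep <- stats$p_value < p_max & stats$auc > auc_min
  out <- stats[keep, , drop = FALSE]
  if (nrow(out) > top_k)
    out <- out[seq_len(top_k), , drop = FALSE]
  if (!nrow(out))
    warning("no markers pass the candidate filter", call. = FALSE)
  out
}
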