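# Fixture builders and independent oracles used across the suite.

# Spectrum with Gaussian peaks on a regular grid (optionally noisy)
gauss_spectrum <- function(id = "s1", peaks_mz = 2084, heights = 1000,
                           sigma = 4, lo = 900, hi = 10500, step = 1,
                           baseline = 0, noise_sd = 0, seed = NULL,
                           group = "unknown") {
  if (!is.null(seed)) set.seed(seed)
  mz <- seq(lo, hi, by = step)
  y <- numeric(length(mz))
  for (k in seq_along(peaks_mz))
    y <- y + heights[k] * exp(-(mz - peaks_mz[k])^2 / (2 * sigma^2))
  if (length(baseline) == 1L && baseline[1] != 0)
    y <- y + baseline * exp(-(mz - lo) / 3000)
  if (noise_sd > 0) y <- y + rnorm(length(mz), sd = noise_sd)
  raw_spectrum(id, mz, pmax(y, 0), group = group)
}

# Mark a spectrum as fully preprocessed without altering intensities,
# for tests that exercise peak detection in isolation.
fake_preprocessed <- function(s, noise_scale = 1) {
  s <- serumpeaks:::as_processed(s)
  s$noise_scale <- noise_scale
  s <- serumpeaks:::log_step(s, "denoise_udwt", list())
  serumpeaks:::log_step(s, "normalize_tic", list(target = sum(s$intensity)))
}

# Small peak matrix with planted group separation on selected columns
toy_matrix <- function(n_hc = 10, n_crc = 10, n_clusters = 5,
                       informative = integer(0), shift = 10, sd = 1,
                       seed = 1) {
  set.seed(seed)
  n <- n_hc + n_crc
  vals <- matrix(abs(rnorm(n * n_clusters, 50, sd * 10)), n, n_clusters)
  groups <- c(rep("HC", n_hc), rep("CRC", n_crc))
  for (j in informative)
    vals[groups == "CRC", j] <- vals[groups == "CRC", j] + shift * 10
  peak_matrix(vals, cluster_mz = 1000 + 100 * seq_len(n_clusters),
              samples = sprintf("s%02d", seq_len(n)), groups = groups)
}

# --- independent oracles -------------------------------------------------

# Two-sided exact Wilcoxon rank-sum p by full enumeration of all
# C(n1+n2, n1) group assignments (no ties assumed).
wilcox_enum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx])) -
    n1 * (n1 + 1) / 2
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# AUC by explicit pair counting with ties scored 0.5
auc_pairs <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# The running-centroid clustering rule, written independently and
# deliberately naively: walk sorted m/z, track the open cluster mean.
cluster_oracle <- function(mz_sorted, tol_rel) {
  cl <- integer(length(mz_sorted))
  k <- 0L
  members <- numeric(0)
  for (i in seq_along(mz_sorted)) {
    if (k == 0L ||
        mz_sorted[i] - mean(members) > tol_rel * mean(members)) {
      k <- k + 1L
      members <- numeric(0)
    }
    cl[i] <- k
    members <- c(members, mz_sorted[i])
  }
  cl
}

# Two-group log-rank test computed from first principles: at each
# distinct event time, observed vs hypergeometric-expected events in
# group 1, variance by the standard formula.
logrank_hand <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  tt <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Hanley-McNeil AUC standard error (reference formula)
hanley_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

# Number of planted cluster masses covered by at least one panel member
# (a member at the merge of two nearby planted masses recovers both)
n_planted_recovered <- function(member_mz, planted_mz, tol_rel = 0.003) {
  sum(vapply(planted_mz, function(p)
    any(abs(member_mz - p) <= tol_rel * p), TRUE))
}

# Panel members matching no planted mass at all (false discoveries)
n_noise_members <- function(member_mz, planted_mz, tol_rel = 0.003) {
  sum(vapply(member_mz, function(m)
    !any(abs(planted_mz - m) <= tol_rel * m), TRUE))
}
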