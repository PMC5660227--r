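#' Denoise a spectrum with the undecimated discrete wavelet transform
#'
#' Decomposes the intensity trace with a shift-invariant (stationary)
#' wavelet transform, thresholds the detail coefficients and inverts the
#' transform. The noise scale is estimated robustly from the finest detail
#' level as `sigma = MAD / 0.6745` and the threshold is the universal
#' (VisuShrink) value `sigma * sqrt(2 log n)`.
#'
#' @param s a spectrum (raw or processed).
#' @param wavelet_name wavelet family; `"d8"` (Daubechies 8-tap, the
#'   default) or `"haar"`.
#' @param levels decomposition depth; default `min(6, floor(log2(n)) - 2)`.
#' @param threshold_rule `"universal"` (soft, the default), `"visu-soft"`
#'   (same) or `"visu-hard"`.
#'
#' @return A `processed_spectrum` with `noise_scale` set and the step
#'   appended to `processing_log`. Output length equals input length.
#' @export
denoise_udwt <- function(s, wavelet_name = "d8", levels = NULL,
                         threshold_rule = c("universal", "visu-soft",
                                            "visu-hard")) {
  threshold_rule <- match.arg(threshold_rule)
  s <- as_processed(s)
  n <- length(s$intensity)
  if (is.null(levels)) levels <- min(6L, floor(log2(n)) - 2L)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  if (n < 2L^levels)
    stop("spectrum too short for ", levels, " levels (need length >= ",
         2L^levels, "); reduce levels or zero-pad the input",
         call. = FALSE)
  x <- reflect_pad(s$intensity)
  w <- udwt_forward(x, levels, wavelet_name)
  sigma <- stats::mad(w$details[[1L]][seq_len(n)])
  lambda <- sigma * sqrt(2 * log(n))
  thr <- if (threshold_rule == "visu-hard") hard_threshold else soft_threshold
  w$details <- lapply(w$details, thr, lambda = lambda)
  s$intensity <- udwt_inverse(w)[seq_len(n)]
  s$noise_scale <- sigma
  log_step(s, "denoise_udwt",
           list(wavelet = wavelet_name, levels = levels,
                threshold_rule = threshold_rule, lambda = lambda,
                noise_scale = sigma))
}

# Centered rolling minimum, window radius h points, O(n log h) via
# doubling of trailing-window minima; ends use the truncated window.
rolling_min <- function(x, h) {
  if (h < 1L) return(x)
  n <- length(x)
  w <- 2L * h + 1L
  xp <- c(rep(Inf, h), x, rep(Inf, h))
  f <- xp
  len <- 1L
  while (len < w) {
    s <- min(len, w - len)
    f <- pmin(f, c(rep(Inf, s), f[seq_len(length(f) - s)]))
    len <- len + s
  }
  f[seq_len(n) + 2L * h]
}

rolling_max <- function(x, h) -rolling_min(-x, h)

# Moving average over radius h with edge-value padding
moving_avg <- function(x, h) {
  if (h < 1L) return(x)
  n <- length(x)
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  cs <- cumsum(xp)
  (cs[seq_len(n) + 2L * h] - c(0, cs)[seq_len(n)]) / (2L * h + 1L)
}

#' Correct the baseline of a spectrum
#'
#' Estimates the baseline as the morphological opening of the intensity
#' trace -- a rolling minimum over `window_da` followed by a rolling
#' maximum over the same window -- smoothed with a moving average over
#' `smooth_da`, then subtracts it and clips negatives to zero. The opening
#' tracks any baseline varying slower than `window_da` exactly while never
#' cutting into peaks narrower than the window.
#'
#' @param s a spectrum.
#' @param window_da rolling min/max window width in Daltons; must exceed
#'   the typical peak width (default 200).
#' @param smooth_da moving-average smoothing width in Daltons (default 100).
#'
#' @return A `processed_spectrum` with the estimated baseline recorded in
#'   the processing log.
#' @export
correct_baseline <- function(s, window_da = 200, smooth_da = 100) {
  if (window_da <= 0) stop("window_da must be > 0", call. = FALSE)
  if (smooth_da < 0) stop("smooth_da must be >= 0", call. = FALSE)
  s <- as_processed(s)
  step <- stats::median(diff(s$mz))
  h <- max(1L, floor(window_da / step / 2))
  hs <- floor(smooth_da / step / 2)
  # odd (point-symmetric) edge reflection keeps the opening exact on
  # monotone baselines right up to the spectrum ends
  x <- s$intensity
  n <- length(x)
  p <- min(n - 1L, h + hs + 1L)
  xp <- c(2 * x[1L] - x[1L + seq_len(p)][p:1],
          x,
          2 * x[n] - x[n - seq_len(p)][seq_len(p)])
  opened <- rolling_max(rolling_min(xp, h), h)
  if (hs >= 1L) opened <- moving_avg(opened, hs)
  baseline <- opened[p + seq_len(n)]
  s$intensity <- pmax(s$intensity - baseline, 0)
  s$baseline <- baseline
  log_step(s, "correct_baseline",
           list(window_da = window_da, smooth_da = smooth_da,
                baseline_max = max(baseline)))
}

#' Normalize a spectrum to a target total ion current
#'
#' Scales intensities so their sum equals `target` (conventionally the
#' cohort-mean TIC), making spectra from shots with different overall gain
#' comparable. The stored noise scale is rescaled by the same factor.
#'
#' @param s a spectrum.
#' @param target the total ion current after scaling.
#' @return A `processed_spectrum`.
#' @export
normalize_tic <- function(s, target) {
  if (!is.numeric(target) || target <= 0)
    stop("target must be a positive number", call. = FALSE)
  s <- as_processed(s)
  tic <- sum(s$intensity)
  if (tic <= 0) stop("cannot normalize an all-zero spectrum", call. = FALSE)
  s$intensity <- (s$intensity / tic) * target
  if (is.finite(s$noise_scale)) s$noise_scale <- (s$noise_scale / tic) * target
  log_step(s, "normalize_tic", list(target = target, scale = target / tic))
}

#' Restrict a spectrum to a mass window
#'
#' Retains points with `lo_da <= mz <= hi_da` (closed interval). The
#' default window 900--10500 Da is the recorded acquisition range for
#' linear-mode serum profiling.
#'
#' @param s a spectrum.
#' @param lo_da,hi_da window bounds in Daltons.
#' @return A `processed_spectrum` containing only in-window points.
#' @export
restrict_mass_range <- function(s, lo_da = 900, hi_da = 10500) {
  if (lo_da >= hi_da) stop("lo_da must be < hi_da", call. = FALSE)
  s <- as_processed(s)
  keep <- s$mz >= lo_da & s$mz <= hi_da
  if (sum(keep) < 2L)
    stop("mass window [", lo_da, ", ", hi_da, "] leaves fewer than 2 ",
         "points", call. = FALSE)
  s$mz <- s$mz[keep]
  s$intensity <- s$intensity[keep]
  log_step(s, "restrict_mass_range", list(lo_da = lo_da, hi_da = hi_da))
}

#' Default preprocessing configuration
#'
#' @return A named list with the tunable preprocessing parameters:
#'   mass window, wavelet settings, baseline widths and TIC target
#'   (`NA` = cohort mean).
#' @export
preprocess_config <- function(mass_lo = 900, mass_hi = 10500,
                              wavelet = "d8", levels = NULL,
                              threshold_rule = "universal",
                              baseline_window_da = 200,
                              baseline_smooth_da = 100,
                              tic_target = NA) {
  list(mass_lo = mass_lo, mass_hi = mass_hi, wavelet = wavelet,
       levels = levels, threshold_rule = threshold_rule,
       baseline_window_da = baseline_window_da,
       baseline_smooth_da = baseline_smooth_da, tic_target = tic_target)
}

#' Preprocess one spectrum through the fixed stage order
#'
#' Applies restrict -> denoise -> baseline -> normalize. `tic_target`
#' must be supplied here (single-spectrum use); for cohort processing use
#' [preprocess_cohort()], which normalizes every spectrum to the cohort
#' mean TIC.
#'
#' @param s a spectrum.
#' @param config a [preprocess_config()] list.
#' @param tic_target overrides `config$tic_target`.
#' @return A fully processed `processed_spectrum`.
#' @export
preprocess_spectrum <- function(s, config = preprocess_config(),
                                tic_target = NULL) {
  s <- restrict_mass_range(s, config$mass_lo, config$mass_hi)
  s <- denoise_udwt(s, config$wavelet, config$levels, config$threshold_rule)
  s <- correct_baseline(s, config$baseline_window_da,
                        config$baseline_smooth_da)
  target <- if (!is.null(tic_target)) tic_target else config$tic_target
  if (is.null(target) || is.na(target)) target <- sum(s$intensity)
  normalize_tic(s, target)
}

#' Preprocess a cohort of spectra
#'
#' Runs restrict -> denoise -> baseline on every spectrum, then
#' normalizes all spectra to the cohort-mean total ion current (or to
#' `config$tic_target` when set), so one acquisition's gain never
#' dominates.
#'
#' @param spectra list of spectra.
#' @param config a [preprocess_config()] list.
#' @return A list of fully processed spectra, in input order.
#' @export
preprocess_cohort <- function(spectra, config = preprocess_config()) {
  stage1 <- lapply(spectra, function(s) {
    s <- restrict_mass_range(s, config$mass_lo, config$mass_hi)
    s <- denoise_udwt(s, config$wavelet, config$levels,
                      config$threshold_rule)
    correct_baseline(s, config$baseline_window_da,
                     config$baseline_smooth_da)
  })
  target <- config$tic_target
  if (is.null(target) || is.na(target))
    target <- mean(vapply(stage1, function(s) sum(s$intensity), 0))
  lapply(stage1, normalize_tic, target = target)
}
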