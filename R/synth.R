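# Default planted differential markers: the seven pattern peaks plus the
# three additional shortlist peaks of a serum CRC profiling cohort.
# Directions: 1781, 1868 and 1694 Da up in CRC; the rest down in CRC.
default_planted <- function(fold_change = 2.5) {
  data.frame(
    mz = c(1781, 1868, 1694, 2084, 1947, 6856, 1951, 2886, 2073, 4478),
    direction = c("up_in_CRC", "up_in_CRC", "up_in_CRC",
                  rep("down_in_CRC", 7L)),
    fold_change = fold_change,
    base_height = c(220, 375, 300, 9600, 1000, 1000, 1000, 2775, 917,
                    4153),
    stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Describes a synthetic serum MALDI-TOF cohort: grid, number of common
#' peak clusters, the planted differential markers with direction and
#' fold change, peak shape, baseline, noise and per-spectrum gain. The
#' defaults emulate a discovery cohort of 90 healthy controls and 127
#' CRC patients profiled on a 1-Da grid over 900-10500 Da with 173
#' common peak clusters, 10 of which are differential (3 up, 7 down in
#' CRC) with fold change 2.5.
#'
#' @param n_hc,n_crc cohort sizes.
#' @param mass_lo,mass_hi,grid_step mass grid (Daltons).
#' @param n_common_peaks total peak clusters shared by all samples.
#' @param planted data.frame (`mz`, `direction`, `fold_change`,
#'   `base_height`) of differential markers; default [default_planted()].
#' @param peak_sigma_rel Gaussian peak width as a fraction of m/z
#'   (default 0.002, linear-TOF-like resolution).
#' @param baseline_amp,baseline_decay exponential chemical baseline
#'   `amp * exp(-(mz - mass_lo)/decay)`.
#' @param noise_sd additive Gaussian noise scale (heteroscedastic:
#'   grows with the square root of the local signal).
#' @param gain_range per-spectrum multiplicative gain, drawn uniformly.
#' @param height_meanlog,height_sdlog log-normal distribution of
#'   cluster base heights across clusters.
#' @param within_sdlog per-sample log-normal intensity scatter within a
#'   cluster.
#' @param random_seed integer seed; everything is reproducible from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_hc = 90L, n_crc = 127L, mass_lo = 900,
                         mass_hi = 10500, grid_step = 1,
                         n_common_peaks = 173L,
                         planted = default_planted(),
                         peak_sigma_rel = 0.002, baseline_amp = 300,
                         baseline_decay = 2000, noise_sd = 2,
                         gain_range = c(0.7, 1.3),
                         height_meanlog = log(800), height_sdlog = 0.8,
                         within_sdlog = 0.6, random_seed = 1L) {
  stopifnot(n_hc >= 0L, n_crc >= 0L, mass_lo < mass_hi, grid_step > 0,
            n_common_peaks >= nrow(planted), all(planted$fold_change > 0),
            all(planted$mz > mass_lo & planted$mz < mass_hi))
  structure(as.list(environment()), class = "synth_config")
}

# cohort-level truth: cluster masses and per-group mean heights,
# deterministic given the seed
draw_cluster_truth <- function(cfg) {
  set.seed(cfg$random_seed)
  n_extra <- cfg$n_common_peaks - nrow(cfg$planted)
  min_sep <- function(mz) pmax(8, 0.008 * mz)
  masses <- cfg$planted$mz
  guard <- 0L
  while (n_extra > 0L) {
    cand <- stats::runif(1L, cfg$mass_lo + 50, cfg$mass_hi - 50)
    if (all(abs(masses - cand) > min_sep(cand))) {
      masses <- c(masses, cand)
      n_extra <- n_extra - 1L
    }
    guard <- guard + 1L
    if (guard > 1e5) stop("cannot place common peaks; window too dense",
                          call. = FALSE)
  }
  n <- length(masses)
  base <- c(cfg$planted$base_height,
            stats::rlnorm(n - nrow(cfg$planted), cfg$height_meanlog,
                          cfg$height_sdlog))
  fc <- rep(1, n)
  dirn <- rep("none", n)
  fc[seq_len(nrow(cfg$planted))] <- cfg$planted$fold_change
  dirn[seq_len(nrow(cfg$planted))] <- cfg$planted$direction
  mean_hc <- base
  mean_crc <- ifelse(dirn == "up_in_CRC", base * fc,
                     ifelse(dirn == "down_in_CRC", base / fc, base))
  ord <- order(masses)
  data.frame(mz = masses, mean_hc = mean_hc, mean_crc = mean_crc,
             fold_change = fc, direction = dirn,
             planted = dirn != "none")[ord, , drop = FALSE]
}

#' Generate a synthetic spectrum cohort with known ground truth
#'
#' Draws the common peak-cluster masses once per cohort (planted masses
#' fixed, the rest uniform over the window with a minimum separation),
#' gives each sample log-normal peak heights around group-specific means
#' (planted clusters differ between groups by their fold change in the
#' stated direction), and renders each spectrum as a sum of Gaussian
#' peaks plus an exponentially decaying baseline and heteroscedastic
#' Gaussian noise, all scaled by a per-spectrum gain. If a planted
#' separation falls below the grid resolution the generator errors.
#'
#' @param cfg a [synth_config()].
#' @return A list: `spectra` (list of [raw_spectrum()]), `manifest`
#'   (data.frame), `truth` (per-cluster data.frame + generator config).
#' @export
generate_spectra <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  grid <- seq(cfg$mass_lo, cfg$mass_hi, by = cfg$grid_step)
  if (any(cfg$peak_sigma_rel * cfg$planted$mz < cfg$grid_step / 2))
    stop("planted peak width below grid resolution; refine grid_step",
         call. = FALSE)
  truth <- draw_cluster_truth(cfg)
  n_total <- cfg$n_hc + cfg$n_crc
  ids <- c(sprintf("HC%03d", seq_len(cfg$n_hc)),
           sprintf("CRC%03d", seq_len(cfg$n_crc)))
  groups <- c(rep("HC", cfg$n_hc), rep("CRC", cfg$n_crc))
  manifest <- data.frame(sample_id = ids, group = groups,
                         stringsAsFactors = FALSE)
  if (cfg$n_crc > 0L) {
    # stage mix of a MALDI discovery cohort: 25/36/48/18 over 127
    stage_p <- c(25, 36, 48, 18) / 127
    manifest$stage <- ""
    manifest$stage[manifest$group == "CRC"] <-
      sample(c("I", "II", "III", "IV"), cfg$n_crc, replace = TRUE,
             prob = stage_p)
  }
  sigma <- cfg$peak_sigma_rel * truth$mz
  baseline <- cfg$baseline_amp * exp(-(grid - cfg$mass_lo) /
                                       cfg$baseline_decay)
  # per-cluster support windows (+-5 sigma) on the grid
  windows <- lapply(seq_len(nrow(truth)), function(k) {
    lo <- truth$mz[k] - 5 * sigma[k]
    hi <- truth$mz[k] + 5 * sigma[k]
    i1 <- max(1L, ceiling((lo - cfg$mass_lo) / cfg$grid_step) + 1L)
    i2 <- min(length(grid), floor((hi - cfg$mass_lo) / cfg$grid_step) + 1L)
    idx <- i1:i2
    list(idx = idx,
         shape = exp(-(grid[idx] - truth$mz[k])^2 / (2 * sigma[k]^2)))
  })
  spectra <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    mu <- if (groups[i] == "CRC") truth$mean_crc else truth$mean_hc
    heights <- stats::rlnorm(nrow(truth),
                             log(mu) - cfg$within_sdlog^2 / 2,
                             cfg$within_sdlog)
    signal <- numeric(length(grid))
    for (k in seq_len(nrow(truth))) {
      w <- windows[[k]]
      signal[w$idx] <- signal[w$idx] + heights[k] * w$shape
    }
    gain <- stats::runif(1L, cfg$gain_range[1L], cfg$gain_range[2L])
    clean <- signal + baseline
    noisy <- clean + stats::rnorm(length(grid),
                                  sd = cfg$noise_sd * sqrt(1 + clean / 100))
    spectra[[i]] <- raw_spectrum(ids[i], grid, pmax(gain * noisy, 0),
                                 group = groups[i],
                                 provenance = list(generator = "synth",
                                                   seed = cfg$random_seed))
  }
  truth_out <- list(clusters = truth, config = unclass(cfg),
                    sample_groups = stats::setNames(groups, ids))
  list(spectra = spectra, manifest = manifest, truth = truth_out)
}

#' Generate a discovery + blind-test cohort split
#'
#' Generates one cohort and splits it, in generation order, into a
#' training set (first `n_train_hc` HC + `n_train_crc` CRC samples) and
#' a blind test set (the rest). Both halves share the cohort's cluster
#' masses and group effects; only the per-sample draws differ.
#'
#' @param cfg a [synth_config()].
#' @param n_train_hc,n_train_crc training-set sizes (defaults 63 and 89,
#'   a typical discovery split).
#' @return A list with elements `train` and `test` (each
#'   `list(spectra, manifest)`) plus `truth`.
#' @export
generate_discovery_cohort <- function(cfg = synth_config(),
                                      n_train_hc = 63L,
                                      n_train_crc = 89L) {
  stopifnot(n_train_hc <= cfg$n_hc, n_train_crc <= cfg$n_crc)
  coh <- generate_spectra(cfg)
  is_hc <- coh$manifest$group == "HC"
  train_ids <- c(coh$manifest$sample_id[is_hc][seq_len(n_train_hc)],
                 coh$manifest$sample_id[!is_hc][seq_len(n_train_crc)])
  in_train <- coh$manifest$sample_id %in% train_ids
  pick <- function(keep) {
    list(spectra = coh$spectra[keep],
         manifest = coh$manifest[keep, , drop = FALSE])
  }
  list(train = pick(in_train), test = pick(!in_train), truth = coh$truth)
}

#' Generate a synthetic clinical marker table
#'
#' Emits per-sample MST1 ELISA-like concentrations (ng/ml) from
#' truncated-at-zero normal distributions with group/stage means and SDs
#' defaulting to published serum values (healthy 959.65 +/- 407.07;
#' stage I 343.97 +/- 277.76 down to stage IV 132.49 +/- 138.36), CEA
#' (ug/l) from log-normals with a higher CRC mean, and a binary FOBT
#' with CRC positivity rate 0.641 and healthy positivity 0.
#'
#' @param n_hc number of healthy controls.
#' @param n_crc_by_stage named integer vector, e.g.
#'   `c(I = 10, II = 16, III = 15, IV = 10)`.
#' @param seed integer seed.
#' @param mst1_params named list of `c(mean, sd)` per group
#'   (`HC`, `I`, `II`, `III`, `IV`).
#' @param fobt_rate_crc FOBT positivity in CRC.
#' @return A data.frame with columns `sample_id`, `group`, `stage`,
#'   `mst1`, `cea`, `fobt`.
#' @export
generate_clinical_table <- function(n_hc = 16L,
                                    n_crc_by_stage = c(I = 10L, II = 16L,
                                                       III = 15L,
                                                       IV = 10L),
                                    seed = 1L,
                                    mst1_params = list(
                                      HC = c(959.65, 407.07),
                                      I = c(343.97, 277.76),
                                      II = c(290, 270),
                                      III = c(220, 240),
                                      IV = c(132.49, 138.36)),
                                    fobt_rate_crc = 0.641) {
  stopifnot(n_hc >= 0L, all(n_crc_by_stage >= 0L))
  unknown <- setdiff(names(n_crc_by_stage), c("I", "II", "III", "IV"))
  if (length(unknown))
    stop("unknown stage key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  # Truncated-at-zero normal whose *post-truncation* mean equals `mean`:
  # the published summary statistics are sample moments of non-negative
  # concentrations, so the location parameter is moment-matched first.
  rtnorm <- function(n, mean, sd) {
    if (n == 0L) return(numeric(0))
    trunc_mean <- function(mu) {
      z <- mu / sd
      mu + sd * stats::dnorm(z) / stats::pnorm(z)
    }
    mu <- stats::uniroot(function(m) trunc_mean(m) - mean,
                         lower = mean - 4 * sd, upper = mean + sd,
                         extendInt = "yes")$root
    x <- stats::rnorm(n, mu, sd)
    while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), mu, sd)
    x
  }
  rows <- list()
  if (n_hc > 0L)
    rows[[1L]] <- data.frame(
      sample_id = sprintf("VHC%03d", seq_len(n_hc)), group = "HC",
      stage = "", mst1 = rtnorm(n_hc, mst1_params$HC[1], mst1_params$HC[2]),
      cea = stats::rlnorm(n_hc, log(1.8), 0.6),
      fobt = 0L, stringsAsFactors = FALSE)
  k <- 0L
  for (st in names(n_crc_by_stage)) {
    n <- n_crc_by_stage[[st]]
    if (n == 0L) next
    pr <- mst1_params[[st]]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("VCRC%03d", k + seq_len(n)), group = "CRC",
      stage = st, mst1 = rtnorm(n, pr[1], pr[2]),
      cea = stats::rlnorm(n, log(3.6), 0.9),
      fobt = stats::rbinom(n, 1L, fobt_rate_crc),
      stringsAsFactors = FALSE)
    k <- k + n
  }
  if (!length(rows))
    return(data.frame(sample_id = character(0), group = character(0),
                      stage = character(0), mst1 = numeric(0),
                      cea = numeric(0), fobt = integer(0)))
  do.call(rbind, rows)
}

#' Generate synthetic survival records
#'
#' Expression is log-normal; event times are exponential with the hazard
#' multiplied by `hazard_ratio` for samples whose expression lies below
#' `cutoff_truth` (low expression = worse prognosis). Each subject is,
#' with probability `censor_rate`, given an independent uniform censoring
#' time on (0, `follow_max`); all others are administratively censored at
#' `follow_max`.
#'
#' @param n number of subjects.
#' @param cutoff_truth expression value below which hazard is elevated.
#' @param hazard_ratio hazard multiplier for the low-expression group
#'   (> 0; 1 = no prognostic effect).
#' @param censor_rate probability of early random censoring, in [0, 1).
#' @param seed integer seed.
#' @param base_hazard monthly event hazard of the high-expression group.
#' @param follow_max administrative follow-up horizon in months.
#' @param expr_meanlog,expr_sdlog expression distribution parameters.
#' @return A data.frame with columns `sample_id`, `time` (months),
#'   `event` (1 = death), `expression`, `true_group`.
#' @export
generate_survival <- function(n = 46L, cutoff_truth = 100,
                              hazard_ratio = 4, censor_rate = 0.2,
                              seed = 1L, base_hazard = 0.004,
                              follow_max = 120,
                              expr_meanlog = log(100),
                              expr_sdlog = 0.6) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  if (n == 0L)
    return(data.frame(sample_id = character(0), time = numeric(0),
                      event = integer(0), expression = numeric(0),
                      true_group = character(0)))
  set.seed(seed)
  expr <- stats::rlnorm(n, expr_meanlog, expr_sdlog)
  low <- expr < cutoff_truth
  hz <- ifelse(low, base_hazard * hazard_ratio, base_hazard)
  t_event <- stats::rexp(n, rate = hz)
  cens <- ifelse(stats::runif(n) < censor_rate,
                 stats::runif(n, 0, follow_max), follow_max)
  time <- pmin(t_event, cens)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             time = pmax(time, 1e-3), event = as.integer(t_event <= cens),
             expression = expr,
             true_group = ifelse(low, "low", "high"),
             stringsAsFactors = FALSE)
}
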