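#' Confusion summary from classification counts
#'
#' @param tp,fn,tn,fp case counts (CRC is the positive class).
#' @return An object of class `confusion_summary` with the counts,
#'   unrounded `sensitivity`, `specificity`, `youden`, per-group accuracy,
#'   and display-rounded percentage fields.
#' @export
confusion_summary <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec,
                 youden = sens + spec - 1,
                 accuracy_crc = sens, accuracy_hc = spec),
            class = "confusion_summary")
}

#' Round half-up to a fixed number of decimals
#'
#' Prediction tables conventionally round half-up (98.85 -> 98.9),
#' unlike R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Confusion metrics as display percentages
#'
#' Converts classification counts into the sensitivity / specificity /
#' per-group accuracy percentages of a standard prediction-results table,
#' rounded half-up to one decimal. Pass `NA` for counts of a group that
#' was not tested. A zero denominator yields `NA` (explicitly undefined),
#' never 0.
#'
#' @param tp,fn correct and misjudged positive (CRC) cases.
#' @param tn,fp correct and misjudged negative (HC) cases.
#' @return A list with `sensitivity_pct`, `specificity_pct`,
#'   `accuracy_crc_pct`, `accuracy_hc_pct` (rounded, half-up, 1 decimal)
#'   and the unrounded `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(tp = NA, fn = NA, tn = NA, fp = NA) {
  sens <- if (!is.na(tp) && !is.na(fn) && tp + fn > 0) tp / (tp + fn)
          else NA_real_
  spec <- if (!is.na(tn) && !is.na(fp) && tn + fp > 0) tn / (tn + fp)
          else NA_real_
  list(sensitivity = sens, specificity = spec,
       sensitivity_pct = round_half_up(100 * sens),
       specificity_pct = round_half_up(100 * spec),
       accuracy_crc_pct = round_half_up(100 * sens),
       accuracy_hc_pct = round_half_up(100 * spec))
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(paste0("<confusion_summary> tp=%d fn=%d tn=%d fp=%d | ",
                     "sens %.1f%% spec %.1f%% J=%.3f\n"),
              x$tp, x$fn, x$tn, x$fp, 100 * x$sensitivity,
              100 * x$specificity, x$youden))
  invisible(x)
}

#' Default SVM parameter set
#'
#' Radial-basis-function kernel SVM settings. `gamma = NA` means
#' `1/(n_features * feature_variance)`; features are z-scored inside each
#' training fold, so this resolves to `1/n_features`.
#'
#' @param cost soft-margin cost C (default 1).
#' @param gamma RBF width; `NA` for the scaled default.
#' @return A named list.
#' @export
svm_params <- function(cost = 1, gamma = NA) {
  list(kernel = "radial", cost = cost, gamma = gamma)
}

# log1p then z-score using training-fold statistics; near-constant
# features (zero variance in the fold) are dropped and reported.
fold_standardize <- function(train, test) {
  lt <- log1p(train)
  mu <- colMeans(lt)
  sd_ <- apply(lt, 2L, stats::sd)
  keep <- which(sd_ > 0)
  list(train = sweep(sweep(lt[, keep, drop = FALSE], 2L, mu[keep]), 2L,
                     sd_[keep], "/"),
       test = sweep(sweep(log1p(test)[, keep, drop = FALSE], 2L,
                          mu[keep]), 2L, sd_[keep], "/"),
       dropped = length(sd_) - length(keep), mu = mu, sd = sd_,
       keep = keep)
}

#' Leave-one-out cross-validation of an SVM on a marker subset
#'
#' For every sample: log1p-transform and z-score the selected features on
#' the remaining n-1 samples, fit an RBF-kernel SVM on them, and predict
#' the held-out sample. Deterministic given the matrix, member set and
#' SVM parameters. Features with zero variance in a training fold are
#' dropped for that fold (counted in the result).
#'
#' @param m a [peak_matrix()] with groups HC and CRC, each >= 2 samples.
#' @param members indices or m/z values (matched exactly) of the clusters
#'   to use.
#' @param params [svm_params()] list.
#' @return A `confusion_summary` (CRC positive); attribute
#'   `n_folds_with_dropped` counts folds that lost a degenerate feature.
#' @export
loocv_evaluate <- function(m, members, params = svm_params()) {
  stopifnot(inherits(m, "peak_matrix"))
  idx <- resolve_members(m, members)
  if (!length(idx)) stop("members must be non-empty", call. = FALSE)
  y <- factor(m$groups, levels = c("HC", "CRC"))
  if (any(table(y) < 2L))
    stop("each group needs at least 2 samples", call. = FALSE)
  X <- m$values[, idx, drop = FALSE]
  n <- nrow(X)
  pred <- character(n)
  dropped_folds <- 0L
  for (i in seq_len(n)) {
    st <- fold_standardize(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    if (st$dropped > 0L) dropped_folds <- dropped_folds + 1L
    if (!ncol(st$train)) {  # every feature degenerate: majority vote
      pred[i] <- names(which.max(table(y[-i])))
      next
    }
    g <- if (is.na(params$gamma)) 1 / ncol(st$train) else params$gamma
    fit <- e1071::svm(st$train, y[-i], kernel = "radial",
                      cost = params$cost, gamma = g, scale = FALSE)
    pred[i] <- as.character(stats::predict(fit, st$test))
  }
  cs <- confusion_summary(tp = sum(pred == "CRC" & y == "CRC"),
                          fn = sum(pred == "HC" & y == "CRC"),
                          tn = sum(pred == "HC" & y == "HC"),
                          fp = sum(pred == "CRC" & y == "HC"))
  attr(cs, "n_folds_with_dropped") <- dropped_folds
  cs
}

resolve_members <- function(m, members) {
  if (is.numeric(members) && all(members %in% seq_along(m$cluster_mz)) &&
      all(members == round(members)) && max(members) <= length(m$cluster_mz))
    return(as.integer(members))
  idx <- match(members, m$cluster_mz)
  if (anyNA(idx))
    stop("members not found in matrix: ",
         paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' Genetic-algorithm configuration
#'
#' @param population_size number of chromosomes (>= 2).
#' @param n_generations number of generations.
#' @param crossover_rate uniform-crossover probability per pair.
#' @param mutation_rate per-bit flip probability.
#' @param elitism_count chromosomes copied unchanged each generation.
#' @param max_panel_size maximum number of markers per panel.
#' @param random_seed mandatory integer seed; the search is fully
#'   reproducible from it.
#' @param min_youden_flag panels whose best Youden index falls below this
#'   floor are flagged as low-quality (default 0.5).
#' @return A named list of class `ga_config`.
#' @export
ga_config <- function(population_size = 50L, n_generations = 100L,
                      crossover_rate = 0.8, mutation_rate = 0.02,
                      elitism_count = 2L, max_panel_size = 10L,
                      random_seed = NULL, min_youden_flag = 0.5) {
  if (is.null(random_seed))
    stop("ga_config requires an explicit random_seed", call. = FALSE)
  stopifnot(population_size >= 2L, max_panel_size >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism_count >= 0L, n_generations >= 1L)
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 max_panel_size = as.integer(max_panel_size),
                 random_seed = as.integer(random_seed),
                 min_youden_flag = min_youden_flag),
            class = "ga_config")
}

# drop random extra bits so at most max_panel_size are set; ensure >= 1
repair_chromosome <- function(bits, max_size) {
  on <- which(bits)
  if (length(on) > max_size)
    bits[sample(on, length(on) - max_size)] <- FALSE
  if (!any(bits)) bits[sample.int(length(bits), 1L)] <- TRUE
  bits
}

# fitness comparison: larger Youden, then fewer members, then lower
# summed candidate p-value
fitness_better <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$youden != b$youden) return(a$youden > b$youden)
  if (a$size != b$size) return(a$size < b$size)
  a$sum_p < b$sum_p
}

#' Genetic-algorithm search for the best marker panel
#'
#' Searches subsets of the candidate markers (bit-vector chromosomes with
#' at most `max_panel_size` bits set) for the panel with the highest
#' leave-one-out cross-validated Youden index `J = sensitivity +
#' specificity - 1`. Fitness ties are broken toward fewer members, then
#' toward lower summed candidate p-values. Uniform crossover, per-bit
#' mutation, tournament selection and elitism; the best panel ever seen
#' is returned, and the best-fitness trajectory is non-decreasing by
#' construction. LOOCV results are cached per subset, so runtime scales
#' with the number of distinct subsets visited.
#'
#' @param m training [peak_matrix()].
#' @param candidates data.frame from [filter_candidates()]; its
#'   `cluster_mz` must all be present in `m`.
#' @param cfg a [ga_config()].
#' @param params [svm_params()].
#' @return An object of class `panel`: `member_mz`, `member_idx`,
#'   `svm_params`, `loocv_result` (confusion summary), `youden`,
#'   `trajectory` (best J per generation), `n_evaluations`,
#'   `low_quality` flag and the `ga_config` used.
#' @export
ga_select <- function(m, candidates, cfg, params = svm_params()) {
  stopifnot(inherits(m, "peak_matrix"), inherits(cfg, "ga_config"))
  if (!nrow(candidates)) stop("candidate list is empty", call. = FALSE)
  cand_idx <- resolve_members(m, candidates$cluster_mz)
  K <- length(cand_idx)
  p_values <- candidates$p_value
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  evaluate <- function(bits) {
    key <- paste(which(bits), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    cs <- loocv_evaluate(m, cand_idx[bits], params)
    n_eval <<- n_eval + 1L
    val <- list(youden = cs$youden, size = sum(bits),
                sum_p = sum(p_values[bits]), bits = bits, loocv = cs)
    cache[[key]] <- val
    val
  }
  set.seed(cfg$random_seed)
  pop <- lapply(seq_len(cfg$population_size), function(i) {
    repair_chromosome(stats::runif(K) <
                        min(0.5, cfg$max_panel_size / K),
                      cfg$max_panel_size)
  })
  fits <- lapply(pop, evaluate)
  best <- NULL
  for (f in fits) if (fitness_better(f, best)) best <- f
  trajectory <- numeric(cfg$n_generations)
  for (gen in seq_len(cfg$n_generations)) {
    ord <- order(vapply(fits, `[[`, 0, "youden"),
                 -vapply(fits, `[[`, 0L, "size"),
                 -vapply(fits, `[[`, 0, "sum_p"),
                 decreasing = TRUE)
    elite <- pop[ord[seq_len(min(cfg$elitism_count, length(pop)))]]
    tournament <- function() {
      ij <- sample.int(length(pop), 2L)
      if (fitness_better(fits[[ij[1L]]], fits[[ij[2L]]])) pop[[ij[1L]]]
      else pop[[ij[2L]]]
    }
    children <- list()
    while (length(children) < cfg$population_size - length(elite)) {
      p1 <- tournament()
      p2 <- tournament()
      if (stats::runif(1) < cfg$crossover_rate) {
        mask <- stats::runif(K) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else {
        c1 <- p1
        c2 <- p2
      }
      mutate <- function(b) {
        flip <- stats::runif(K) < cfg$mutation_rate
        repair_chromosome(xor(b, flip), cfg$max_panel_size)
      }
      children <- c(children, list(mutate(c1)), list(mutate(c2)))
    }
    pop <- c(elite, children[seq_len(cfg$population_size - length(elite))])
    fits <- lapply(pop, evaluate)
    for (f in fits) if (fitness_better(f, best)) best <- f
    trajectory[gen] <- best$youden
  }
  structure(list(member_mz = m$cluster_mz[cand_idx[best$bits]],
                 member_idx = cand_idx[best$bits],
                 svm_params = params,
                 loocv_result = best$loocv,
                 youden = best$youden,
                 trajectory = trajectory,
                 n_evaluations = n_eval,
                 low_quality = best$youden < cfg$min_youden_flag,
                 ga_config = cfg),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("<panel> %d markers (%s Da), LOOCV J=%.3f%s\n",
              length(x$member_mz),
              paste(sprintf("%.0f", x$member_mz), collapse = ", "),
              x$youden,
              if (isTRUE(x$low_quality)) " [LOW QUALITY]" else ""))
  invisible(x)
}

#' Exhaustive search over all candidate subsets
#'
#' Evaluates every non-empty subset of up to `max_panel_size` candidates
#' by LOOCV Youden index with the same tie-breaking as [ga_select()].
#' Intended as the reference for small candidate sets.
#'
#' @inheritParams ga_select
#' @param max_panel_size largest subset size considered.
#' @return A `panel` object (without a GA trajectory).
#' @export
exhaustive_select <- function(m, candidates, params = svm_params(),
                              max_panel_size = nrow(candidates)) {
  cand_idx <- resolve_members(m, candidates$cluster_mz)
  K <- length(cand_idx)
  if (K > 16L) stop("exhaustive search limited to 16 candidates",
                    call. = FALSE)
  best <- NULL
  for (code in seq_len(2L^K - 1L)) {
    bits <- as.logical(bitwAnd(code, 2L^(seq_len(K) - 1L)))
    if (sum(bits) > max_panel_size) next
    cs <- loocv_evaluate(m, cand_idx[bits], params)
    f <- list(youden = cs$youden, size = sum(bits),
              sum_p = sum(candidates$p_value[bits]), bits = bits,
              loocv = cs)
    if (fitness_better(f, best)) best <- f
  }
  structure(list(member_mz = m$cluster_mz[cand_idx[best$bits]],
                 member_idx = cand_idx[best$bits],
                 svm_params = params,
                 loocv_result = best$loocv,
                 youden = best$youden,
                 trajectory = numeric(0),
                 n_evaluations = 2L^K - 1L,
                 low_quality = FALSE,
                 ga_config = NULL),
            class = "panel")
}

#' Fit the final SVM classifier on the full training matrix
#'
#' Freezes the log1p/z-score standardization parameters on the complete
#' training set and fits the RBF SVM on the panel members. The returned
#' handle carries everything needed to score new samples without touching
#' training data again.
#'
#' @param m training [peak_matrix()].
#' @param panel a `panel` from [ga_select()] or [exhaustive_select()].
#' @return An object of class `panel_model`.
#' @export
fit_final <- function(m, panel) {
  stopifnot(inherits(panel, "panel"))
  idx <- tryCatch(resolve_members(m, panel$member_mz),
                  error = function(e) stop("panel members absent from ",
                                           "matrix: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  X <- log1p(m$values[, idx, drop = FALSE])
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  if (any(sd_ == 0))
    stop("panel member with zero variance in training matrix",
         call. = FALSE)
  Xs <- sweep(sweep(X, 2L, mu), 2L, sd_, "/")
  y <- factor(m$groups, levels = c("HC", "CRC"))
  g <- if (is.na(panel$svm_params$gamma)) 1 / ncol(Xs)
       else panel$svm_params$gamma
  fit <- e1071::svm(Xs, y, kernel = "radial",
                    cost = panel$svm_params$cost, gamma = g,
                    scale = FALSE)
  cfg <- list(member_mz = panel$member_mz, svm_params = panel$svm_params,
              mu = unname(mu), sd = unname(sd_))
  structure(list(panel = panel, svm_fit = fit, mu = mu, sd = sd_,
                 gamma = g, member_mz = panel$member_mz,
                 config_hash = config_hash(cfg)),
            class = "panel_model")
}

# stable content hash of a config list (hex digest of a serialized copy)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Evaluate a fitted panel model on a blind test matrix
#'
#' Matches the panel's member m/z values to the test matrix clusters
#' within the clustering tolerance, applies the frozen training
#' standardization (no refit, no re-standardization on test data) and
#' scores the predictions. Test labels are consulted only at the scoring
#' step.
#'
#' @param model a `panel_model` from [fit_final()].
#' @param test test-set [peak_matrix()].
#' @param tol_rel m/z matching tolerance (fraction; default 0.003).
#' @return A `confusion_summary` over the test samples.
#' @export
blind_test <- function(model, test, tol_rel = 0.003) {
  stopifnot(inherits(model, "panel_model"), inherits(test, "peak_matrix"))
  if (!length(test$samples)) stop("test matrix is empty", call. = FALSE)
  idx <- vapply(model$member_mz, function(mz) {
    d <- abs(test$cluster_mz - mz)
    j <- which.min(d)
    if (d[j] <= tol_rel * mz) j else NA_integer_
  }, 0L)
  if (anyNA(idx))
    stop("test matrix lacks clusters matching panel m/z: ",
         paste(sprintf("%.1f", model$member_mz[is.na(idx)]),
               collapse = ", "), call. = FALSE)
  X <- log1p(test$values[, idx, drop = FALSE])
  Xs <- sweep(sweep(X, 2L, model$mu), 2L, model$sd, "/")
  pred <- as.character(stats::predict(model$svm_fit, Xs))
  y <- factor(test$groups, levels = c("HC", "CRC"))
  confusion_summary(tp = sum(pred == "CRC" & y == "CRC"),
                    fn = sum(pred == "HC" & y == "CRC"),
                    tn = sum(pred == "HC" & y == "HC"),
                    fp = sum(pred == "CRC" & y == "HC"))
}
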