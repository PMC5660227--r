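#' Assemble a full run configuration
#'
#' Nested configuration for the end-to-end driver. A single global seed
#' fans out to per-stage seeds through a fixed counter-based derivation,
#' so any stage can be re-run in isolation with its own seed.
#'
#' @param random_seed global integer seed.
#' @param preprocess a [preprocess_config()] list.
#' @param peakcall list of peak-calling parameters (`snr_min`,
#'   `min_sep_da`, `tol_rel`, `min_prevalence`).
#' @param rank list of candidate-filter parameters (`preset` or explicit
#'   `p_max`, `auc_min`, `top_k`).
#' @param ga list of [ga_config()] arguments (seed is filled in from the
#'   global seed unless given).
#' @param svm list of [svm_params()] arguments.
#' @return A list of class `run_config`.
#' @export
run_config <- function(random_seed = 1L,
                       preprocess = preprocess_config(),
                       peakcall = list(snr_min = 3, min_sep_da = NULL,
                                       tol_rel = 0.003,
                                       min_prevalence = 0.1),
                       rank = list(preset = "shortlist"),
                       ga = list(population_size = 16L,
                                 n_generations = 10L),
                       svm = list(cost = 1, gamma = NA)) {
  structure(list(random_seed = as.integer(random_seed),
                 preprocess = preprocess, peakcall = peakcall,
                 rank = rank, ga = ga, svm = svm),
            class = "run_config")
}

# counter-based stage seed derivation; stays below 2^31
stage_seed <- function(global_seed, stage_index) {
  as.integer((as.numeric(global_seed) * 48271 + stage_index * 10007) %%
               2147483647)
}

#' Run the discovery pipeline: spectra to validated panel
#'
#' Executes preprocess -> peak calling -> Wilcoxon ranking -> candidate
#' filtering -> GA panel selection -> final SVM fit -> blind-set
#' evaluation. Train and test sample ids must be disjoint (leakage
#' guard); blind labels are used only when scoring predictions.
#'
#' @param config a [run_config()].
#' @param train_spectra,train_manifest discovery set.
#' @param test_spectra,test_manifest blind set.
#' @return A list of class `discovery_report`: `panel`, `model`,
#'   `loocv` and `blind` confusion summaries, `markers` (full ranking),
#'   `candidates`, `n_clusters`, the `config` echoed, and `tables` in
#'   training/blind prediction-table layout.
#' @export
run_discovery <- function(config, train_spectra, train_manifest,
                          test_spectra, test_manifest) {
  stopifnot(inherits(config, "run_config"))
  overlap <- intersect(train_manifest$sample_id, test_manifest$sample_id)
  if (length(overlap))
    stop("train/test sample ids overlap: ",
         paste(utils::head(overlap, 5L), collapse = ", "), call. = FALSE)
  if (length(unique(train_manifest$group)) < 2L)
    stop("training set must contain both groups", call. = FALSE)
  pc <- config$peakcall
  train_proc <- preprocess_cohort(train_spectra, config$preprocess)
  train_mat <- call_peak_matrix(train_proc, train_manifest,
                                snr_min = pc$snr_min,
                                min_sep_da = pc$min_sep_da,
                                tol_rel = pc$tol_rel,
                                min_prevalence = pc$min_prevalence)
  markers <- wilcoxon_rank_markers(train_mat)
  candidates <- do.call(filter_candidates,
                        c(list(stats = markers), config$rank))
  if (!nrow(candidates))
    stop("no candidate markers pass the filter", call. = FALSE)
  ga_args <- config$ga
  if (is.null(ga_args$random_seed))
    ga_args$random_seed <- stage_seed(config$random_seed, 4L)
  cfg_ga <- do.call(ga_config, ga_args)
  params <- do.call(svm_params, config$svm)
  panel <- ga_select(train_mat, candidates, cfg_ga, params)
  model <- fit_final(train_mat, panel)
  test_proc <- preprocess_cohort(test_spectra, config$preprocess)
  test_mat <- call_peak_matrix(test_proc, test_manifest,
                               snr_min = pc$snr_min,
                               min_sep_da = pc$min_sep_da,
                               tol_rel = pc$tol_rel,
                               min_prevalence = pc$min_prevalence)
  blind <- blind_test(model, test_mat, tol_rel = pc$tol_rel)
  loocv <- panel$loocv_result
  layout <- function(cs, n_hc, n_crc) {
    data.frame(
      group = c("HC", "CRC"),
      total = c(n_hc, n_crc),
      correct = c(cs$tn, cs$tp),
      misjudged = c(cs$fp, cs$fn),
      sensitivity_pct = c(NA, round_half_up(100 * cs$sensitivity)),
      specificity_pct = c(round_half_up(100 * cs$specificity), NA))
  }
  structure(list(
    panel = panel, model = model, loocv = loocv, blind = blind,
    markers = markers, candidates = candidates,
    n_clusters = length(train_mat$cluster_mz),
    train_matrix = train_mat, test_matrix = test_mat,
    config = config,
    tables = list(
      training = layout(loocv, sum(train_mat$groups == "HC"),
                        sum(train_mat$groups == "CRC")),
      blind = layout(blind, sum(test_mat$groups == "HC"),
                     sum(test_mat$groups == "CRC")))),
    class = "discovery_report")
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("Discovery report\n================\n")
  print(x$panel)
  cat(sprintf("clusters: %d; candidates: %d\n", x$n_clusters,
              nrow(x$candidates)))
  cat("\nTraining (LOOCV):\n")
  print(x$tables$training, row.names = FALSE)
  cat("\nBlind test:\n")
  print(x$tables$blind, row.names = FALSE)
  invisible(x)
}

#' Write a discovery report to JSON (plus a Markdown summary)
#'
#' @param report a `discovery_report`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_discovery_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_counts <- function(cs) cs[c("tp", "fn", "tn", "fp", "sensitivity",
                                 "specificity", "youden")]
  payload <- list(
    panel = list(member_mz = report$panel$member_mz,
                 youden = report$panel$youden,
                 n_evaluations = report$panel$n_evaluations,
                 trajectory = report$panel$trajectory,
                 low_quality = report$panel$low_quality),
    loocv = as_counts(report$loocv),
    blind = as_counts(report$blind),
    n_clusters = report$n_clusters,
    config = list(random_seed = report$config$random_seed,
                  preprocess = report$config$preprocess,
                  peakcall = report$config$peakcall,
                  rank = report$config$rank, ga = report$config$ga,
                  svm = report$config$svm),
    config_hash = report$model$config_hash)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  md <- c("# Discovery report", "",
          sprintf("Panel: %s Da (LOOCV J = %.3f)",
                  paste(sprintf("%.0f", report$panel$member_mz),
                        collapse = ", "), report$panel$youden), "",
          "## Training (LOOCV)", "",
          knit_table(report$tables$training), "",
          "## Blind test", "", knit_table(report$tables$blind))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

knit_table <- function(d) {
  fmt <- function(v) ifelse(is.na(v), "/", format(v, trim = TRUE))
  header <- paste0("| ", paste(names(d), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
  rows <- apply(d, 1L, function(r) paste0("| ", paste(fmt(r),
                                                      collapse = " | "),
                                          " |"))
  c(header, sep, rows)
}

#' Run the validation layer on clinical and survival tables
#'
#' Computes per-marker ROC curves (MST1, CEA) for CRC vs HC and for the
#' early-stage subset (stage I-II vs HC), the logistic combination of
#' MST1 + CEA + FOBT, group comparisons, and -- when a survival table is
#' given -- ROC-derived high/low dichotomization of expression by 5-year
#' outcome followed by Kaplan-Meier curves and a log-rank test.
#'
#' @param clinical data.frame with columns `group`, `stage`, `mst1`,
#'   `cea`, `fobt`.
#' @param survival_tab optional data.frame with `time`, `event`,
#'   `expression`.
#' @return A list of class `validation_report`.
#' @export
run_validation <- function(clinical, survival_tab = NULL) {
  if (is.null(clinical) || !nrow(clinical))
    stop("clinical table is empty", call. = FALSE)
  need <- c("group", "stage", "mst1", "cea", "fobt")
  missing <- setdiff(need, names(clinical))
  if (length(missing))
    stop("clinical table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  is_crc <- clinical$group == "CRC"
  # MST1 is lower in CRC; CEA higher. Orient each marker so that the
  # positive (CRC) class is flagged by its pathological direction.
  roc_mst1 <- roc_analysis(clinical$mst1, is_crc, positive_high = FALSE)
  roc_cea <- roc_analysis(log(clinical$cea), is_crc, positive_high = TRUE)
  early <- clinical$stage %in% c("I", "II") | !is_crc
  roc_mst1_early <- roc_analysis(clinical$mst1[early], is_crc[early],
                                 positive_high = FALSE)
  roc_cea_early <- roc_analysis(log(clinical$cea[early]), is_crc[early],
                                positive_high = TRUE)
  comb <- combine_markers(
    data.frame(mst1 = as.numeric(scale(clinical$mst1)),
               log_cea = as.numeric(scale(log(clinical$cea))),
               fobt = clinical$fobt),
    is_crc)
  cmp_groups <- group_compare(clinical$mst1, clinical$group,
                              design = "welch")
  stage_levels <- c("I", "II", "III", "IV")
  crc_staged <- clinical[is_crc & clinical$stage %in% stage_levels, ]
  cmp_stages <- if (length(unique(crc_staged$stage)) >= 2L)
    group_compare(crc_staged$mst1, crc_staged$stage, design = "anova")
  else NULL
  table4 <- data.frame(
    comparison = c("MST1 in CRC vs HC", "CEA in CRC vs HC",
                   "MST1 in early stage CRC vs HC",
                   "CEA in early stage CRC vs HC"),
    auc = c(roc_mst1$auc, roc_cea$auc, roc_mst1_early$auc,
            roc_cea_early$auc),
    ci_lo = c(roc_mst1$auc_ci_95[1], roc_cea$auc_ci_95[1],
              roc_mst1_early$auc_ci_95[1], roc_cea_early$auc_ci_95[1]),
    ci_hi = c(roc_mst1$auc_ci_95[2], roc_cea$auc_ci_95[2],
              roc_mst1_early$auc_ci_95[2], roc_cea_early$auc_ci_95[2]),
    sensitivity_pct = round_half_up(100 * c(
      roc_mst1$sens_at_cutoff, roc_cea$sens_at_cutoff,
      roc_mst1_early$sens_at_cutoff, roc_cea_early$sens_at_cutoff)),
    specificity_pct = round_half_up(100 * c(
      roc_mst1$spec_at_cutoff, roc_cea$spec_at_cutoff,
      roc_mst1_early$spec_at_cutoff, roc_cea_early$spec_at_cutoff)))
  surv <- NULL
  if (!is.null(survival_tab) && nrow(survival_tab)) {
    need_s <- c("time", "event", "expression")
    miss_s <- setdiff(need_s, names(survival_tab))
    if (length(miss_s))
      stop("survival table missing column(s): ",
           paste(miss_s, collapse = ", "), call. = FALSE)
    dead5y <- as.integer(survival_tab$event == 1 &
                           survival_tab$time <= 60)
    dich <- dichotomize_by_outcome_roc(survival_tab$expression, dead5y)
    km <- km_logrank(survival_tab$time, survival_tab$event, dich$groups)
    surv <- list(dichotomy = dich, km = km,
                 n_high = sum(dich$groups == "high"),
                 n_low = sum(dich$groups == "low"))
  }
  structure(list(roc_mst1 = roc_mst1, roc_cea = roc_cea,
                 roc_mst1_early = roc_mst1_early,
                 roc_cea_early = roc_cea_early,
                 combination = comb, table4 = table4,
                 compare_groups = cmp_groups,
                 compare_stages = cmp_stages, survival = surv),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report\n=================\n")
  print(x$table4, row.names = FALSE, digits = 3)
  cat(sprintf("\nCombined MST1+CEA+FOBT AUC: %.3f\n",
              x$combination$roc$auc))
  if (!is.null(x$survival))
    cat(sprintf("log-rank: chisq %.2f, p %.4g (high n=%d, low n=%d)\n",
                x$survival$km$chisq, x$survival$km$p, x$survival$n_high,
                x$survival$n_low))
  invisible(x)
}
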