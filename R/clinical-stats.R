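#' Empirical ROC analysis with Youden-optimal cutoff
#'
#' Builds the empirical ROC curve over all distinct score thresholds
#' (midpoints between consecutive unique scores, plus the extremes),
#' computes the AUC by the Mann-Whitney statistic (ties 0.5; identical to
#' the trapezoidal area under the empirical curve), a 95% confidence
#' interval by the Hanley-McNeil formula, and the cutoff maximizing the
#' Youden index `J = sensitivity + specificity - 1`. When several
#' thresholds tie for the maximal J, the one closest to the median score
#' is reported (the midpoint of the two closest if equidistant).
#'
#' @param scores numeric marker values.
#' @param labels binary labels; `TRUE`/1 (or the `positive` level) marks
#'   the positive class.
#' @param positive_high if `TRUE` (default) higher scores indicate the
#'   positive class; a sample is called positive when `score > cutoff`.
#' @param positive the label value treated as positive, default the
#'   larger/`TRUE` one.
#'
#' @return An object of class `roc_result`: `thresholds`, `tpr`, `fpr`,
#'   `auc`, `auc_ci_95`, `youden_cutoff`, `sens_at_cutoff`,
#'   `spec_at_cutoff`, `n_pos`, `n_neg`, `positive_high`.
#' @export
roc_analysis <- function(scores, labels, positive_high = TRUE,
                         positive = NULL) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (is.null(positive)) {
    u <- sort(unique(labels))
    if (length(u) != 2L) stop("labels must contain exactly two classes",
                              call. = FALSE)
    positive <- u[2L]
  }
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  s <- if (positive_high) scores else -scores
  uq <- sort(unique(s))
  if (length(uq) < 2L)
    stop("scores are constant; ROC analysis undefined", call. = FALSE)
  thr <- c(uq[1L] - 1, (uq[-length(uq)] + uq[-1L]) / 2, uq[length(uq)] + 1)
  tpr <- vapply(thr, function(t) sum(s[pos] > t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(s[!pos] > t) / n_neg, 0)
  # sweep from the strictest threshold down: tpr and fpr non-decreasing
  sweep_ord <- order(thr, decreasing = TRUE)
  thr <- thr[sweep_ord]
  tpr <- tpr[sweep_ord]
  fpr <- fpr[sweep_ord]
  auc <- mann_whitney_u(s[pos], s[!pos]) / (n_pos * n_neg)
  # Hanley & McNeil (1982) analytic standard error
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  j <- tpr + (1 - fpr) - 1
  jmax <- max(j)
  cand <- thr[j >= jmax - 1e-12]
  med <- stats::median(s)
  d <- abs(cand - med)
  nearest <- cand[d <= min(d) + 1e-12]
  cutoff <- mean(range(nearest))
  at <- which.min(abs(thr - cutoff))
  res <- structure(list(
    thresholds = if (positive_high) thr else -thr,
    tpr = tpr, fpr = fpr, auc = auc, auc_se = se, auc_ci_95 = ci,
    youden_cutoff = if (positive_high) cutoff else -cutoff,
    sens_at_cutoff = tpr[at], spec_at_cutoff = 1 - fpr[at],
    n_pos = n_pos, n_neg = n_neg, positive_high = positive_high),
    class = "roc_result")
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), cutoff ",
                     "%.4g: sens %.1f%%, spec %.1f%% (n=%d/%d)\n"),
              x$auc, x$auc_ci_95[1], x$auc_ci_95[2], x$youden_cutoff,
              100 * x$sens_at_cutoff, 100 * x$spec_at_cutoff,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Combine markers by logistic regression and score the combination
#'
#' Fits an additive logistic model on the supplied features (continuous
#' features z-scored, binary 0/1 features entered as-is), takes the
#' fitted linear predictor as the combined score and runs
#' [roc_analysis()] on it. Rows with missing feature values are dropped
#' (count reported). If the classes are perfectly separated the model is
#' refit with a small ridge penalty instead of failing.
#'
#' @param features data.frame of marker columns (e.g. MST1, CEA, FOBT).
#' @param labels binary class labels, positive = disease.
#' @return A list: `score` (combined score per retained row), `roc`
#'   (a `roc_result`), `coefficients`, `n_dropped_rows`, `ridge`
#'   (logical: ridge fallback used).
#' @export
combine_markers <- function(features, labels) {
  features <- as.data.frame(features)
  keep_cols <- vapply(features, function(f) length(unique(f[!is.na(f)])) > 1L,
                      TRUE)
  if (!all(keep_cols)) {
    warning("dropping constant feature(s): ",
            paste(names(features)[!keep_cols], collapse = ", "),
            call. = FALSE)
    features <- features[, keep_cols, drop = FALSE]
  }
  if (!ncol(features)) stop("no usable features", call. = FALSE)
  complete <- stats::complete.cases(features) & !is.na(labels)
  n_dropped <- sum(!complete)
  features <- features[complete, , drop = FALSE]
  labels <- labels[complete]
  y <- as.integer(labels == sort(unique(labels))[2L])
  X <- as.matrix(vapply(features, function(f) {
    f <- as.numeric(f)
    if (all(f %in% c(0, 1))) f else as.numeric(scale(f))
  }, numeric(nrow(features))))
  fit <- suppressWarnings(stats::glm(y ~ X, family = stats::binomial()))
  separated <- !fit$converged || any(abs(stats::coef(fit)[-1L]) > 15)
  ridge <- FALSE
  if (separated) {
    ridge <- TRUE
    Xr <- if (ncol(X) == 1L) cbind(X, 0) else X  # glmnet needs >= 2 cols
    gf <- glmnet::glmnet(Xr, y, family = "binomial", alpha = 0,
                         lambda = 1e-3)
    beta <- as.numeric(gf$beta)[seq_len(ncol(X))]
    score <- drop(X %*% beta) + gf$a0
    coefs <- c(intercept = unname(gf$a0),
               stats::setNames(beta, colnames(features)))
  } else {
    score <- drop(stats::predict(fit, type = "link"))
    coefs <- stats::setNames(stats::coef(fit),
                             c("intercept", colnames(features)))
  }
  list(score = score, roc = roc_analysis(score, y, positive_high = TRUE),
       coefficients = coefs, n_dropped_rows = n_dropped, ridge = ridge)
}

#' Two-group or multi-group comparison of quantitative data
#'
#' Standard two-sided comparisons: Student's t-test (`"t_test"`), Welch's
#' t-test (`"welch"`) or one-way ANOVA (`"anova"`). When every
#' observation equals every other the statistic is 0 and p is 1 by
#' convention; when within-group variance is zero everywhere but the
#' group means differ the test is undefined and errors.
#'
#' @param values numeric observations.
#' @param group_labels group membership, >= 2 groups, each >= 2 values.
#' @param design `"t_test"`, `"welch"` or `"anova"`.
#' @return A list with `statistic`, `p_value`, `design`, `df`.
#' @export
group_compare <- function(values, group_labels,
                          design = c("t_test", "welch", "anova")) {
  design <- match.arg(design)
  g <- factor(group_labels)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("each group needs >= 2 values",
                               call. = FALSE)
  vars <- tapply(values, g, stats::var)
  if (all(vars == 0)) {
    means <- tapply(values, g, mean)
    if (all(means == means[1]))
      return(list(statistic = 0, p_value = 1, design = design,
                  df = NA_real_))
    stop("zero within-group variance in every group with unequal means; ",
         "test undefined", call. = FALSE)
  }
  if (design == "anova") {
    fit <- stats::aov(values ~ g)
    tab <- summary(fit)[[1L]]
    return(list(statistic = tab[["F value"]][1L],
                p_value = tab[["Pr(>F)"]][1L], design = design,
                df = tab[["Df"]]))
  }
  if (nlevels(g) != 2L)
    stop("t-tests require exactly 2 groups; use design = 'anova'",
         call. = FALSE)
  tt <- stats::t.test(values ~ g, var.equal = design == "t_test")
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       design = design, df = unname(tt$parameter))
}

#' Dichotomize expression by outcome-driven ROC cutoff
#'
#' Determines the expression cutoff that best separates a binary outcome
#' (e.g. dead vs alive) via the Youden index of [roc_analysis()], then
#' splits samples into `high` (> cutoff) and `low` (<= cutoff) groups.
#' Orientation is chosen automatically so the reported AUC is >= 0.5.
#'
#' @param expression continuous marker values.
#' @param outcome binary outcome; `TRUE`/1 = event (death).
#' @return A list: `cutoff`, `groups` (factor high/low), `roc`, and
#'   `direction` (`"low_expression_risk"` or `"high_expression_risk"`).
#' @export
dichotomize_by_outcome_roc <- function(expression, outcome) {
  if (length(unique(expression)) < 2L)
    stop("expression is constant; cannot dichotomize", call. = FALSE)
  r_hi <- roc_analysis(expression, outcome, positive_high = TRUE)
  r <- if (r_hi$auc >= 0.5) r_hi
       else roc_analysis(expression, outcome, positive_high = FALSE)
  groups <- factor(ifelse(expression > r$youden_cutoff, "high", "low"),
                   levels = c("low", "high"))
  list(cutoff = r$youden_cutoff, groups = groups, roc = r,
       direction = if (r$positive_high) "high_expression_risk"
                   else "low_expression_risk")
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the standard two-group
#' log-rank statistic (hypergeometric variance, ties handled by the
#' standard formula), with a two-sided p-value from the chi-square(1)
#' distribution.
#'
#' @param time follow-up time in months (> 0).
#' @param event 1 = death, 0 = censored.
#' @param group two-level group factor (e.g. high/low expression).
#' @return A list: `fit` (a [survival::survfit] object), `chisq`, `p`,
#'   `n_events`.
#' @export
km_logrank <- function(time, event, group) {
  if (any(time <= 0)) stop("time must be > 0", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  g <- factor(group)
  if (nlevels(g) != 2L) stop("exactly 2 groups required", call. = FALSE)
  if (sum(event) < 1L)
    stop("no events; log-rank test undefined", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, rho = 0)
  p <- stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd_$chisq), p = p,
       n_events = sum(event))
}
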