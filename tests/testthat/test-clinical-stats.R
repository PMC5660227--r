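test_that("ROC worked examples match pair counting", {
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_cutoff, 2.5)
  expect_equal(r$sens_at_cutoff, 1)
  expect_equal(r$spec_at_cutoff, 1)
  expect_equal(roc_analysis(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_analysis(c(1, 2, 2, 3), c(0, 0, 1, 1))$auc, 0.875)
  expect_error(roc_analysis(1:4, rep(1, 4)), "two classes")
  expect_error(roc_analysis(rep(2, 4), c(0, 0, 1, 1)), "constant")
})

test_that("empirical AUC equals the pair-counting oracle on random instances", {
  set.seed(20)
  for (i in 1:100) {
    n_pos <- sample(3:12, 1)
    n_neg <- sample(3:12, 1)
    scores <- c(sample(1:20, n_pos, TRUE), sample(1:20, n_neg, TRUE))
    labels <- c(rep(1, n_pos), rep(0, n_neg))
    if (length(unique(scores)) < 2) next
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, auc_pairs(scores[labels == 1],
                                  scores[labels == 0]),
                 info = paste("instance", i))
    expect_true(all(diff(r$tpr) >= 0))
    expect_true(all(diff(r$fpr) >= 0))
    expect_gte(r$auc, r$auc_ci_95[1])
    expect_lte(r$auc, r$auc_ci_95[2])
    expect_equal(r$auc_se, hanley_se(r$auc, n_pos, n_neg))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:20) {
    scores <- rnorm(40)
    labels <- rbinom(40, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_analysis(scores, labels)
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<")))
    expect_equal(r$auc, as.numeric(ref))
  }
})

test_that("orientation flip leaves the AUC unchanged", {
  set.seed(22)
  scores <- rnorm(30)
  labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- c(0, 1)
  a <- roc_analysis(scores, labels, positive_high = TRUE)$auc
  b <- roc_analysis(-scores, labels, positive_high = FALSE)$auc
  expect_equal(a, b)
})

test_that("binormal scores approach the theoretical AUC and cutoff", {
  set.seed(23)
  neg <- rnorm(2000, 0, 1)
  pos <- rnorm(2000, 2, 1)
  r <- roc_analysis(c(neg, pos), c(rep(0, 2000), rep(1, 2000)))
  expect_lt(abs(r$auc - pnorm(2 / sqrt(2))), 0.02)
  expect_lt(abs(r$youden_cutoff - 1), 0.15)
})

test_that("logistic combination of a single feature preserves its ROC", {
  set.seed(24)
  x <- c(rnorm(40, 0), rnorm(40, 1.5))
  y <- c(rep(0, 40), rep(1, 40))
  comb <- combine_markers(data.frame(m = x), y)
  expect_equal(comb$roc$auc, roc_analysis(x, y)$auc)
})

test_that("combining informative features does not lose discrimination", {
  set.seed(25)
  n <- 250
  y <- rep(c(0, 1), each = n)
  f1 <- rnorm(2 * n, mean = y * 1.2)
  f2 <- rnorm(2 * n, mean = y * 1.0)
  comb <- combine_markers(data.frame(f1 = f1, f2 = f2), y)
  best_single <- max(roc_analysis(f1, y)$auc, roc_analysis(f2, y)$auc)
  expect_gte(comb$roc$auc, best_single - 0.02)
})

test_that("constant features are dropped and separation triggers ridge", {
  set.seed(26)
  y <- rep(c(0, 1), each = 10)
  expect_warning(
    comb <- combine_markers(data.frame(good = rnorm(20, y),
                                       flat = rep(3, 20)), y),
    "constant")
  expect_named(comb$coefficients, c("intercept", "good"))
  sep <- combine_markers(data.frame(perfect = y * 10 + rnorm(20, 0, 0.01)),
                         y)
  expect_true(sep$ridge)
  expect_equal(sep$roc$auc, 1)
})

test_that("group comparisons return standard statistics", {
  # 3x3 worked ANOVA fixture: groups (1,2,3), (2,3,4), (6,7,8)
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- group_compare(v, g, design = "anova")
  # hand calculation: SSB = 42, SSW = 6, F = (42/2)/(6/6) = 21
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, pf(21, 2, 6, lower.tail = FALSE))
  tt <- group_compare(c(1, 2, 3, 5, 6, 7), rep(c("x", "y"), each = 3),
                      design = "t_test")
  ref <- t.test(c(1, 2, 3), c(5, 6, 7), var.equal = TRUE)
  expect_equal(tt$p_value, ref$p.value)
  expect_equal(abs(tt$statistic), abs(unname(ref$statistic)))
  eq <- group_compare(rep(5, 6), rep(c("x", "y"), each = 3))
  expect_equal(eq$p_value, 1)
  expect_error(group_compare(c(1, 1, 1, 2, 2, 2),
                             rep(c("x", "y"), each = 3)), "undefined")
})

test_that("permuted labels give well-calibrated p-values", {
  set.seed(27)
  hits <- vapply(1:200, function(i) {
    v <- rnorm(20)
    g <- sample(rep(c("a", "b"), 10))
    group_compare(v, g, design = "welch")$p_value
  }, 0)
  expect_gt(mean(hits > 0.05), 0.90)  # ~95% expected
  ks <- suppressWarnings(ks.test(hits, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("outcome-driven dichotomization recovers a planted cutoff", {
  expr <- c(1, 2, 3, 4, 10, 11, 12, 13)
  outcome <- c(1, 1, 1, 1, 0, 0, 0, 0)  # low expression -> death
  d <- dichotomize_by_outcome_roc(expr, outcome)
  expect_gt(d$cutoff, 4)
  expect_lt(d$cutoff, 10)
  expect_identical(as.character(d$groups),
                   rep(c("low", "high"), each = 4))
  expect_identical(d$direction, "low_expression_risk")
  set.seed(28)
  sim <- generate_survival(n = 46, cutoff_truth = 100, hazard_ratio = 6,
                           seed = 28)
  dead5y <- as.integer(sim$event == 1 & sim$time <= 60)
  d2 <- dichotomize_by_outcome_roc(sim$expression, dead5y)
  gaps <- sort(sim$expression)
  slot <- findInterval(d2$cutoff, gaps)
  true_slot <- findInterval(100, gaps)
  expect_lte(abs(slot - true_slot), 6)
  expect_error(dichotomize_by_outcome_roc(rep(1, 10), rbinom(10, 1, 0.5)),
               "constant")
})

test_that("log-rank matches the hand-computed 6-record example", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  group <- rep(c("A", "B"), each = 3)
  res <- km_logrank(time, event, group)
  hand <- logrank_hand(time, event, group)
  expect_equal(res$chisq, hand$chisq, tolerance = 1e-10)
  expect_equal(res$p, hand$p, tolerance = 1e-10)
  # identical groups -> no signal
  t2 <- rep(c(3, 5, 8), 2)
  e2 <- rep(c(1, 0, 1), 2)
  same <- km_logrank(t2, e2, rep(c("A", "B"), each = 3))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-10)
  expect_error(km_logrank(c(1, 2, 3, 4), rep(0, 4),
                          rep(c("A", "B"), 2)), "no events")
})

test_that("KM with no censoring equals the empirical survival function", {
  time <- c(2, 4, 4, 7, 9, 12)
  event <- rep(1, 6)
  fit <- km_logrank(c(time, time + 1), rep(1, 12),
                    rep(c("A", "B"), each = 6))$fit
  sf <- summary(fit)
  grp_a <- sf$strata == levels(sf$strata)[1]
  surv_a <- sf$surv[grp_a]
  # empirical: fraction of the 6 subjects still alive after each time
  emp <- vapply(sf$time[grp_a], function(t) mean(time > t), 0)
  expect_equal(surv_a, emp)
})
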