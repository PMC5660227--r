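test_that("LOOCV is perfect on a cleanly separated 1-D feature", {
  set.seed(1)
  m <- peak_matrix(matrix(c(abs(rnorm(10, 0, 0.05)),
                            rnorm(10, 10, 0.05)), ncol = 1),
                   cluster_mz = 2084, samples = sprintf("s%d", 1:20),
                   groups = c(rep("HC", 10), rep("CRC", 10)))
  cs <- loocv_evaluate(m, 1)
  expect_equal(cs$sensitivity, 1)
  expect_equal(cs$specificity, 1)
  expect_equal(cs$youden, 1)
  expect_equal(cs$tp + cs$fn, 10)
  expect_equal(cs$tn + cs$fp, 10)
})

test_that("LOOCV Youden is near zero under permuted labels", {
  # n = 48 keeps the well-known small-sample pessimism of LOOCV (the
  # held-out class is always the slight minority) inside the band
  set.seed(99)
  base <- matrix(abs(rnorm(48 * 2, 50, 10)), 48, 2)
  js <- vapply(1:50, function(i) {
    set.seed(1000 + i)
    g <- sample(c(rep("HC", 24), rep("CRC", 24)))
    m <- peak_matrix(base, c(1500, 2500), sprintf("s%d", 1:48), g)
    loocv_evaluate(m, 1:2)$youden
  }, 0)
  expect_lt(abs(mean(js)), 0.15)
})

test_that("LOOCV preconditions and degenerate features are handled", {
  m <- peak_matrix(matrix(1:6, ncol = 1), 1000, sprintf("s%d", 1:6),
                   c("HC", rep("CRC", 5)))
  expect_error(loocv_evaluate(m, 1), "at least 2")
  # a zero-variance feature is dropped per fold, not fatal
  set.seed(2)
  m2 <- peak_matrix(cbind(c(abs(rnorm(6, 0, 0.1)), rnorm(6, 9, 0.1)),
                          rep(5, 12)),
                    c(1000, 2000), sprintf("s%d", 1:12),
                    c(rep("HC", 6), rep("CRC", 6)))
  cs <- loocv_evaluate(m2, 1:2)
  expect_equal(attr(cs, "n_folds_with_dropped"), 12L)
  expect_equal(cs$youden, 1)
})

test_that("GA finds the planted discriminator among noise features", {
  set.seed(7)
  n <- 20
  X <- cbind(matrix(abs(rnorm(n * 7, 50, 10)), n, 7),
             c(abs(rnorm(n / 2, 0, 0.3)), rnorm(n / 2, 10, 0.3)))
  m <- peak_matrix(X, 1000 + 100 * (1:8), sprintf("s%d", 1:n),
                   c(rep("HC", n / 2), rep("CRC", n / 2)))
  cand <- data.frame(cluster_mz = m$cluster_mz,
                     p_value = c(rep(0.5, 7), 1e-8))
  oracle <- exhaustive_select(m, cand)
  expect_equal(oracle$youden, 1)
  expect_true(1800 %in% oracle$member_mz)
  ga <- ga_select(m, cand,
                  ga_config(population_size = 20, n_generations = 30,
                            random_seed = 42))
  expect_equal(ga$youden, 1)
  expect_true(1800 %in% ga$member_mz)
  expect_false(ga$low_quality)
})

test_that("duplicated perfect features collapse to a single member", {
  set.seed(8)
  f <- c(abs(rnorm(10, 0, 0.2)), rnorm(10, 10, 0.2))
  m <- peak_matrix(cbind(f, f), c(1000, 2000), sprintf("s%d", 1:20),
                   c(rep("HC", 10), rep("CRC", 10)))
  cand <- data.frame(cluster_mz = c(1000, 2000), p_value = c(1e-8, 1e-8))
  ga <- ga_select(m, cand, ga_config(population_size = 8,
                                     n_generations = 10,
                                     random_seed = 3))
  expect_equal(ga$youden, 1)
  expect_length(ga$member_mz, 1L)
})

test_that("panels below the Youden floor are flagged as low quality", {
  set.seed(14)
  m <- peak_matrix(matrix(abs(rnorm(40 * 3, 50, 10)), 40, 3),
                   c(1000, 2000, 3000), sprintf("s%d", 1:40),
                   sample(rep(c("HC", "CRC"), 20)))
  cand <- data.frame(cluster_mz = m$cluster_mz, p_value = rep(0.5, 3))
  cfg <- ga_config(population_size = 6, n_generations = 5,
                   random_seed = 5)
  ga <- ga_select(m, cand, cfg)
  expect_true(ga$low_quality)    # pure noise cannot reach J = 0.5
  expect_lt(ga$youden, cfg$min_youden_flag)
  # the flag follows the configured floor, not a fixed constant
  lenient <- ga_config(population_size = 6, n_generations = 5,
                       random_seed = 5, min_youden_flag = -1)
  expect_false(ga_select(m, cand, lenient)$low_quality)
})

test_that("GA best-fitness trajectory is non-decreasing and seeded runs repeat", {
  set.seed(15)
  m <- toy_matrix(n_hc = 8, n_crc = 8, n_clusters = 6,
                  informative = c(1, 4), shift = 3, seed = 15)
  cand <- data.frame(cluster_mz = m$cluster_mz, p_value = runif(6))
  cfg <- ga_config(population_size = 10, n_generations = 12,
                   random_seed = 77)
  ga1 <- ga_select(m, cand, cfg)
  expect_true(all(diff(ga1$trajectory) >= 0))
  ga2 <- ga_select(m, cand, cfg)
  expect_identical(ga1$member_mz, ga2$member_mz)
  expect_identical(ga1$trajectory, ga2$trajectory)
})

test_that("final fit is deterministic and blind evaluation matches members by m/z", {
  set.seed(16)
  n <- 24
  X <- cbind(c(abs(rnorm(n / 2, 1, 0.2)), rnorm(n / 2, 8, 0.2)),
             abs(rnorm(n, 50, 10)))
  m <- peak_matrix(X, c(2084, 3000), sprintf("s%d", 1:n),
                   c(rep("HC", n / 2), rep("CRC", n / 2)))
  cand <- data.frame(cluster_mz = 2084, p_value = 1e-9)
  panel <- exhaustive_select(m, cand)
  mod1 <- fit_final(m, panel)
  mod2 <- fit_final(m, panel)
  expect_identical(mod1$config_hash, mod2$config_hash)
  # test matrix with the member cluster at slightly shifted m/z
  set.seed(17)
  Xt <- cbind(c(abs(rnorm(5, 1, 0.2)), rnorm(5, 8, 0.2)))
  mt <- peak_matrix(Xt, 2084 + 2, sprintf("t%d", 1:10),
                    c(rep("HC", 5), rep("CRC", 5)))
  cs <- blind_test(mod1, mt)
  expect_equal(cs$sensitivity, 1)
  expect_equal(cs$specificity, 1)
  # unmatched member -> error naming the mass
  mt_bad <- peak_matrix(Xt, 5000, sprintf("t%d", 1:10),
                        c(rep("HC", 5), rep("CRC", 5)))
  expect_error(blind_test(mod1, mt_bad), "2084")
  no_member <- peak_matrix(matrix(1:4, 2, 2), c(100, 200),
                           c("a", "b"), c("HC", "CRC"))
  expect_error(fit_final(no_member, panel), "members")
})

test_that("confusion metrics reproduce prediction-table percentages", {
  tr <- confusion_metrics(tp = 88, fn = 1, tn = 62, fp = 1)
  expect_equal(tr$sensitivity_pct, 98.9)
  expect_equal(tr$specificity_pct, 98.4)
  bl <- confusion_metrics(tp = 36, fn = 2, tn = 24, fp = 2)
  expect_equal(bl$sensitivity_pct, 94.7)
  expect_equal(bl$specificity_pct, 92.3)
  part <- confusion_metrics(tp = 0, fn = 0, tn = 5, fp = 0)
  expect_true(is.na(part$sensitivity_pct))
  expect_equal(part$specificity_pct, 100.0)
})
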