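test_that("pooled t-test matches its closed form and the reference", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res["t"]), -3.674235, tolerance = 1e-6)
  expect_equal(unname(res["p"]), 0.021312, tolerance = 1e-4)
  expect_equal(unname(two_sample_t(c(1, 2, 3), c(1, 2, 3))["t"]), 0)
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), sd = 2)
    ref <- t.test(x, y, var.equal = TRUE)
    got <- two_sample_t(x, y)
    expect_equal(unname(got["t"]), unname(ref$statistic), tolerance = 1e-10)
    expect_equal(unname(got["p"]), ref$p.value, tolerance = 1e-10)
  }
})

test_that("row-wise t handles masks and degenerate rows in place", {
  set.seed(12)
  mat <- matrix(rnorm(10 * 8), 10, 8)
  mat[1, 1:2] <- NA
  mat[2, ] <- 5                       # zero variance, equal means
  ts <- row_t_stats(mat, 1:4, 5:8)
  ref <- two_sample_t(mat[1, 1:4], mat[1, 5:8])
  expect_equal(ts$t[1], unname(ref["t"]), tolerance = 1e-12)
  expect_equal(ts$t[2], 0)
  expect_equal(ts$p[2], 1)
  expect_true(ts$flagged[2])
})

test_that("BH adjustment matches the step-up oracle and is order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    expect_equal(bh_fdr(p), naive_bh(p), tolerance = 1e-12)
    o <- sample(length(p))
    expect_equal(bh_fdr(p[o]), bh_fdr(p)[o])
  }
})

test_that("3v3 permutation p is exhaustive and hits its floor of 0.1", {
  mat <- rbind(c(1, 2, 3, 7, 8, 9),       # well separated
               c(5, 5.1, 4.9, 5, 5.05, 4.95))
  labs <- rep(c("a", "b"), each = 3)
  p <- univariate_permutation_p(mat, labs, B = 1000, seed = 1)
  expect_equal(p[1], 0.1)                 # 2 of 20 assignments
  expect_equal(p[1], naive_exhaustive_perm_p(mat[1, ], labs))
  expect_equal(p[2], naive_exhaustive_perm_p(mat[2, ], labs))
  # near-zero statistic: almost every relabelling is as extreme
  expect_gt(p[2], 0.8)
})

test_that("Monte-Carlo permutation p is seeded and floor-bounded", {
  set.seed(14)
  mat <- matrix(rnorm(5 * 16), 5, 16)
  labs <- rep(c("a", "b"), each = 8)
  p1 <- univariate_permutation_p(mat, labs, B = 60, seed = 7)
  p2 <- univariate_permutation_p(mat, labs, B = 60, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 1 / 61))
})

test_that("global permutation test detects planted signal, honours B=1", {
  sim <- random_two_group_matrix(200, 8, effect = 3, n_effect = 40,
                                 sd = 0.5, seed = 15)
  res <- global_permutation_test(sim$mat, sim$labels, alpha = 0.001,
                                 B = 99, seed = 2)
  expect_equal(res$p, 0)
  expect_gte(res$n_significant, 30)
  res1 <- global_permutation_test(sim$mat, sim$labels, B = 1, seed = 2)
  expect_true(res1$p %in% c(0, 1))
})

test_that("one-way F equals t^2 for two classes and matches lm/anova", {
  set.seed(16)
  mat <- matrix(rnorm(6 * 10), 6, 10)
  labs2 <- rep(c("a", "b"), each = 5)
  ft <- multiclass_f_test(mat, labs2)
  tt <- row_t_stats(mat, 1:5, 6:10)
  expect_equal(ft$F, tt$t^2, tolerance = 1e-10)
  labs4 <- rep(c("a", "b", "c", "d"), len = 10)
  mat[2, 3] <- NA
  ft4 <- multiclass_f_test(mat, labs4)
  for (g in 1:6) {
    keep <- !is.na(mat[g, ])
    ref <- anova(lm(mat[g, keep] ~ factor(labs4[keep])))
    expect_equal(ft4$F[g], ref$`F value`[1], tolerance = 1e-10)
    expect_equal(ft4$p[g], ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("multivariate selection respects threshold monotonicity", {
  sim <- random_two_group_matrix(300, 10, effect = 2, n_effect = 25,
                                 sd = 0.5, seed = 17)
  sel <- multivariate_permutation_select(sim$mat, sim$labels, B = 100,
                                         seed = 3)
  expect_gt(length(sel$selected_assays), 0)
  inside <- sel$observed_p[sel$selected_assays]
  outside <- sel$observed_p[setdiff(which(!is.na(sel$observed_p)),
                                    sel$selected_assays)]
  expect_true(all(inside <= sel$p_cutoff))
  expect_true(all(outside >= sel$p_cutoff))
  # degenerate confidence: expected-count mode still runs
  sel0 <- multivariate_permutation_select(sim$mat, sim$labels,
                                          confidence = 0, B = 50, seed = 3)
  expect_true(length(sel0$selected_assays) >= length(sel$selected_assays))
})

test_that("compare_classes is calibrated on a null contrast and ordered", {
  d <- generate_dataset(synthetic_config(seed = 18))   # no effects
  norm <- compute_delta_ct(d$ct)
  cmp <- compare_classes(norm, d$annotations, c("Mel 60", "Mel 30"),
                         mode = "II", stat = "t")
  expect_s3_class(cmp, "comparison_result")
  expect_equal(nrow(cmp), 666)
  frac <- mean(cmp$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
  expect_false(is.unsorted(cmp$p, na.rm = TRUE))
})

test_that("mode I reports calibrated fold changes for planted effects", {
  d <- generate_dataset(study_like_preset(seed = 19))
  norm <- compute_delta_ct(d$ct)
  cmp <- compare_classes(norm, d$annotations, c("Mel 60", "Mel 30"),
                         mode = "I")
  expect_true(all(c("fc", "log2_fc", "fc_bin", "t", "p", "fdr_bh") %in%
                    names(cmp)))
  expect_true(all(cmp$fdr_bh >= cmp$p, na.rm = TRUE))
  top <- d$truth$assay_id[which.max(abs(d$truth$log2fc))]
  est <- cmp$log2_fc[match(top, cmp$assay_id)]
  truth <- d$truth$log2fc[match(top, d$truth$assay_id)]
  expect_lt(abs(est - truth), 1)
  expect_lt(match(top, cmp$assay_id), 5)   # strongest effect ranks on top
})

test_that("four-class node-status contrast runs the F-test path", {
  d <- generate_dataset(study_like_preset(seed = 20))
  norm <- compute_delta_ct(d$ct)
  ann <- d$annotations
  mel <- ann[ann$group %in% c("Mel 60", "Mel 30") & !is.na(ann$node_positive), ]
  cls <- split(mel$sample_id,
               paste(mel$group, ifelse(mel$node_positive, "N+", "N-")))
  cmp <- compare_classes(norm, ann, cls, mode = "II")
  expect_true("F" %in% names(cmp))
  expect_equal(sum(grepl("^geomean_", names(cmp))), 4)
  expect_true(all(cmp$p >= 0 & cmp$p <= 1, na.rm = TRUE))
})
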