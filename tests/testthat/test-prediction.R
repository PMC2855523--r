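sep_data <- function(n_per = 8, G = 60, delta = 4, sd = 0.5, seed = 31) {
  set.seed(seed)
  mat <- matrix(rnorm(G * 2 * n_per, sd = sd), G)
  mat[1:3, seq_len(n_per)] <- mat[1:3, seq_len(n_per)] + delta
  rownames(mat) <- paste0("a", seq_len(G))
  list(mat = mat, labels = rep(c("Mel 60", "Mel 30"), each = n_per))
}

test_that("feature selection finds planted markers and stays empty on null", {
  d <- sep_data()
  sel <- select_features(d$mat, d$labels, alpha = 0.001)
  expect_true(all(1:3 %in% sel))
  set.seed(32)
  nullmat <- matrix(rnorm(666 * 16), 666)
  sel0 <- select_features(nullmat, rep(c("x", "y"), each = 8),
                          alpha = 0.001, stat = "t")
  expect_lt(length(sel0), 10)        # expectation ~0.67 assays
})

test_that("classifier definitions behave as specified on simple geometry", {
  x <- matrix(c(0, 0.2, -0.1, 4, 4.2, 3.9), 1)
  y <- rep(c("lo", "hi"), each = 3)
  ccp <- train_classifier(classifier_spec("compound_covariate"), x, y)
  expect_equal(as.character(predict(ccp, x)), y)   # zero training error
  # threshold midway between class mean scores
  scores <- drop(crossprod(x, ccp$weights))
  expect_equal(ccp$threshold, (mean(scores[1:3]) + mean(scores[4:6])) / 2)
  knn <- train_classifier(classifier_spec("knn1"), x, y)
  expect_equal(as.character(predict(knn, x[, 2, drop = FALSE])), "lo")
  # DLDA on one feature reduces to nearest centroid
  set.seed(33)
  xr <- matrix(rnorm(12), 1)
  yr <- rep(c("A", "B"), each = 6)
  dl <- train_classifier(classifier_spec("dlda"), xr, yr)
  nc <- train_classifier(classifier_spec("nearest_centroid"), xr, yr)
  new <- matrix(rnorm(20), 1)
  expect_identical(predict(dl, new), predict(nc, new))
})

test_that("all classifier methods separate well-separated classes", {
  d <- sep_data()
  for (m in c("compound_covariate", "dlda", "knn1", "knn3",
              "nearest_centroid", "svm_linear", "bayesian_cc")) {
    rep_m <- loocv(d$mat, d$labels, classifier_spec(m))
    expect_equal(rep_m$error_rate, 0, info = m)
    expect_equal(unname(rep_m$class_rates), matrix(1, 2, 4), info = m)
  }
})

test_that("LOOCV rates recompute from stored predictions and swap on relabel", {
  d <- sep_data(seed = 34, delta = 1.5)
  rep1 <- loocv(d$mat, d$labels, classifier_spec("dlda"))
  pred <- rep1$predictions; truth <- rep1$labels
  for (cl in levels(truth)) {
    tp <- sum(pred == cl & truth == cl); fn <- sum(pred != cl & truth == cl)
    expect_equal(rep1$class_rates[cl, "sensitivity"], tp / (tp + fn))
  }
  expect_equal(rep1$error_rate, mean(pred != truth))
  swapped <- ifelse(d$labels == "Mel 60", "Mel 30", "Mel 60")
  rep2 <- loocv(d$mat, swapped, classifier_spec("dlda"))
  expect_equal(rep2$class_rates["Mel 30", "sensitivity"],
               rep1$class_rates["Mel 60", "sensitivity"])
  expect_equal(rep2$class_rates["Mel 60", "specificity"],
               rep1$class_rates["Mel 30", "specificity"])
})

test_that("permuted labels give chance-level error", {
  d <- sep_data()
  set.seed(35)
  err <- loocv(d$mat, sample(d$labels),
               classifier_spec("dlda", selection_stat = "t",
                               selection_alpha = 0.5))$error_rate
  expect_gte(err, 0.25)
  expect_lte(err, 0.75)
})

test_that("in-fold selection never sees the left-out sample", {
  d <- sep_data(seed = 36, delta = 2)
  spec <- classifier_spec("compound_covariate", selection_stat = "t",
                          selection_alpha = 0.01)
  rep1 <- loocv(d$mat, d$labels, spec)
  n <- ncol(d$mat)
  for (i in c(1, 5, n)) {
    tr <- setdiff(seq_len(n), i)
    expect_identical(rep1$fold_features[[i]],
                     select_features(d$mat[, tr], d$labels[tr],
                                     alpha = 0.01, stat = "t"))
  }
})

test_that("a feature informative only through the left-out sample cannot help", {
  # each feature encodes the label of exactly one sample; honest nested
  # reselection must leave CV error at chance
  set.seed(37)
  n <- 16
  labels <- rep(c("g1", "g2"), each = n / 2)
  mat <- matrix(rnorm(n * n, 0, 1), n, n)
  for (i in seq_len(n))
    mat[i, i] <- if (labels[i] == "g1") 50 else -50
  rownames(mat) <- paste0("leak", seq_len(n))
  rep1 <- loocv(mat, labels, classifier_spec("dlda", selection_alpha = 0.1,
                                             selection_stat = "t"))
  expect_gte(rep1$error_rate, 0.25)
})

test_that("permutation significance is seeded and near-minimal when separable", {
  d <- sep_data(n_per = 6, G = 40)
  spec <- classifier_spec("compound_covariate", selection_stat = "t")
  res1 <- permutation_significance(d$mat, d$labels, spec,
                                   n_permutations = 20, seed = 5)
  res2 <- permutation_significance(d$mat, d$labels, spec,
                                   n_permutations = 20, seed = 5)
  expect_identical(res1$perm_errors, res2$perm_errors)
  expect_equal(res1$observed_error, 0)
  expect_lte(res1$p, 0.1)
})

test_that("empty in-fold selection degrades to a flagged majority model", {
  m <- train_classifier(classifier_spec("dlda"),
                        matrix(numeric(0), 0, 6),
                        c("a", "a", "a", "a", "b", "b"))
  expect_true(m$degenerate)
  expect_equal(as.character(predict(m, matrix(0, 0, 3))), rep("a", 3))
})
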