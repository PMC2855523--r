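# minimal hand-built card: 2 analyte assays + 4 MammU6 wells, one panel
mini_ct <- function(ct_vals, ctrl_vals, samples = c("S1", "S2"),
                    ctrl_mask = NULL) {
  wells <- data.frame(
    assay_id = c("m1-101", "m2-102", rep("MammU6-4395470", 4)),
    panel = "A", well = c(1L, 1L, 1:4))
  ct <- rbind(ct_vals, ctrl_vals)
  mask <- is.na(ct)
  if (!is.null(ctrl_mask)) mask[2 + seq_len(4), ] <- ctrl_mask
  ct[mask] <- NA
  colnames(ct) <- samples
  ct_matrix(ct, wells = wells, mask = mask, samples = samples)
}

test_that("control wells aggregate by per-card mean over unmasked wells", {
  x <- mini_ct(matrix(25, 2, 2), matrix(c(20.0, 20.2, 19.8, 20.0), 4, 2))
  expect_equal(unname(aggregate_endogenous_control(x)["A", ]), c(20, 20))

  x <- mini_ct(matrix(25, 2, 2), matrix(c(20, 21, NA, 22), 4, 2))
  expect_equal(unname(aggregate_endogenous_control(x)["A", ]), c(21, 21))

  x <- mini_ct(matrix(25, 2, 2), matrix(NA_real_, 4, 2))
  expect_error(aggregate_endogenous_control(x), "normalization error")
})

test_that("delta-Ct subtracts the card's control and propagates masks", {
  x <- mini_ct(matrix(c(25, 30, NA, 28), 2, 2),
               matrix(c(20, 20, 20, 20, 22, 22, 22, 22), 4, 2))
  norm <- compute_delta_ct(x)
  expect_equal(norm$assay_ids, c("m1-101", "m2-102"))
  expect_equal(unname(norm$delta_ct[1, 1]), 5)
  expect_equal(unname(norm$delta_ct[2, 1]), 10)
  expect_true(is.na(norm$delta_ct[1, 2]))
  expect_equal(unname(norm$delta_ct[2, 2]), 6)
})

test_that("delta-Ct is invariant to per-sample additive CT shifts", {
  d <- generate_dataset(synthetic_config(n_assays = 30,
                                         panel_split = c(A = 20, B = 10),
                                         groups = c("Mel 60" = 3,
                                                    "Nevus 30" = 2),
                                         censor_ct = Inf, seed = 9))
  norm0 <- compute_delta_ct(d$ct)
  shifted <- d$ct
  shift <- seq_len(length(shifted$samples)) * 1.7
  shifted$ct <- sweep(shifted$ct, 2, shift, "+")
  norm1 <- compute_delta_ct(shifted)
  expect_equal(norm1$delta_ct, norm0$delta_ct, tolerance = 1e-12)
})

test_that("relative quantification satisfies its closed forms", {
  x <- mini_ct(matrix(c(25, 27, 27, 26), 2, 2),
               matrix(20, 4, 2))
  norm <- compute_delta_ct(x)
  rq <- compute_rq(norm, "S2")
  # calibrator vs itself
  expect_equal(unname(rq$rq[, "S2"]), c(1, 1))
  # delta-Ct 5 vs calibrator 7 -> ddct -2, rq 4
  expect_equal(unname(rq$ddct[1, "S1"]), -2)
  expect_equal(unname(rq$rq[1, "S1"]), 4)
  expect_error(compute_rq(norm, "nope"), "unknown calibrator")
})

test_that("reciprocal calibrator products are exactly one", {
  d <- generate_dataset(synthetic_config(n_assays = 40,
                                         panel_split = c(A = 25, B = 15),
                                         groups = c("Mel 60" = 3,
                                                    "Nevus 30" = 2),
                                         censor_ct = Inf, seed = 2))
  norm <- compute_delta_ct(d$ct)
  s <- norm$samples
  ra <- compute_rq(norm, s[1])
  rb <- compute_rq(norm, s[3])
  expect_equal(ra$rq[, s[3]] * rb$rq[, s[1]],
               rep(1, length(norm$assay_ids)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("group fold change matches hand computation and reciprocity", {
  norm <- structure(list(
    assay_ids = "m1-101", panel = "A",
    delta_ct = matrix(c(1, 3, 3, 5), 1, 4,
                      dimnames = list(NULL, paste0("S", 1:4))),
    mask = matrix(FALSE, 1, 4), samples = paste0("S", 1:4), batch = NULL),
    class = "normalized_matrix")
  groups <- list(g1 = c("S1", "S2"), g2 = c("S3", "S4"))
  fc <- group_fold_change(norm, groups, "g1", "g2")
  expect_equal(fc$fc, 4)          # 2^-(2 - 4)
  expect_equal(fc$log2_fc, 2)
  rev <- group_fold_change(norm, groups, "g2", "g1")
  expect_equal(fc$fc * rev$fc, 1)
  same <- group_fold_change(norm, list(a = groups$g1, b = groups$g1),
                            "a", "b")
  expect_equal(same$fc, 1)
  expect_equal(same$log2_fc, 0)
})

test_that("fold-change bins are magnitude-symmetric with fixed edges", {
  expect_equal(fc_bin(34.6805), "FC > 4")
  expect_equal(fc_bin(0.2785), "FC 2.0-4.0")
  expect_equal(fc_bin(1.8143), "FC 1.6-2.0")
  expect_equal(fc_bin(1.4101), "FC 1.2-1.6")
  expect_true(is.na(fc_bin(1.0)))
  expect_error(fc_bin(-2), "positive")
  set.seed(5)
  fcs <- 2^runif(200, -6, 6)
  expect_identical(fc_bin(fcs), fc_bin(1 / fcs))
})

test_that("intensity geometric-mean ratios reproduce group fold changes", {
  set.seed(8)
  dct <- matrix(rnorm(50 * 8, 5, 2), 50, 8,
                dimnames = list(NULL, paste0("S", 1:8)))
  norm <- structure(list(assay_ids = paste0("a", 1:50), panel = "A",
                         delta_ct = dct, mask = dct * 0 > 1,
                         samples = paste0("S", 1:8), batch = NULL),
                    class = "normalized_matrix")
  expect_equal(unname(intensity_transform(norm)[3, 1]),
               unname(2^(-dct[3, 1])))
  ints <- intensity_transform(norm)
  groups <- list(c1 = paste0("S", 1:4), c2 = paste0("S", 5:8))
  geo <- function(v) exp(mean(log(v)))
  ratio <- apply(ints, 1, function(r) geo(r[1:4]) / geo(r[5:8]))
  fc <- group_fold_change(norm, groups, "c1", "c2")
  expect_equal(unname(ratio), fc$fc, tolerance = 1e-12)
})
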