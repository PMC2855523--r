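test_that("study-like preset mirrors the profiled design", {
  cfg <- study_like_preset()
  expect_equal(unname(cfg$groups),
               c(10, 10, 3, 3))
  expect_equal(names(cfg$groups),
               c("Mel 60", "Mel 30", "Nevus 60", "Nevus 30"))
  expect_equal(cfg$n_assays, 666)
  expect_equal(unname(cfg$panel_split), c(377, 289))
  expect_equal(cfg$n_batches, 3)
  expect_equal(nrow(cfg$effects), 30)
  expect_setequal(unique(fc_bin(2^abs(cfg$effects$log2fc))),
                  c("FC > 4", "FC 2.0-4.0", "FC 1.6-2.0", "FC 1.2-1.6"))
})

test_that("generated annotations carry one global calibrator and batches", {
  d <- generate_dataset(study_like_preset(seed = 41))
  ann <- d$annotations
  expect_equal(sum(ann$is_calibrator), 1L)
  expect_equal(ann$group[ann$is_calibrator], "Nevus 30")
  expect_equal(sort(unique(ann$batch)), 1:3)
  cfgb <- study_like_preset(seed = 41)
  cfgb$batch_calibration <- TRUE
  db <- generate_dataset(cfgb)
  expect_equal(as.vector(table(db$annotations$batch[
    db$annotations$is_calibrator])), rep(1L, 3))
})

test_that("degenerate config gives flat relative quantification", {
  cfg <- synthetic_config(n_assays = 50, panel_split = c(A = 30, B = 20),
                          noise_sd = 0, control_ct_sd = 0, seed = 42)
  d <- generate_dataset(cfg)
  norm <- compute_delta_ct(d$ct)
  rq <- compute_rq(norm, d$annotations$sample_id[d$annotations$is_calibrator])
  expect_equal(max(abs(rq$ddct), na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(range(rq$rq, na.rm = TRUE), c(1, 1), tolerance = 1e-12)
})

test_that("the same seed reproduces the dataset exactly", {
  d1 <- generate_dataset(study_like_preset(seed = 43))
  d2 <- generate_dataset(study_like_preset(seed = 43))
  expect_identical(d1$ct$ct, d2$ct$ct)
  expect_identical(d1$ct$mask, d2$ct$mask)
  expect_identical(d1$annotations, d2$annotations)
  expect_identical(d1$truth, d2$truth)
})

test_that("a planted 4-fold effect is recovered within its noise band", {
  ids <- synthetic_assay_ids(synthetic_config())
  eff <- data.frame(assay_id = ids[100], group = "Mel 60", log2fc = 2)
  hits <- vapply(1:5, function(s) {
    d <- generate_dataset(synthetic_config(effects = eff, seed = 400 + s))
    norm <- compute_delta_ct(d$ct)
    gfc <- group_fold_change(norm,
                             split(d$annotations$sample_id,
                                   d$annotations$group),
                             "Mel 60", "Mel 30")
    gfc$fc[match(ids[100], gfc$assay_id)]
  }, numeric(1))
  expect_true(all(hits >= 3.0 & hits <= 5.3))
})

test_that("estimated fold changes are invariant to per-sample shifts", {
  ids <- synthetic_assay_ids(synthetic_config())
  eff <- data.frame(assay_id = ids[c(5, 50)], group = "Mel 60",
                    log2fc = c(1, -1))
  run <- function(shift_sd) {
    d <- generate_dataset(synthetic_config(effects = eff,
                                           sample_shift_sd = shift_sd,
                                           censor_ct = Inf, seed = 44))
    norm <- compute_delta_ct(d$ct)
    group_fold_change(norm,
                      split(d$annotations$sample_id, d$annotations$group),
                      "Mel 60", "Mel 30")$fc
  }
  expect_equal(run(0), run(2), tolerance = 1e-12)
})

test_that("censoring masks high-CT wells after noise", {
  cfg <- synthetic_config(baseline_ct_range = c(36, 40), censor_ct = 38,
                          seed = 45)
  d <- generate_dataset(cfg)
  expect_gt(sum(d$ct$mask), 0)
  expect_true(all(d$ct$ct[!d$ct$mask] <= 38))
  # negative-control wells sit near the ceiling and are mostly censored
  neg <- d$ct$wells$assay_id == "ath-miR159a-4373390"
  expect_gt(mean(d$ct$mask[neg, ]), 0.5)
})
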