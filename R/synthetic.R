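#' Configuration for the synthetic CT data generator
#'
#' Fully parameterises a simulated two-panel TLDA experiment. Defaults
#' emulate the melanoma profiling design: 666 assays split 377/289 across
#' panels A and B, four MammU6 control replicate wells per card, one
#' negative-control well per card, 26 samples in four groups
#' (Mel 60/Mel 30: 10 each, Nevus 60/Nevus 30: 3 each), three processing
#' batches, and censoring of high CT values as undetermined.
#'
#' The CT model is
#' `CT[a, s] = baseline_a + sample_shift_s + batch_shift_b(s)
#'  - effect(a, group(s)) + noise`,
#' with control wells sharing the sample and batch shifts so that the
#' delta-Ct transform removes them exactly. Effects are planted on the
#' delta-Ct scale as `-log2FC` (one CT cycle = one doubling), matching the
#' `2^-ddCt` quantification model. Censoring is applied after noise so
#' that masking correlates with low expression, as on real cards.
#'
#' @param n_assays total analyte assays (default 666).
#' @param panel_split named integer vector, assays per panel (default
#'   `c(A = 377, B = 289)`).
#' @param n_control_replicates endogenous-control wells per card
#'   (default 4).
#' @param groups named integer vector of samples per group.
#' @param n_batches processing batches (default 3).
#' @param baseline_ct_range per-assay mean CT drawn uniformly from this
#'   range (cycles, default 22-34).
#' @param control_ct_mean,control_ct_sd endogenous-control well CT mean
#'   (20) and replicate sd (0.15 cycles).
#' @param noise_sd technical CT noise sd for analyte wells (0.5 cycles).
#' @param sample_shift_sd sd of the per-sample global CT offset (1.0
#'   cycles; removed by normalization).
#' @param batch_shift_sd sd of the per-batch CT offset (0.3 cycles).
#' @param effects data.frame with columns `assay_id`, `group`, `log2fc`:
#'   planted group expression effects (positive `log2fc` = higher
#'   expression, i.e. lower CT, in that group). `NULL` for a global null.
#' @param censor_ct CT ceiling above which a well becomes undetermined
#'   (default 38).
#' @param batch_calibration mark one calibrator per batch instead of a
#'   single global calibrator (default FALSE; the global calibrator is the
#'   first `Nevus 30` sample, "PN1"-style).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_assays = 666,
                             panel_split = c(A = 377, B = 289),
                             n_control_replicates = 4,
                             groups = c("Mel 60" = 10, "Mel 30" = 10,
                                        "Nevus 60" = 3, "Nevus 30" = 3),
                             n_batches = 3,
                             baseline_ct_range = c(22, 34),
                             control_ct_mean = 20, control_ct_sd = 0.15,
                             noise_sd = 0.5, sample_shift_sd = 1.0,
                             batch_shift_sd = 0.3, effects = NULL,
                             censor_ct = 38, batch_calibration = FALSE,
                             seed = 1) {
  if (sum(panel_split) != n_assays)
    stop("panel_split must sum to n_assays")
  if (any(groups < 1)) stop("group counts must be >= 1")
  sds <- c(control_ct_sd, noise_sd, sample_shift_sd, batch_shift_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  cfg <- list(n_assays = n_assays, panel_split = panel_split,
              n_control_replicates = n_control_replicates, groups = groups,
              n_batches = n_batches, baseline_ct_range = baseline_ct_range,
              control_ct_mean = control_ct_mean,
              control_ct_sd = control_ct_sd, noise_sd = noise_sd,
              sample_shift_sd = sample_shift_sd,
              batch_shift_sd = batch_shift_sd, effects = effects,
              censor_ct = censor_ct, batch_calibration = batch_calibration,
              seed = as.integer(seed))
  if (!is.null(effects)) {
    need <- c("assay_id", "group", "log2fc")
    if (!all(need %in% names(effects)))
      stop("effects must have columns assay_id, group, log2fc")
    bad <- setdiff(effects$assay_id, synthetic_assay_ids(cfg))
    if (length(bad))
      stop("planted assay(s) not in the assay universe: ",
           paste(utils::head(bad, 3), collapse = ", "))
    if (!all(effects$group %in% names(groups)))
      stop("planted effect group(s) not in the design")
  }
  structure(cfg, class = "synthetic_config")
}

#' Assay identifiers of a synthetic configuration
#'
#' Deterministic analyte assay names in the TLDA style
#' (`syn-miR-<n>-<assayID>`), panel A first.
#'
#' @param config a `synthetic_config`.
#' @return character vector of `n_assays` identifiers.
#' @export
synthetic_assay_ids <- function(config) {
  sprintf("syn-miR-%03d-%d", seq_len(config$n_assays),
          4000000L + seq_len(config$n_assays))
}

# internal: deterministic sample names and group labels
.synthetic_samples <- function(groups) {
  prefix <- c("Mel 60" = "AM", "Mel 30" = "PM",
              "Nevus 60" = "AN", "Nevus 30" = "PN")
  ids <- unlist(lapply(names(groups), function(g)
    paste0(prefix[[g]], seq_len(groups[[g]]))), use.names = FALSE)
  data.frame(sample_id = ids,
             group = rep(names(groups), groups),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic TLDA CT dataset
#'
#' Draws a complete CT export (analyte wells, replicated MammU6 control
#' wells and a negative-control well per card), sample annotations and the
#' planted-effect truth table from a [synthetic_config()]. The same seed
#' reproduces the dataset exactly.
#'
#' @param config a `synthetic_config`.
#' @return list with elements `ct` (a [ct_matrix()]), `annotations` (a
#'   `sample_annotation` data.frame), `truth` (data.frame of planted
#'   effects: `assay_id`, `group`, `log2fc`) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  smp <- .synthetic_samples(config$groups)
  ns <- nrow(smp)
  na <- config$n_assays
  assay_ids <- synthetic_assay_ids(config)
  panel <- rep(names(config$panel_split), config$panel_split)
  batch <- rep_len(seq_len(config$n_batches), ns)

  # fixed draw order, standard normals scaled afterwards: the RNG stream
  # stays aligned when an sd parameter changes (including sd = 0)
  baseline <- stats::runif(na, config$baseline_ct_range[1],
                           config$baseline_ct_range[2])
  sample_shift <- stats::rnorm(ns) * config$sample_shift_sd
  batch_shift <- stats::rnorm(config$n_batches) * config$batch_shift_sd
  noise <- matrix(stats::rnorm(na * ns) * config$noise_sd, na, ns)
  nrep <- config$n_control_replicates
  ctrl_noise <- matrix(stats::rnorm(2 * nrep * ns) * config$control_ct_sd,
                       2 * nrep, ns)
  neg_noise <- matrix(stats::rnorm(2 * ns) * 0.5, 2, ns)

  offset <- sample_shift + batch_shift[batch]          # per sample
  effect_ct <- matrix(0, na, ns)
  if (!is.null(config$effects)) {
    for (r in seq_len(nrow(config$effects))) {
      a <- match(config$effects$assay_id[r], assay_ids)
      cols <- which(smp$group == config$effects$group[r])
      effect_ct[a, cols] <- effect_ct[a, cols] + config$effects$log2fc[r]
    }
  }
  ct_analyte <- baseline + noise - effect_ct
  ct_analyte <- sweep(ct_analyte, 2, offset, "+")
  ct_ctrl <- config$control_ct_mean + ctrl_noise
  ct_ctrl <- sweep(ct_ctrl, 2, offset, "+")
  ct_neg <- 39 + neg_noise
  ct_neg <- sweep(ct_neg, 2, offset, "+")

  wells <- rbind(
    data.frame(assay_id = assay_ids, panel = panel, well = 1L,
               stringsAsFactors = FALSE),
    data.frame(assay_id = "MammU6-4395470",
               panel = rep(c("A", "B"), each = nrep),
               well = rep(seq_len(nrep), 2), stringsAsFactors = FALSE),
    data.frame(assay_id = "ath-miR159a-4373390", panel = c("A", "B"),
               well = 1L, stringsAsFactors = FALSE))
  ct <- rbind(ct_analyte, ct_ctrl, ct_neg)
  mask <- ct > config$censor_ct
  ct[mask] <- NA
  colnames(ct) <- smp$sample_id
  ctm <- ct_matrix(ct, wells = wells, mask = mask,
                   samples = smp$sample_id, batch = batch)

  ann <- .synthetic_annotations(smp, batch, config$batch_calibration)
  truth <- if (is.null(config$effects))
    data.frame(assay_id = character(0), group = character(0),
               log2fc = numeric(0), stringsAsFactors = FALSE)
  else as.data.frame(config$effects, stringsAsFactors = FALSE)
  list(ct = ctm, annotations = ann, truth = truth, config = config)
}

# internal: deterministic study-like annotations
.synthetic_annotations <- function(smp, batch, batch_calibration) {
  ages <- list(
    "Mel 60" = c(64, 69, 69, 72, 73, 78, 79, 79, 82, 86),
    "Mel 30" = c(21, 26, 26, 28, 28, 28, 29, 29, 29, 29),
    "Nevus 60" = c(62, 63, 68), "Nevus 30" = c(12, 14, 26))
  nst <- list(
    "Mel 60" = c("pN0", "pN3", "pN0", "cN0", "pN3", "pN2c", "cN0", "cN0",
                 "pN0", "cN0"),
    "Mel 30" = c("pN0", "pN1a", "pN0", "pN0", "n/a", "pN0", "pN0", "cN0",
                 "pN3", "cN0"),
    "Nevus 60" = c("n/a", "n/a", "n/a"), "Nevus 30" = c("n/a", "n/a", "n/a"))
  stg <- list(
    "Mel 60" = c("1B", "3C", "2A", "0", "3C", "3B", "1A", "1A", "2B", "1B"),
    "Mel 30" = c("Unknown", "3B", "2A", "1B", "n/a", "1A", "1A", "0", "4",
                 "1A"),
    "Nevus 60" = c("n/a", "n/a", "n/a"), "Nevus 30" = c("n/a", "n/a", "n/a"))
  pick <- function(tbl) unlist(lapply(unique(smp$group), function(g)
    rep_len(tbl[[g]], sum(smp$group == g))), use.names = FALSE)
  ann <- data.frame(sample_id = smp$sample_id, group = smp$group,
                    age = pick(ages), stage_group = pick(stg),
                    n_stage = pick(nst), batch = batch,
                    stringsAsFactors = FALSE)
  if (batch_calibration) {
    ann$is_calibrator <- !duplicated(batch)
  } else {
    cal <- which(ann$group == "Nevus 30")[1]
    if (is.na(cal)) cal <- 1L
    ann$is_calibrator <- seq_len(nrow(ann)) == cal
  }
  as_sample_annotation(ann)
}

#' Study-like synthetic preset
#'
#' A [synthetic_config()] mirroring the profiled study design: 26 samples
#' in four groups (10/10/3/3), 666 assays split 377/289 over two panels,
#' three batches, and 30 planted `Mel 60` expression effects spanning the
#' reported fold-change bins (|log2FC| from ~0.35 to ~5, both directions).
#'
#' @param seed integer seed stored in the config.
#' @return a `synthetic_config`.
#' @export
study_like_preset <- function(seed = 1) {
  cfg <- synthetic_config(seed = seed)
  ids <- synthetic_assay_ids(cfg)
  # 15 planted assays per panel, deterministic positions
  pos <- c(seq(11, 361, by = 25), 377 + seq(9, 289, by = 20))[1:30]
  l2 <- c(5.1, -2.4, 3.2, -2.8, 2.3, 4.1, -2.2, 2.6,      # |FC| > 4
          1.9, -1.4, 1.15, 1.8, -1.6, 1.25, 1.45, -1.1,   # FC 2-4
          0.95, -0.8, 0.85, 0.75, -0.9, 0.78, 0.88,       # FC 1.6-2
          0.5, -0.35, 0.6, 0.4, -0.55, 0.45, 0.62)        # FC 1.2-1.6
  cfg$effects <- data.frame(assay_id = ids[pos], group = "Mel 60",
                            log2fc = l2, stringsAsFactors = FALSE)
  cfg
}
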