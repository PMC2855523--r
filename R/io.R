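#' Read a CT export table into a `ct_matrix`
#'
#' Parses delimited CT exports as produced by real-time PCR instrument
#' software, in long form (one row per sample/assay/well) or wide form
#' (assays x samples). Cells equal to the undetermined token (or empty) are
#' masked; everything else must parse as a number.
#'
#' @param path path to a delimited text file.
#' @param format_options list of dialect settings; recognised keys (with
#'   defaults): `layout` (`"long"` or `"wide"`), `sep` (`"\t"`, or `","`
#'   when `path` ends in `.csv`), `sample_col` (`"Sample"`), `assay_col`
#'   (`"Assay"`), `panel_col` (`"Panel"`), `well_col` (`"Well"`),
#'   `ct_col` (`"CT"`), `batch_col` (`"Batch"`, optional),
#'   `undetermined` (`"Undetermined"`), `panel_map` (named character
#'   vector assay -> panel, for wide layouts without a panel column),
#'   `control_name` (`"MammU6"`), `negative_name` (`"ath-miR159a"`).
#' @return a [ct_matrix()].
#' @seealso [write_ct_table()] for the lossless inverse.
#' @export
read_ct_table <- function(path, format_options = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  fo <- .ct_dialect(path, format_options)
  tab <- utils::read.table(path, header = TRUE, sep = fo$sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (identical(fo$layout, "wide")) {
    return(.read_ct_wide(tab, fo))
  }
  need <- c(fo$sample_col, fo$assay_col, fo$ct_col)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("format error: cannot resolve column(s) ",
         paste(missing_cols, collapse = ", "))
  sample <- tab[[fo$sample_col]]
  assay <- tab[[fo$assay_col]]
  well <- if (fo$well_col %in% names(tab)) as.integer(tab[[fo$well_col]])
          else 1L
  panel <- if (fo$panel_col %in% names(tab)) tab[[fo$panel_col]]
           else .panel_lookup(assay, fo$panel_map)
  ct_raw <- tab[[fo$ct_col]]
  key <- paste(sample, assay, panel, well, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("integrity error: duplicate (sample, assay, well) row: ",
         gsub("\r", " / ", dup))
  }
  ct_num <- .parse_ct(ct_raw, fo$undetermined)

  samples <- unique(sample)
  wtab <- unique(data.frame(assay_id = assay, panel = panel, well = well,
                            stringsAsFactors = FALSE))
  # deterministic well order: panel, then first appearance
  wtab <- wtab[order(match(paste(wtab$assay_id, wtab$panel, wtab$well),
                           paste(assay, panel, well))), , drop = FALSE]
  rownames(wtab) <- NULL
  ridx <- match(paste(assay, panel, well, sep = "\r"),
                paste(wtab$assay_id, wtab$panel, wtab$well, sep = "\r"))
  cidx <- match(sample, samples)
  ct <- matrix(NA_real_, nrow(wtab), length(samples))
  mask <- matrix(TRUE, nrow(wtab), length(samples))
  ct[cbind(ridx, cidx)] <- ct_num
  mask[cbind(ridx, cidx)] <- is.na(ct_num)
  colnames(ct) <- samples
  batch <- NULL
  if (fo$batch_col %in% names(tab)) {
    batch <- tab[[fo$batch_col]][match(samples, sample)]
  }
  ct_matrix(ct, wells = wtab, mask = mask, samples = samples, batch = batch,
            control_name = fo$control_name, negative_name = fo$negative_name)
}

.ct_dialect <- function(path, format_options) {
  fo <- list(layout = "long", sep = NULL, sample_col = "Sample",
             assay_col = "Assay", panel_col = "Panel", well_col = "Well",
             ct_col = "CT", batch_col = "Batch",
             undetermined = "Undetermined", panel_map = NULL,
             control_name = "MammU6", negative_name = "ath-miR159a")
  fo[names(format_options)] <- format_options
  if (is.null(fo$sep))
    fo$sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fo
}

.parse_ct <- function(ct_raw, undetermined) {
  ct_raw <- trimws(ct_raw)
  und <- ct_raw == undetermined | ct_raw == "" | is.na(ct_raw)
  ct_num <- suppressWarnings(as.numeric(ct_raw))
  bad <- !und & is.na(ct_num)
  if (any(bad))
    stop("parse error: non-numeric CT value(s): ",
         paste(utils::head(unique(ct_raw[bad]), 3), collapse = ", "))
  ct_num[und] <- NA_real_
  ct_num
}

.panel_lookup <- function(assay, panel_map) {
  if (is.null(panel_map))
    stop("format error: no panel column and no panel_map supplied")
  p <- unname(panel_map[assay])
  if (anyNA(p))
    stop("format error: assay(s) missing from panel_map: ",
         paste(utils::head(unique(assay[is.na(p)]), 3), collapse = ", "))
  p
}

.read_ct_wide <- function(tab, fo) {
  assay_col <- fo$assay_col
  if (!assay_col %in% names(tab))
    stop("format error: cannot resolve column ", assay_col)
  assay <- tab[[assay_col]]
  panel <- if (fo$panel_col %in% names(tab)) tab[[fo$panel_col]]
           else .panel_lookup(assay, fo$panel_map)
  drop <- c(assay_col, intersect(fo$panel_col, names(tab)),
            intersect(fo$well_col, names(tab)))
  well <- if (fo$well_col %in% names(tab)) as.integer(tab[[fo$well_col]])
          else 1L
  samples <- setdiff(names(tab), drop)
  ct <- sapply(samples, function(s) .parse_ct(tab[[s]], fo$undetermined))
  ct <- matrix(ct, nrow = nrow(tab), dimnames = list(NULL, samples))
  wtab <- data.frame(assay_id = assay, panel = panel, well = well,
                     stringsAsFactors = FALSE)
  ct_matrix(ct, wells = wtab, mask = is.na(ct), samples = samples,
            control_name = fo$control_name, negative_name = fo$negative_name)
}

#' Write a `ct_matrix` as a long-form CT export
#'
#' Produces a tab-delimited long-form table (`Sample`, `Assay`, `Panel`,
#' `Well`, `CT`, plus `Batch` when present) that [read_ct_table()] parses
#' back losslessly, masks included: masked wells are written as
#' `Undetermined`.
#'
#' @param x a [ct_matrix()].
#' @param path output path.
#' @param undetermined token written for masked wells.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, undetermined = "Undetermined") {
  stopifnot(inherits(x, "ct_matrix"))
  ns <- length(x$samples)
  nw <- nrow(x$wells)
  long <- data.frame(
    Sample = rep(x$samples, each = nw),
    Assay = rep(x$wells$assay_id, ns),
    Panel = rep(x$wells$panel, ns),
    Well = rep(x$wells$well, ns),
    CT = ifelse(as.vector(x$mask), undetermined,
                sprintf("%.17g", as.vector(x$ct))),
    stringsAsFactors = FALSE)
  if (!is.null(x$batch))
    long$Batch <- rep(unname(x$batch), each = nw)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample-annotation table
#'
#' Expects a delimited table with at least `sample_id` and `group` columns;
#' optional columns are `age`, `stage_group`, `n_stage`, `batch` and
#' `is_calibrator`. Group labels are restricted to the study's closed set
#' `Mel 60`, `Mel 30`, `Nevus 60`, `Nevus 30`. Nodal status is derived from
#' `n_stage`: `pN1`/`pN2`/`pN3` (any sub-stage) is node positive, `pN0` or
#' `cN0` node negative, anything else unknown (`NA`).
#'
#' @param path path to a CSV/TSV file (separator inferred from extension).
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return data.frame of class `sample_annotation` with columns
#'   `sample_id`, `group`, `age`, `stage_group`, `n_stage`,
#'   `node_positive`, `batch`, `is_calibrator`.
#' @export
read_sample_annotations <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_sample_annotation(tab)
}

#' Validate a data.frame of sample annotations
#'
#' @param tab data.frame with at least `sample_id` and `group`.
#' @return the validated, completed `sample_annotation` data.frame (see
#'   [read_sample_annotations()]).
#' @export
as_sample_annotation <- function(tab) {
  need <- c("sample_id", "group")
  if (!all(need %in% names(tab)))
    stop("annotation table must have columns sample_id and group")
  groups_ok <- c("Mel 60", "Mel 30", "Nevus 60", "Nevus 30")
  bad <- setdiff(unique(tab$group), groups_ok)
  if (length(bad))
    stop("validation error: unknown group label(s): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("validation error: duplicate sample_id")
  for (col in c("age", "stage_group", "n_stage", "batch"))
    if (is.null(tab[[col]])) tab[[col]] <- NA
  if (is.null(tab$is_calibrator)) tab$is_calibrator <- FALSE
  tab$is_calibrator <- as.logical(tab$is_calibrator)
  tab$node_positive <- derive_node_positive(tab$n_stage)
  keep <- c("sample_id", "group", "age", "stage_group", "n_stage",
            "node_positive", "batch", "is_calibrator")
  out <- tab[, c(keep, setdiff(names(tab), keep)), drop = FALSE]
  class(out) <- c("sample_annotation", "data.frame")
  out
}

#' Derive nodal positivity from an AJCC N-stage string
#'
#' @param n_stage character vector (e.g. `"pN1a"`, `"cN0"`, `"n/a"`).
#' @return logical vector; `NA` where the status cannot be determined.
#' @export
#' @examples
#' derive_node_positive(c("pN1a", "cN0", "n/a"))
derive_node_positive <- function(n_stage) {
  n_stage <- trimws(as.character(n_stage))
  out <- rep(NA, length(n_stage))
  out[grepl("^[pc]?N[123]", n_stage)] <- TRUE
  out[grepl("^[pc]?N0", n_stage)] <- FALSE
  out
}

#' Write a result table in a fixed report layout
#'
#' Serialises comparison or cross-validation results as tab-delimited text
#' in one of the standard report layouts, with all floating point columns
#' written to at least 4 decimals.
#'
#' @param results a data.frame of comparison results (layouts `"fc"`,
#'   `"intensity"`) or a `cv_report` (layout `"cv"`).
#' @param path output path.
#' @param layout one of `"fc"` (miR, FC, Log2(FC), p value, FDR (BH),
#'   FC Bin), `"intensity"` (MiR, Parametric p-value, FDR, Permutation
#'   p-value, per-class geometric mean intensities, Fold-change) or `"cv"`
#'   (Class, Sensitivity, Specificity, PPV, NPV).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(results, path, layout = c("fc", "intensity",
                                                         "cv")) {
  layout <- match.arg(layout)
  fmt <- function(v, digits = 4) ifelse(is.na(v), "N/A",
                                        formatC(v, digits = digits,
                                                format = "f"))
  if (layout == "fc") {
    out <- data.frame(
      `miR` = results$assay_id,
      `FC` = fmt(results$fc),
      `Log2(FC)` = fmt(results$log2_fc),
      `p value` = fmt(results$p),
      `FDR (BH)` = fmt(results$fdr_bh),
      `FC Bin` = ifelse(is.na(results$fc_bin), "", results$fc_bin),
      check.names = FALSE, stringsAsFactors = FALSE)
  } else if (layout == "intensity") {
    gm <- results[, grep("^geomean_", names(results)), drop = FALSE]
    out <- data.frame(
      `MiR` = results$assay_id,
      `Parametric p-value` = fmt(results$p, 5),
      `FDR` = fmt(results$fdr_bh, 5),
      `Permutation p-value` = fmt(results$perm_p, 5),
      check.names = FALSE, stringsAsFactors = FALSE)
    for (i in seq_len(ncol(gm)))
      out[[paste("Geom mean of intensities in class", i)]] <- fmt(gm[[i]])
    if (!is.null(results$fc)) out[["Fold-change"]] <- fmt(results$fc)
  } else {
    stopifnot(inherits(results, "cv_report"))
    r <- results$class_rates
    out <- data.frame(
      Class = rownames(r),
      Sensitivity = fmt(r[, "sensitivity"], 3),
      Specificity = fmt(r[, "specificity"], 3),
      PPV = fmt(r[, "ppv"], 3),
      NPV = fmt(r[, "npv"], 3),
      stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
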