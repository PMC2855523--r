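#' Aggregate endogenous-control wells per sample and panel
#'
#' The endogenous control (MammU6) is spotted in four replicate wells on
#' each TLDA card. This returns the arithmetic mean CT of the unmasked
#' control replicate wells, computed per sample per panel (per card).
#'
#' @param x a [ct_matrix()].
#' @param control_name regular expression identifying the control assay;
#'   defaults to the pattern recorded when `x` was built (`"MammU6"`).
#' @return numeric matrix, panels x samples, of mean control CT values.
#' @export
aggregate_endogenous_control <- function(x, control_name = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  role <- .well_role(x)
  is_ctrl <- if (is.null(control_name)) role == "endogenous"
             else grepl(control_name, x$wells$assay_id)
  if (!any(is_ctrl))
    stop("normalization error: no endogenous-control wells found")
  panels <- sort(unique(x$wells$panel))
  out <- matrix(NA_real_, length(panels), length(x$samples),
                dimnames = list(panels, x$samples))
  for (p in panels) {
    rows <- which(is_ctrl & x$wells$panel == p)
    if (!length(rows)) next
    cts <- x$ct[rows, , drop = FALSE]
    cts[x$mask[rows, , drop = FALSE]] <- NA
    n_ok <- colSums(!is.na(cts))
    if (any(n_ok == 0))
      stop("normalization error: no unmasked ", "control well for sample(s) ",
           paste(x$samples[n_ok == 0], collapse = ", "), " on panel ", p)
    out[p, ] <- colMeans(cts, na.rm = TRUE)
  }
  out
}

#' Subtract the endogenous-control CT: the delta-Ct transform
#'
#' Computes `delta_ct[a, s] = CT[a, s] - CT_control[panel(a), s]` for every
#' non-control assay. This removes per-sample loading and efficiency
#' offsets: adding a constant to every CT of a sample (including its
#' control wells) leaves its delta-Ct unchanged. Control assays (endogenous
#' and negative) are excluded from the output; masks propagate.
#'
#' @param x a [ct_matrix()].
#' @param control_ct panels x samples matrix from
#'   [aggregate_endogenous_control()]; computed internally when `NULL`.
#' @return an object of class `normalized_matrix`: list with `assay_ids`,
#'   `panel` (per-assay), `delta_ct` (assays x samples, `NA` where masked),
#'   `mask`, `samples`, `batch`.
#' @export
compute_delta_ct <- function(x, control_ct = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  if (is.null(control_ct)) control_ct <- aggregate_endogenous_control(x)
  if (anyNA(control_ct))
    stop("normalization error: control CT undefined for some sample/panel")
  role <- .well_role(x)
  keep <- which(role == "none")
  if (!length(keep)) stop("no analyte assays present")
  w <- x$wells[keep, , drop = FALSE]
  ct <- x$ct[keep, , drop = FALSE]
  mask <- x$mask[keep, , drop = FALSE]
  ct[mask] <- NA
  dct <- ct - control_ct[w$panel, , drop = FALSE]
  # analyte assays have one well each; aggregate any replicates by mean
  if (anyDuplicated(paste(w$assay_id, w$panel))) {
    agg <- rowsum(ifelse(is.na(dct), 0, dct), w$assay_id, reorder = FALSE) /
      rowsum((!is.na(dct)) * 1, w$assay_id, reorder = FALSE)
    agg[is.nan(agg)] <- NA
    first <- !duplicated(w$assay_id)
    dct <- agg[unique(w$assay_id), , drop = FALSE]
    w <- w[first, , drop = FALSE]
  }
  rownames(dct) <- NULL
  structure(
    list(assay_ids = w$assay_id, panel = w$panel, delta_ct = dct,
         mask = is.na(dct), samples = x$samples, batch = x$batch),
    class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix (delta-Ct):", length(x$assay_ids), "assays x",
      length(x$samples), "samples;", sum(x$mask), "masked\n")
  invisible(x)
}

#' Relative quantification against a calibrator sample
#'
#' Computes `ddct[a, s] = delta_ct[a, s] - delta_ct[a, calibrator]` and the
#' relative quantity `rq = 2^-ddct` (the standard comparative-CT fold
#' change). The calibrator sample's RQ is exactly 1 for every assay whose
#' calibrator delta-Ct is unmasked; assays masked in the calibrator are
#' masked for all samples.
#'
#' @param norm a `normalized_matrix` from [compute_delta_ct()].
#' @param calibrator_id sample identifier of the calibrator.
#' @return object of class `relative_quantification`: list with
#'   `assay_ids`, `panel`, `ddct`, `rq`, `mask`, `samples`,
#'   `calibrator_id`.
#' @export
compute_rq <- function(norm, calibrator_id) {
  stopifnot(inherits(norm, "normalized_matrix"))
  j <- match(calibrator_id, norm$samples)
  if (is.na(j)) stop("unknown calibrator id: ", calibrator_id)
  cal <- norm$delta_ct[, j]
  ddct <- norm$delta_ct - cal
  rq <- 2^(-ddct)
  structure(
    list(assay_ids = norm$assay_ids, panel = norm$panel, ddct = ddct,
         rq = rq, mask = is.na(ddct), samples = norm$samples,
         calibrator_id = calibrator_id),
    class = "relative_quantification")
}

#' Bin a fold change by magnitude
#'
#' Bins are defined on `m = max(fc, 1/fc)` so they are symmetric for up-
#' and down-regulation: `m > 4` is `"FC > 4"`, then `"FC 2.0-4.0"`,
#' `"FC 1.6-2.0"`, `"FC 1.2-1.6"`; `m <= 1.2` has no bin (`NA`).
#'
#' @param fc positive numeric vector of fold changes.
#' @return character vector of bin labels (`NA` below 1.2-fold).
#' @export
#' @examples
#' fc_bin(c(34.6805, 0.2785, 1.0))
fc_bin <- function(fc) {
  if (any(!is.na(fc) & fc <= 0)) stop("fold changes must be positive")
  m <- pmax(fc, 1 / fc)
  out <- rep(NA_character_, length(fc))
  out[!is.na(m) & m > 1.2] <- "FC 1.2-1.6"
  out[!is.na(m) & m > 1.6] <- "FC 1.6-2.0"
  out[!is.na(m) & m > 2] <- "FC 2.0-4.0"
  out[!is.na(m) & m > 4] <- "FC > 4"
  out
}

#' Group-level fold change between two sample groups
#'
#' The group fold change of an assay is the ratio of the geometric mean RQ
#' of the numerator group to that of the denominator group — equivalently
#' `2^-(mean delta-Ct numerator - mean delta-Ct denominator)`, so the
#' calibrator cancels. Masked values are excluded from the means.
#'
#' @param rq a `relative_quantification` (or a `normalized_matrix`, in
#'   which case the calibrator-free delta-Ct form is used directly).
#' @param groups named list mapping group label -> character vector of
#'   sample ids.
#' @param numerator,denominator group labels (keys of `groups`).
#' @return data.frame with one row per assay: `assay_id`, `fc`, `log2_fc`,
#'   `fc_bin`, `n_num`, `n_den`, `evaluable`. Assays with an empty unmasked
#'   group are flagged `evaluable = FALSE` with `NA` estimates.
#' @export
group_fold_change <- function(rq, groups, numerator, denominator) {
  if (inherits(rq, "relative_quantification")) {
    vals <- -rq$ddct          # log2 RQ
    samples <- rq$samples
    ids <- rq$assay_ids
  } else if (inherits(rq, "normalized_matrix")) {
    vals <- -rq$delta_ct
    samples <- rq$samples
    ids <- rq$assay_ids
  } else stop("rq must be a relative_quantification or normalized_matrix")
  for (g in c(numerator, denominator)) {
    if (is.null(groups[[g]])) stop("unknown group: ", g)
    if (!length(intersect(groups[[g]], samples)))
      stop("group ", g, " has no samples in the matrix")
  }
  jn <- match(intersect(groups[[numerator]], samples), samples)
  jd <- match(intersect(groups[[denominator]], samples), samples)
  mn <- rowMeans(vals[, jn, drop = FALSE], na.rm = TRUE)
  md <- rowMeans(vals[, jd, drop = FALSE], na.rm = TRUE)
  n_num <- rowSums(!is.na(vals[, jn, drop = FALSE]))
  n_den <- rowSums(!is.na(vals[, jd, drop = FALSE]))
  log2_fc <- mn - md
  evaluable <- n_num >= 1 & n_den >= 1
  log2_fc[!evaluable] <- NA
  fc <- 2^log2_fc
  data.frame(assay_id = ids, fc = fc, log2_fc = log2_fc,
             fc_bin = fc_bin(fc), n_num = n_num, n_den = n_den,
             evaluable = evaluable, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Intensity transform of normalized CT values
#'
#' Maps delta-Ct to a positive abundance scale, `intensity = 2^-delta_ct`,
#' so that higher expression gives larger intensity and the ratio of class
#' geometric mean intensities equals the group fold change exactly.
#'
#' @param norm a `normalized_matrix`.
#' @return numeric matrix (assays x samples) of intensities, `NA` where
#'   masked.
#' @export
intensity_transform <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  out <- 2^(-norm$delta_ct)
  rownames(out) <- norm$assay_ids
  colnames(out) <- norm$samples
  out
}

# internal: named list group -> sample ids from a sample_annotation
.groups_from_annotation <- function(ann) {
  split(ann$sample_id, ann$group)
}
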