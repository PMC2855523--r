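#' CT matrix container for TLDA exports
#'
#' A `ct_matrix` holds raw cycle-threshold (CT) values from one or more
#' TaqMan low density array (TLDA) cards: one row per well (replicate
#' control wells keep distinct well indices), one column per sample, with an
#' explicit mask for "Undetermined" wells. Endogenous-control and
#' negative-control wells are identified by assay-name pattern so that
#' normalization can aggregate and exclude them.
#'
#' @param ct numeric matrix of CT values (wells x samples). CT is the PCR
#'   cycle at which fluorescence crosses the detection threshold; lower CT
#'   means higher abundance. Values are typically in 10-40 cycles.
#' @param wells data.frame with columns `assay_id` (full name with trailing
#'   assay-ID suffix, e.g. `"hsa-miR-204-4373094"`), `panel` (`"A"` or
#'   `"B"`) and `well` (integer replicate index within assay/panel).
#' @param mask logical matrix, same shape as `ct`; `TRUE` marks
#'   undetermined/missing wells. Defaults to `is.na(ct)`.
#' @param samples character vector of sample identifiers (defaults to
#'   `colnames(ct)`).
#' @param batch character or integer vector of per-sample processing batch
#'   labels, recycled to the number of samples; may be `NULL`.
#' @param control_name regular expression identifying the endogenous
#'   control assay (default `"MammU6"`).
#' @param negative_name regular expression identifying the negative-control
#'   assay (default `"ath-miR159a"`).
#'
#' @return An object of class `ct_matrix`: a list with elements `ct`,
#'   `mask`, `wells`, `samples`, `batch` and `control_roles` (named
#'   character vector, one of `"endogenous"`, `"negative"`, `"none"` per
#'   distinct assay).
#' @export
ct_matrix <- function(ct, wells, mask = NULL, samples = colnames(ct),
                      batch = NULL, control_name = "MammU6",
                      negative_name = "ath-miR159a") {
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  if (is.null(mask)) mask <- is.na(ct)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(ct)))
    stop("mask must have the same dimensions as ct")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(ct)))
  samples <- as.character(samples)
  if (length(samples) != ncol(ct))
    stop("length(samples) must equal ncol(ct)")
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers")
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  req <- c("assay_id", "panel", "well")
  if (!all(req %in% names(wells)))
    stop("wells must have columns assay_id, panel, well")
  if (nrow(wells) != nrow(ct))
    stop("nrow(wells) must equal nrow(ct)")
  if (!all(wells$panel %in% c("A", "B")))
    stop("panel labels must be 'A' or 'B'")
  key <- paste(wells$assay_id, wells$panel, wells$well, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (assay_id, panel, well) combinations")
  if (!is.null(batch)) {
    batch <- rep_len(as.character(batch), length(samples))
    names(batch) <- samples
  }
  ids <- unique(wells$assay_id)
  roles <- rep("none", length(ids))
  roles[grepl(control_name, ids)] <- "endogenous"
  roles[grepl(negative_name, ids)] <- "negative"
  names(roles) <- ids
  colnames(ct) <- colnames(mask) <- samples
  rownames(ct) <- rownames(mask) <- NULL
  # CT values must be finite wherever unmasked
  if (any(!mask & !is.finite(ct)))
    stop("non-finite CT value in unmasked cell")
  structure(
    list(ct = ct, mask = mask, wells = wells, samples = samples,
         batch = batch, control_roles = roles),
    class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  n_assay <- length(unique(x$wells$assay_id))
  cat("ct_matrix:", nrow(x$ct), "wells (", n_assay, "assays ) x",
      length(x$samples), "samples\n")
  cat("  panels:", paste(names(table(x$wells$panel)),
                         table(x$wells$panel), collapse = ", "), "\n")
  cat("  masked wells:", sum(x$mask), "\n")
  ctrl <- x$control_roles[x$control_roles != "none"]
  if (length(ctrl))
    cat("  controls:", paste(names(ctrl), "(", ctrl, ")", collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' Strip the assay-ID suffix from a TLDA assay name
#'
#' TLDA assay identifiers carry a trailing numeric assay-ID (e.g.
#' `"hsa-miR-204-4373094"`). The full string is the primary key throughout
#' the package (it distinguishes miR and miR* forms that would otherwise
#' collide); this helper derives the human-readable name.
#'
#' @param assay_id character vector of full assay identifiers.
#' @return character vector with the trailing `-<digits>` suffix removed.
#' @export
#' @examples
#' strip_assay_suffix("hsa-miR-204-4373094")
strip_assay_suffix <- function(assay_id) {
  sub("-[0-9]+$", "", assay_id)
}

#' Replace undetermined CT values by a ceiling value
#'
#' Undetermined wells are masked by default and excluded from all
#' downstream means. This optional censoring policy instead substitutes a
#' fixed ceiling CT (treating no-amplification as "at or beyond the last
#' cycle observed") and unmasks the wells, a common alternative in TLDA
#' practice.
#'
#' @param x a `ct_matrix`.
#' @param ceiling_ct CT value substituted for masked wells (cycles,
#'   default 40).
#' @return a `ct_matrix` with no masked wells.
#' @export
apply_ct_ceiling <- function(x, ceiling_ct = 40) {
  stopifnot(inherits(x, "ct_matrix"), is.numeric(ceiling_ct))
  x$ct[x$mask] <- ceiling_ct
  x$mask[] <- FALSE
  x
}

# internal: indices of wells by control role
.well_role <- function(x) {
  unname(x$control_roles[x$wells$assay_id])
}
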