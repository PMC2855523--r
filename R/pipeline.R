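#' Run the full TLDA analysis pipeline from a configuration
#'
#' Config-driven orchestration: load (or simulate) CT data, normalize,
#' run the configured class comparisons, embed and cluster the samples,
#' run class prediction, and write every artifact plus a manifest with
#' checksums and a run log. Reruns with an identical configuration produce
#' identical artifacts.
#'
#' @param config either a path to a YAML file or a list with elements:
#'   \describe{
#'     \item{`ct_path`, `annotation_path`}{input files for real data
#'       (parsed by [read_ct_table()] / [read_sample_annotations()]); or}
#'     \item{`synthetic`}{a list of [synthetic_config()] arguments (or a
#'       `synthetic_config`) to simulate instead;}
#'     \item{`out_dir`}{output directory (created if needed);}
#'     \item{`mode`}{`"I"` or `"II"` (default `"II"`);}
#'     \item{`contrasts`}{list of length-2 character vectors of group
#'       labels (default `list(c("Mel 60", "Mel 30"))`);}
#'     \item{`calibrator`}{calibrator sample id for mode I (default: the
#'       annotation's calibrator);}
#'     \item{`n_permutations`}{per-assay permutation count for mode II
#'       comparisons and the multivariate selection (default 200);}
#'     \item{`confidence`, `fdr_bound`}{multivariate selection settings
#'       (defaults 0.90 / 0.10);}
#'     \item{`predict`}{`NULL` to skip, or a list with `contrast`
#'       (length-2 groups) and `methods` (classifier names, see
#'       [classifier_spec()]);}
#'     \item{`embed`, `cluster`}{logical switches (default TRUE);}
#'     \item{`seed`}{integer seed for every stochastic stage (default 1).}
#'   }
#' @return invisibly, a list with `manifest` (data.frame of artifact paths
#'   and md5 checksums), `results` (in-memory stage outputs) and
#'   `log_path`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("missing config file: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .pipeline_defaults(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                            "\n", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("tldaRQ", as.character(utils::packageVersion("tldaRQ")),
       "| seed", cfg$seed, "| mode", cfg$mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("ERROR in stage", name, ":", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list()
  artifacts <- character(0)
  emit <- function(path) artifacts <<- c(artifacts, path)

  # --- load or simulate -------------------------------------------------
  dat <- stage("input", {
    if (!is.null(cfg$synthetic)) {
      sc <- cfg$synthetic
      if (!inherits(sc, "synthetic_config")) {
        sc$seed <- sc$seed %||% cfg$seed
        # YAML deserialises named vectors as lists
        for (f in c("panel_split", "groups"))
          if (!is.null(sc[[f]])) sc[[f]] <- unlist(sc[[f]])
        if (!is.null(sc$effects))
          sc$effects <- as.data.frame(lapply(as.data.frame(sc$effects),
                                             unlist))
        sc <- do.call(synthetic_config, sc)
      }
      generate_dataset(sc)
    } else {
      if (is.null(cfg$ct_path) || !file.exists(cfg$ct_path))
        stop("missing CT input file: ", cfg$ct_path %||% "<unset>")
      if (is.null(cfg$annotation_path) || !file.exists(cfg$annotation_path))
        stop("missing annotation file: ", cfg$annotation_path %||% "<unset>")
      list(ct = read_ct_table(cfg$ct_path, cfg$format_options %||% list()),
           annotations = read_sample_annotations(cfg$annotation_path),
           truth = NULL)
    }
  })
  logf("input:", length(unique(dat$ct$wells$assay_id)), "assays x",
       length(dat$ct$samples), "samples")

  # --- normalization ----------------------------------------------------
  norm <- stage("normalization", compute_delta_ct(dat$ct))
  results$normalized <- norm
  p <- file.path(cfg$out_dir, "normalized_delta_ct.tsv")
  utils::write.table(
    data.frame(assay_id = norm$assay_ids, panel = norm$panel,
               round(norm$delta_ct, 4), check.names = FALSE),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  emit(p)

  # --- class comparisons ------------------------------------------------
  results$comparisons <- list()
  for (ctr in cfg$contrasts) {
    key <- paste(gsub(" ", "", ctr), collapse = "_vs_")
    cmp <- stage(paste0("compare:", key),
                 compare_classes(norm, dat$annotations, ctr,
                                 mode = cfg$mode,
                                 calibrator = cfg$calibrator,
                                 n_permutations =
                                   if (cfg$mode == "II") cfg$n_permutations
                                   else 0,
                                 seed = cfg$seed))
    results$comparisons[[key]] <- cmp
    p <- file.path(cfg$out_dir, paste0("comparison_", key, ".tsv"))
    write_result_table(cmp[cmp$p <= cfg$alpha & !cmp$flagged, ], p,
                       layout = if (cfg$mode == "II") "intensity" else "fc")
    emit(p)
    logf("compare", key, ":", sum(cmp$p <= cfg$alpha, na.rm = TRUE),
         "significant at", cfg$alpha)
    if (cfg$mode == "II") {
      sel <- stage(paste0("mvselect:", key), {
        cls <- .resolve_contrast(norm, dat$annotations, ctr)
        idx <- lapply(cls, match, table = norm$samples)
        sub <- -norm$delta_ct[, unlist(idx), drop = FALSE]
        multivariate_permutation_select(
          sub, rep(names(cls), lengths(cls)),
          confidence = cfg$confidence, fdr_bound = cfg$fdr_bound,
          B = max(cfg$n_permutations, 100), seed = cfg$seed)
      })
      results$selection[[key]] <- sel
      logf("mvselect", key, ":", length(sel$selected_assays),
           "assays selected")
    }
  }

  # --- unsupervised -----------------------------------------------------
  if (isTRUE(cfg$embed)) {
    emb <- stage("embed", mds_embed(-norm$delta_ct))
    results$embedding <- emb
    p <- file.path(cfg$out_dir, "mds_embedding.tsv")
    write_embedding(emb, p); emit(p)
  }
  if (isTRUE(cfg$cluster)) {
    tree <- stage("cluster",
                  hierarchical_cluster(-norm$delta_ct, axis = "samples"))
    results$cluster <- tree
    p <- file.path(cfg$out_dir, "sample_dendrogram.txt")
    od <- tree$samples$order
    writeLines(paste(colnames(tree$matrix)[od], collapse = "\t"), p)
    emit(p)
  }

  # --- class prediction -------------------------------------------------
  if (!is.null(cfg$predict)) {
    pr <- cfg$predict
    cls <- .resolve_contrast(norm, dat$annotations,
                             pr$contrast %||% c("Mel 60", "Mel 30"))
    idx <- lapply(cls, match, table = norm$samples)
    sub <- -norm$delta_ct[, unlist(idx), drop = FALSE]
    rownames(sub) <- norm$assay_ids
    labs <- rep(names(cls), lengths(cls))
    results$cv <- list()
    for (m in (pr$methods %||% c("compound_covariate", "dlda"))) {
      spec <- classifier_spec(m,
                              selection_alpha = pr$selection_alpha %||%
                                0.001)
      rep_m <- stage(paste0("predict:", m), loocv(sub, labs, spec))
      results$cv[[m]] <- rep_m
      p <- file.path(cfg$out_dir, paste0("cv_", m, ".tsv"))
      write_result_table(rep_m, p, layout = "cv")
      emit(p)
      logf("predict", m, ": error rate",
           sprintf("%.3f", rep_m$error_rate))
    }
  }

  # --- manifest ---------------------------------------------------------
  manifest <- data.frame(path = artifacts,
                         md5 = unname(tools::md5sum(artifacts)),
                         stringsAsFactors = FALSE)
  mp <- file.path(cfg$out_dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  logf("done:", nrow(manifest), "artifacts")
  invisible(list(manifest = manifest, results = results,
                 log_path = log_path))
}

# internal: fill pipeline defaults
.pipeline_defaults <- function(config) {
  defaults <- list(out_dir = "tldaRQ_out", mode = "II",
                   contrasts = list(c("Mel 60", "Mel 30")),
                   alpha = 0.05, n_permutations = 200, confidence = 0.90,
                   fdr_bound = 0.10, calibrator = NULL, predict = NULL,
                   embed = TRUE, cluster = TRUE, seed = 1)
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  cfg$mode <- match.arg(cfg$mode, c("I", "II"))
  cfg
}
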