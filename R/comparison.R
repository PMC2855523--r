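#' Pooled-variance two-sample t-test
#'
#' Classic two-sided equal-variance t-test, the univariate statistic of the
#' class comparisons. Degenerate assays (zero pooled variance) are not
#' dropped: when the means are equal the statistic is 0 with p = 1; when
#' they differ with zero variance the p-value is set to 1 and flagged, so
#' the multiple-testing universe stays intact.
#'
#' @param x,y numeric vectors (the two classes); `NA` dropped.
#' @return named numeric vector `c(t, df, p)`.
#' @export
two_sample_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per class")
  d <- n1 + n2 - 2
  v <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / d
  diff <- mean(x) - mean(y)
  if (v <= 0) {
    tt <- if (diff == 0) 0 else sign(diff) * Inf
    return(c(t = tt, df = d, p = 1))
  }
  tt <- diff / sqrt(v * (1 / n1 + 1 / n2))
  c(t = tt, df = d, p = 2 * stats::pt(-abs(tt), d))
}

# internal: per-row class summaries with NA handling
.row_group_stats <- function(mat, idx) {
  m <- mat[, idx, drop = FALSE]
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  list(n = n, mu = mu, ss = ss)
}

#' Row-wise two-class t statistics
#'
#' Vectorised pooled (or RVM-moderated, when `hyper` is given) two-sample
#' t statistics over the rows of an assays x samples matrix. This is the
#' kernel the permutation machinery re-invokes for every relabelling.
#'
#' @param mat numeric matrix, assays x samples (`NA` = masked).
#' @param idx1,idx2 column indices of the two classes.
#' @param hyper optional `rvm_hyper`; when supplied the shrunken variance
#'   and augmented degrees of freedom are used.
#' @return data.frame with columns `t`, `df`, `p`, `flagged` (degenerate or
#'   under-replicated rows, p forced to 1).
#' @export
row_t_stats <- function(mat, idx1, idx2, hyper = NULL) {
  g1 <- .row_group_stats(mat, idx1)
  g2 <- .row_group_stats(mat, idx2)
  d <- g1$n + g2$n - 2
  ok <- g1$n >= 2 & g2$n >= 2
  v <- (g1$ss + g2$ss) / pmax(d, 1)
  diff <- g1$mu - g2$mu
  if (!is.null(hyper)) {
    s2 <- .rvm_shrink(v, d, hyper)
    dfree <- d + 2 * hyper$a
  } else {
    s2 <- v
    dfree <- d
  }
  se <- sqrt(s2 * (1 / g1$n + 1 / g2$n))
  tt <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- 2 * stats::pt(-abs(tt), dfree)
  flagged <- !ok | !is.finite(tt) | v <= 0    # degenerate rows: p forced to 1
  p[flagged] <- 1
  tt[!ok] <- NA
  data.frame(t = tt, df = dfree, p = p, flagged = flagged)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment; a thin validated wrapper so report
#' columns are explicit about the procedure.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return vector of BH-adjusted values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# internal: all distinct assignments of n1 class-1 columns among n
.assignments <- function(n, n1) {
  utils::combn(n, n1)
}

#' Per-assay univariate permutation p-values
#'
#' For each assay, the two-sided permutation p-value of its class
#' difference under random relabelling of the samples. When the number of
#' distinct label assignments `choose(n, n1)` is at most `B`, the exact
#' exhaustive distribution is enumerated (the p-value is then the exact
#' proportion, identity included); otherwise `B` Monte-Carlo permutations
#' are drawn and the add-one convention `(1 + k) / (1 + B)` is used so no
#' p-value is zero.
#'
#' @param mat assays x samples matrix (`NA` = masked).
#' @param labels two-level factor (or coercible) over the columns.
#' @param B number of permutations (>= 1).
#' @param seed integer seed for the Monte-Carlo branch.
#' @param stat `"t"` (pooled) or `"rvm"`.
#' @param hyper `rvm_hyper` used when `stat = "rvm"`; fitted from the
#'   observed data when `NULL`.
#' @return numeric vector of permutation p-values, one per row of `mat`.
#' @export
univariate_permutation_p <- function(mat, labels, B = 1000, seed = 1,
                                     stat = c("t", "rvm"), hyper = NULL) {
  stat <- match.arg(stat)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need two or more classes")
  if (nlevels(labels) != 2)
    stop("univariate permutation p is defined for two classes")
  if (B < 1) stop("B must be >= 1")
  n <- length(labels)
  idx1 <- which(labels == levels(labels)[1])
  idx2 <- which(labels == levels(labels)[2])
  if (stat == "rvm" && is.null(hyper)) hyper <- .fit_hyper(mat, idx1, idx2)
  h <- if (stat == "rvm") hyper else NULL
  obs <- abs(row_t_stats(mat, idx1, idx2, h)$t)
  n1 <- length(idx1)
  n_assign <- choose(n, n1)
  if (n_assign <= B) {
    asg <- .assignments(n, n1)
    count <- integer(nrow(mat))
    for (k in seq_len(ncol(asg))) {
      i1 <- asg[, k]
      tb <- abs(row_t_stats(mat, i1, setdiff(seq_len(n), i1), h)$t)
      count <- count + (!is.na(tb) & !is.na(obs) & tb >= obs)
    }
    p <- count / ncol(asg)
  } else {
    set.seed(seed)
    count <- integer(nrow(mat))
    for (k in seq_len(B)) {
      i1 <- sample(n, n1)
      tb <- abs(row_t_stats(mat, i1, setdiff(seq_len(n), i1), h)$t)
      count <- count + (!is.na(tb) & !is.na(obs) & tb >= obs)
    }
    p <- (1 + count) / (1 + B)
  }
  p[is.na(obs)] <- NA
  p
}

# internal: fit RVM hyperparameters from the pooled within-class variances
.fit_hyper <- function(mat, idx1, idx2) {
  g1 <- .row_group_stats(mat, idx1)
  g2 <- .row_group_stats(mat, idx2)
  d <- g1$n + g2$n - 2
  v <- (g1$ss + g2$ss) / pmax(d, 1)
  fit_rvm(v[d >= 1], d[d >= 1])
}

#' Global permutation test of any class difference
#'
#' Permutes the class labels, recomputes every assay's p-value for each
#' permutation, and counts how many assays are significant at `alpha`. The
#' global p-value is the proportion of permutations giving at least as many
#' significant assays as the observed labelling.
#'
#' @param mat assays x samples matrix.
#' @param labels two-level class labels over the columns.
#' @param alpha per-assay significance level counted (default 0.001).
#' @param B number of permutations.
#' @param seed integer seed.
#' @param stat,hyper statistic choice as in [univariate_permutation_p()].
#' @return list with `p` (global p-value), `n_significant` (observed
#'   count), `perm_counts` (length-`B` integer vector).
#' @export
global_permutation_test <- function(mat, labels, alpha = 0.001, B = 1000,
                                    seed = 1, stat = c("t", "rvm"),
                                    hyper = NULL) {
  stat <- match.arg(stat)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two classes")
  if (B < 1) stop("B must be >= 1")
  idx1 <- which(labels == levels(labels)[1])
  idx2 <- which(labels == levels(labels)[2])
  if (stat == "rvm" && is.null(hyper)) hyper <- .fit_hyper(mat, idx1, idx2)
  h <- if (stat == "rvm") hyper else NULL
  n <- length(labels)
  n1 <- length(idx1)
  obs <- sum(row_t_stats(mat, idx1, idx2, h)$p <= alpha, na.rm = TRUE)
  set.seed(seed)
  counts <- integer(B)
  for (k in seq_len(B)) {
    i1 <- sample(n, n1)
    counts[k] <- sum(row_t_stats(mat, i1, setdiff(seq_len(n), i1), h)$p <=
                       alpha, na.rm = TRUE)
  }
  list(p = mean(counts >= obs), n_significant = obs, perm_counts = counts)
}

#' Multivariate permutation feature selection with bounded FDR
#'
#' Selects differentially expressed assays so that, with the stated
#' confidence over the permutation distribution of false-discovery counts,
#' the proportion of false discoveries among the selected assays is below
#' `fdr_bound` (the standard 90%-confidence / 10%-FDR class-comparison
#' setting). Candidate cutoffs are the ordered observed p-values; for
#' each cutoff the `confidence`-quantile of the permuted count of p-values
#' below the cutoff estimates the false discoveries, and the largest cutoff
#' whose bound holds is used. `confidence = 0` degenerates to controlling
#' the expected number of false discoveries.
#'
#' @param mat assays x samples matrix.
#' @param labels two-level class labels.
#' @param confidence confidence level on the FDR bound (default 0.90).
#' @param fdr_bound false discovery proportion bound (default 0.10).
#' @param B number of permutations (>= 100 for a usable quantile).
#' @param seed integer seed.
#' @param stat,hyper statistic choice; default is the random-variance t.
#' @return object of class `mvperm_result`: list with `selected_assays`
#'   (integer row indices), `p_cutoff`, `observed_p`, `confidence`,
#'   `fdr_bound`, `n_permutations`.
#' @export
multivariate_permutation_select <- function(mat, labels, confidence = 0.90,
                                            fdr_bound = 0.10, B = 1000,
                                            seed = 1,
                                            stat = c("rvm", "t"),
                                            hyper = NULL) {
  stat <- match.arg(stat)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two classes")
  if (confidence > 0 && B < 100)
    stop("B must be >= 100 to estimate the confidence quantile")
  idx1 <- which(labels == levels(labels)[1])
  idx2 <- which(labels == levels(labels)[2])
  if (stat == "rvm" && is.null(hyper)) hyper <- .fit_hyper(mat, idx1, idx2)
  h <- if (stat == "rvm") hyper else NULL
  obs_p <- row_t_stats(mat, idx1, idx2, h)$p
  usable <- which(!is.na(obs_p))
  ord <- usable[order(obs_p[usable])]
  sorted_p <- obs_p[ord]
  n <- length(labels)
  n1 <- length(idx1)
  set.seed(seed)
  # the observed labelling counts as one member of the permutation set
  V <- matrix(0L, B + 1, length(ord))
  V[1, ] <- findInterval(sorted_p, sorted_p)
  minp <- numeric(B + 1)
  minp[1] <- sorted_p[1]
  for (k in seq_len(B)) {
    i1 <- sample(n, n1)
    pb <- row_t_stats(mat, i1, setdiff(seq_len(n), i1), h)$p
    V[k + 1, ] <- findInterval(sorted_p, sort(pb[!is.na(pb)]))
    minp[k + 1] <- min(pb, na.rm = TRUE)
  }
  # gate: permutation min-p test of the global null at level 1 - confidence,
  # so that under a complete null the selection is empty with the stated
  # confidence (exact by label exchangeability)
  gate_p <- mean(minp <= sorted_p[1])
  if (confidence > 0 && gate_p > 1 - confidence) {
    i_max <- 0L
  } else {
    qV <- if (confidence == 0) colMeans(V)
          else apply(V, 2, stats::quantile, probs = confidence, type = 1)
    ok <- qV <= fdr_bound * seq_along(ord)
    i_max <- if (any(ok)) max(which(ok)) else 0L
  }
  selected <- if (i_max > 0) ord[seq_len(i_max)] else integer(0)
  structure(
    list(selected_assays = selected,
         p_cutoff = if (i_max > 0) sorted_p[i_max] else NA_real_,
         observed_p = obs_p, confidence = confidence,
         fdr_bound = fdr_bound, n_permutations = B),
    class = "mvperm_result")
}

#' @export
print.mvperm_result <- function(x, ...) {
  cat("multivariate permutation selection:", length(x$selected_assays),
      "assays at", sprintf("%.0f%% confidence FDR <= %.0f%%",
                           100 * x$confidence, 100 * x$fdr_bound),
      "( B =", x$n_permutations, ")\n")
  invisible(x)
}

#' Row-wise one-way ANOVA F-test
#'
#' One-way fixed-effects F statistic per assay across 2+ classes (used for
#' the four-way node-status comparison). Classes reduced to a single
#' member still contribute to the between-class term; degrees of freedom
#' adjust per row to the classes and samples actually observed.
#'
#' @param mat assays x samples matrix (`NA` = masked), or a numeric vector
#'   for a single assay.
#' @param labels class labels over the columns (2 or more levels).
#' @return data.frame with columns `F`, `df1`, `df2`, `p`.
#' @export
multiclass_f_test <- function(mat, labels) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least two classes")
  if (length(labels) != ncol(mat))
    stop("labels must match the number of columns")
  K <- nlevels(labels)
  G <- nrow(mat)
  n_k <- mu_k <- ss_k <- vector("list", K)
  for (k in seq_len(K)) {
    st <- .row_group_stats(mat, which(labels == levels(labels)[k]))
    n_k[[k]] <- st$n; mu_k[[k]] <- st$mu; ss_k[[k]] <- st$ss
  }
  N <- Reduce(`+`, n_k)
  k_present <- Reduce(`+`, lapply(n_k, function(n) (n >= 1) * 1))
  grand <- Reduce(`+`, Map(function(n, m) ifelse(n >= 1, n * m, 0),
                           n_k, mu_k)) / N
  ssb <- Reduce(`+`, Map(function(n, m) ifelse(n >= 1, n * (m - grand)^2, 0),
                         n_k, mu_k))
  ssw <- Reduce(`+`, ss_k)
  df1 <- k_present - 1
  df2 <- N - k_present
  Fs <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(Fs, df1, df2, lower.tail = FALSE)
  bad <- df1 < 1 | df2 < 1 | !is.finite(Fs)
  p[bad & !is.na(ssb) & ssb > 0 & ssw == 0] <- 1  # degenerate, flagged
  Fs[df1 < 1 | df2 < 1] <- NA
  data.frame(F = Fs, df1 = df1, df2 = df2, p = p)
}

#' Run a full class comparison over a normalized matrix
#'
#' Drives one contrast end to end and returns one record per assay, sorted
#' by p-value. Two analysis modes are provided, mirroring the two
#' normalization routes:
#' \describe{
#'   \item{`mode = "I"`}{relative quantification: statistics on per-sample
#'     log2 RQ values (delta-delta-Ct against a calibrator), plain pooled
#'     t-test, group fold change as ratio of geometric mean RQ.}
#'   \item{`mode = "II"`}{normalized CT: statistics on the MammU6
#'     delta-Ct values (log2 intensity scale), random-variance t by
#'     default, optional per-assay permutation p-values, per-class
#'     geometric mean intensities reported.}
#' }
#'
#' @param norm a `normalized_matrix` (from [compute_delta_ct()]).
#' @param annotations a `sample_annotation` data.frame.
#' @param contrast either a length-2 character vector of group labels
#'   (numerator first), or a named list of 2+ character vectors of sample
#'   ids defining custom classes (e.g. stage-restricted subsets, node
#'   status groups). With more than two classes a one-way F-test is run.
#' @param mode `"I"` or `"II"` (see above).
#' @param calibrator calibrator sample id for mode I; defaults to the
#'   annotation's `is_calibrator` sample (first if several).
#' @param stat statistic for mode II: `"rvm"` (default) or `"t"`.
#' @param n_permutations per-assay permutation p-values for mode II
#'   (0 disables).
#' @param seed integer seed for permutation machinery.
#' @return data.frame of class `comparison_result`, one row per assay,
#'   sorted by p then assay id: `assay_id`, `fc`, `log2_fc`, `fc_bin`,
#'   `t` (or `F`), `p`, `fdr_bh`, `perm_p` (mode II), `geomean_<class>`
#'   columns (mode II), `flagged`.
#' @export
compare_classes <- function(norm, annotations, contrast,
                            mode = c("I", "II"), calibrator = NULL,
                            stat = c("rvm", "t"), n_permutations = 0,
                            seed = 1) {
  mode <- match.arg(mode)
  stat <- match.arg(stat)
  stopifnot(inherits(norm, "normalized_matrix"))
  classes <- .resolve_contrast(norm, annotations, contrast)
  if (any(lengths(classes) == 0))
    stop("empty contrast group")
  if (mode == "I") {
    if (is.null(calibrator)) {
      cal <- annotations$sample_id[which(annotations$is_calibrator)]
      if (!length(cal)) stop("mode I needs a calibrator sample")
      calibrator <- cal[1]
    }
    rqo <- compute_rq(norm, calibrator)
    vals <- -rqo$ddct                    # log2 RQ
  } else {
    vals <- -norm$delta_ct               # log2 intensity
  }
  n_classes <- length(classes)
  col_idx <- lapply(classes, match, table = norm$samples)
  if (n_classes == 2) {
    h <- NULL
    if (mode == "II" && stat == "rvm")
      h <- .fit_hyper(vals, col_idx[[1]], col_idx[[2]])
    ts <- row_t_stats(vals, col_idx[[1]], col_idx[[2]],
                      if (mode == "II") h else NULL)
    m1 <- rowMeans(vals[, col_idx[[1]], drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(vals[, col_idx[[2]], drop = FALSE], na.rm = TRUE)
    log2_fc <- m1 - m2
    out <- data.frame(assay_id = norm$assay_ids, fc = 2^log2_fc,
                      log2_fc = log2_fc, fc_bin = fc_bin(2^log2_fc),
                      t = ts$t, p = ts$p, fdr_bh = bh_fdr(ts$p),
                      flagged = ts$flagged, stringsAsFactors = FALSE)
    if (mode == "II") {
      for (k in seq_len(2))
        out[[paste0("geomean_", names(classes)[k])]] <-
          2^rowMeans(vals[, col_idx[[k]], drop = FALSE], na.rm = TRUE)
      if (n_permutations > 0) {
        sub <- vals[, c(col_idx[[1]], col_idx[[2]]), drop = FALSE]
        lab <- rep(names(classes), lengths(classes))
        out$perm_p <- univariate_permutation_p(sub, lab,
                                               B = n_permutations,
                                               seed = seed, stat = stat,
                                               hyper = h)
      }
    }
  } else {
    sub_idx <- unlist(col_idx)
    lab <- rep(names(classes), lengths(classes))
    ft <- multiclass_f_test(vals[, sub_idx, drop = FALSE], lab)
    out <- data.frame(assay_id = norm$assay_ids, F = ft$F, p = ft$p,
                      fdr_bh = bh_fdr(ft$p), flagged = !is.finite(ft$F),
                      stringsAsFactors = FALSE)
    for (k in seq_len(n_classes))
      out[[paste0("geomean_", names(classes)[k])]] <-
        2^rowMeans(vals[, col_idx[[k]], drop = FALSE], na.rm = TRUE)
  }
  out <- out[order(out$p, out$assay_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "contrast") <- names(classes)
  attr(out, "universe") <- length(norm$assay_ids)
  class(out) <- c("comparison_result", "data.frame")
  out
}

# internal: resolve a contrast spec into a named list of sample-id vectors
.resolve_contrast <- function(norm, annotations, contrast) {
  if (is.character(contrast)) {
    groups <- .groups_from_annotation(annotations)
    missing <- setdiff(contrast, names(groups))
    if (length(missing))
      stop("unknown group(s) in contrast: ", paste(missing, collapse = ", "))
    classes <- groups[contrast]
  } else if (is.list(contrast)) {
    classes <- contrast
    if (is.null(names(classes)))
      names(classes) <- paste0("class", seq_along(classes))
  } else stop("contrast must be a character vector or list")
  lapply(classes, intersect, y = norm$samples)
}
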