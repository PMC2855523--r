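#' Classifier specification for class prediction
#'
#' @param method one of `"compound_covariate"`, `"dlda"`, `"knn1"`,
#'   `"knn3"`, `"nearest_centroid"`, `"svm_linear"`, `"bayesian_cc"`.
#' @param selection_alpha per-fold feature-selection significance level
#'   (default 0.001).
#' @param selection_stat feature-selection statistic: `"rvm"` (default,
#'   the random-variance t) or `"t"`.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(method = c("compound_covariate", "dlda", "knn1",
                                       "knn3", "nearest_centroid",
                                       "svm_linear", "bayesian_cc"),
                            selection_alpha = 0.001,
                            selection_stat = c("rvm", "t")) {
  structure(list(method = match.arg(method),
                 selection_alpha = selection_alpha,
                 selection_stat = match.arg(selection_stat)),
            class = "classifier_spec")
}

#' Select differentially expressed features on a training set
#'
#' Features with a two-class p-value below `alpha`, ordered by p. Used
#' inside every cross-validation fold so that the left-out sample never
#' influences the gene list of the model that predicts it.
#'
#' @param mat features x samples training matrix.
#' @param labels two-level training labels.
#' @param alpha significance level (default 0.001).
#' @param stat `"rvm"` or `"t"`.
#' @return integer vector of row indices, ordered by increasing p (may be
#'   empty).
#' @export
select_features <- function(mat, labels, alpha = 0.001,
                            stat = c("rvm", "t")) {
  stat <- match.arg(stat)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("both classes must be present")
  idx1 <- which(labels == levels(labels)[1])
  idx2 <- which(labels == levels(labels)[2])
  h <- NULL
  if (stat == "rvm") {
    # under-replicated folds (no residual df) fall back to the plain t
    h <- tryCatch(.fit_hyper(mat, idx1, idx2), error = function(e) NULL)
  }
  p <- row_t_stats(mat, idx1, idx2, h)$p
  sel <- which(!is.na(p) & p < alpha)
  sel[order(p[sel])]
}

#' Train a classifier on selected features
#'
#' Per-method definitions: compound covariate predictor scores a sample by
#' the t-statistic-weighted sum of its feature values, thresholded midway
#' between the training class mean scores; DLDA is a Gaussian discriminant
#' with a pooled diagonal covariance; kNN uses Euclidean distance with
#' majority vote (knn3 ties broken by the nearest neighbour); nearest
#' centroid classifies to the closest class-mean profile; the linear SVM
#' uses unit cost without rescaling; the Bayesian compound covariate
#' applies Gaussian class-conditional posteriors (equal priors) to the CCP
#' score.
#'
#' An empty feature set yields a degenerate majority-class model (flagged).
#'
#' @param spec a [classifier_spec()].
#' @param mat features x samples training matrix restricted to selected
#'   features (0 rows allowed).
#' @param labels two-level training labels.
#' @return a fitted model object of class `tlda_classifier`.
#' @export
train_classifier <- function(spec, mat, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("single-class training set")
  lv <- levels(labels)
  model <- list(spec = spec, levels = lv, degenerate = FALSE)
  if (is.null(dim(mat)) || nrow(mat) == 0) {
    model$degenerate <- TRUE
    tabs <- table(labels)
    model$majority <- names(tabs)[which.max(tabs)]
    return(structure(model, class = "tlda_classifier"))
  }
  i1 <- which(labels == lv[1]); i2 <- which(labels == lv[2])
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  method <- spec$method
  if (method %in% c("compound_covariate", "bayesian_cc")) {
    ts <- row_t_stats(mat, i1, i2)$t
    ts[!is.finite(ts)] <- 0
    scores <- drop(crossprod(mat, ts))
    s1 <- mean(scores[i1]); s2 <- mean(scores[i2])
    model$weights <- ts
    model$threshold <- (s1 + s2) / 2
    model$class1_high <- s1 > s2
    if (method == "bayesian_cc") {
      sd_pool <- sqrt(((length(i1) - 1) * stats::var(scores[i1]) +
                       (length(i2) - 1) * stats::var(scores[i2])) /
                      (length(i1) + length(i2) - 2))
      model$score_means <- c(s1, s2)
      model$score_sd <- max(sd_pool, 1e-8)
    }
  } else if (method %in% c("dlda", "nearest_centroid")) {
    model$centroids <- cbind(m1, m2)
    if (method == "dlda") {
      ss1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2)
      ss2 <- rowSums((mat[, i2, drop = FALSE] - m2)^2)
      v <- (ss1 + ss2) / (length(i1) + length(i2) - 2)
      model$pooled_var <- pmax(v, 1e-12)
    }
  } else if (method %in% c("knn1", "knn3")) {
    model$train_x <- mat
    model$train_y <- labels
    model$k <- if (method == "knn1") 1L else 3L
  } else if (method == "svm_linear") {
    model$svm <- e1071::svm(x = t(mat), y = labels, kernel = "linear",
                            cost = 1, scale = FALSE)
  }
  structure(model, class = "tlda_classifier")
}

#' Predict class labels with a fitted classifier
#'
#' @param object a `tlda_classifier` from [train_classifier()].
#' @param newdata features x samples matrix (same feature rows as used in
#'   training).
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.tlda_classifier <- function(object, newdata, ...) {
  lv <- object$levels
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1)
  ns <- ncol(newdata)
  if (object$degenerate)
    return(factor(rep(object$majority, ns), levels = lv))
  method <- object$spec$method
  if (method == "compound_covariate") {
    scores <- drop(crossprod(newdata, object$weights))
    hi <- scores > object$threshold
    pred <- ifelse(hi == object$class1_high, lv[1], lv[2])
  } else if (method == "bayesian_cc") {
    scores <- drop(crossprod(newdata, object$weights))
    d1 <- stats::dnorm(scores, object$score_means[1], object$score_sd,
                       log = TRUE)
    d2 <- stats::dnorm(scores, object$score_means[2], object$score_sd,
                       log = TRUE)
    pred <- ifelse(d1 >= d2, lv[1], lv[2])
  } else if (method == "dlda") {
    d1 <- colSums((newdata - object$centroids[, 1])^2 / object$pooled_var)
    d2 <- colSums((newdata - object$centroids[, 2])^2 / object$pooled_var)
    pred <- ifelse(d1 <= d2, lv[1], lv[2])
  } else if (method == "nearest_centroid") {
    d1 <- colSums((newdata - object$centroids[, 1])^2)
    d2 <- colSums((newdata - object$centroids[, 2])^2)
    pred <- ifelse(d1 <= d2, lv[1], lv[2])
  } else if (method %in% c("knn1", "knn3")) {
    pred <- character(ns)
    for (j in seq_len(ns)) {
      dd <- colSums((object$train_x - newdata[, j])^2)
      o <- order(dd)
      nb <- object$train_y[o[seq_len(min(object$k, length(o)))]]
      tab <- table(nb)
      top <- names(tab)[tab == max(tab)]
      pred[j] <- if (length(top) == 1) top
                 else as.character(object$train_y[o[1]])   # tie: nearest
    }
  } else if (method == "svm_linear") {
    pred <- as.character(stats::predict(object$svm, t(newdata)))
  }
  factor(pred, levels = lv)
}

#' Leave-one-out cross-validation with in-fold feature reselection
#'
#' Each sample is predicted by a model trained on all other samples; the
#' entire model-building process — including feature selection and, for the
#' random-variance statistic, the hyperparameter fit — is repeated inside
#' every fold, so no information from the left-out sample can leak into its
#' own prediction.
#'
#' @param mat features x samples matrix (rownames = assay ids).
#' @param labels two-level class labels over the columns.
#' @param spec a [classifier_spec()].
#' @return object of class `cv_report`: list with `predictions` (factor),
#'   `labels`, `error_rate`, `confusion`, `class_rates` (per-class
#'   sensitivity/specificity/PPV/NPV matrix), `fold_features` (list of
#'   selected row indices per fold), `spec`.
#' @export
loocv <- function(mat, labels, spec = classifier_spec()) {
  labels <- factor(labels)
  if (any(table(labels) < 2)) stop("need at least 2 samples per class")
  if (nlevels(labels) != 2) stop("class prediction is two-class")
  n <- ncol(mat)
  pred <- character(n)
  fold_features <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    sel <- select_features(mat[, tr, drop = FALSE], labels[tr],
                           alpha = spec$selection_alpha,
                           stat = spec$selection_stat)
    fold_features[[i]] <- sel
    fit <- train_classifier(spec, mat[sel, tr, drop = FALSE], labels[tr])
    pred[i] <- as.character(predict(fit, mat[sel, i, drop = FALSE]))
  }
  pred <- factor(pred, levels = levels(labels))
  .cv_report(pred, labels, fold_features, spec)
}

# internal: build the report from stored per-fold predictions
.cv_report <- function(pred, labels, fold_features, spec) {
  lv <- levels(labels)
  confusion <- table(truth = labels, predicted = pred)
  rates <- t(vapply(lv, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fn <- sum(pred != cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    tn <- sum(pred != cl & labels != cl)
    c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  }, numeric(4)))
  structure(
    list(predictions = pred, labels = labels,
         error_rate = mean(pred != labels), confusion = confusion,
         class_rates = rates, fold_features = fold_features, spec = spec),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("LOOCV", x$spec$method, "- error rate",
      sprintf("%.3f", x$error_rate), "\n")
  print(round(x$class_rates, 3))
  invisible(x)
}

#' Permutation significance of a cross-validated error rate
#'
#' Repeats the entire LOOCV (feature reselection included) under random
#' permutations of the class labels. The p-value is the proportion of
#' permutations whose cross-validated error is no greater than the
#' observed error.
#'
#' @param mat features x samples matrix.
#' @param labels two-level class labels.
#' @param spec a [classifier_spec()].
#' @param n_permutations number of label permutations (study default
#'   1000).
#' @param seed integer seed.
#' @param report an optional precomputed `cv_report` for the observed
#'   labels (avoids recomputation).
#' @return list with `p`, `observed_error`, `perm_errors`.
#' @export
permutation_significance <- function(mat, labels, spec = classifier_spec(),
                                     n_permutations = 1000, seed = 1,
                                     report = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  labels <- factor(labels)
  if (is.null(report)) report <- loocv(mat, labels, spec)
  obs <- report$error_rate
  set.seed(seed)
  perm_errors <- vapply(seq_len(n_permutations), function(b) {
    loocv(mat, sample(labels), spec)$error_rate
  }, numeric(1))
  list(p = mean(perm_errors <= obs), observed_error = obs,
       perm_errors = perm_errors)
}
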