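#' Fit the random variance model by maximum likelihood
#'
#' The random variance model shares variance information across assays:
#' per-assay residual precisions `1/sigma^2` are drawn from a gamma prior
#' with shape `a` and scale `b`, so that each observed residual variance
#' `v_g` (with `d_g` degrees of freedom) satisfies
#' `v_g * a * b ~ F(d_g, 2a)`. The hyperparameters are estimated by
#' maximising the corresponding F log-likelihood over `(log a, log b)`.
#'
#' Fitting is deterministic given the inputs; several method-of-moments
#' starting points guard against local optima. Very homogeneous variance
#' sets push `a` towards its upper bound (full shrinkage towards the common
#' value), which is the model's correct limit.
#'
#' @param variances per-assay residual (pooled within-class) variances;
#'   non-positive values are dropped.
#' @param dfs per-assay residual degrees of freedom (recycled).
#' @return object of class `rvm_hyper`: list with `a`, `b`, `loglik`,
#'   `n_used`, `convergence`.
#' @references Wright & Simon-style inverse-gamma variance prior with
#'   augmented degrees of freedom `d + 2a`.
#' @export
fit_rvm <- function(variances, dfs) {
  dfs <- rep_len(dfs, length(variances))
  ok <- is.finite(variances) & variances > 0 & dfs >= 1
  v <- variances[ok]
  d <- dfs[ok]
  if (length(v) < 10)
    stop("fit_rvm needs at least 10 assays with positive variance")
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(1e12)
    ll <- sum(stats::df(a * b * v, d, 2 * a, log = TRUE)) +
      length(v) * log(a * b)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  # method-of-moments style starts around b ~ 1/mean(v), several shapes
  starts <- list(c(log(2), log(1 / mean(v))),
                 c(log(0.5), log(1 / mean(v))),
                 c(log(10), log(1 / stats::median(v))))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, nll, method = "L-BFGS-B",
                        lower = c(-15, -30), upper = c(15, 30),
                        control = list(maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value) || best$value >= 1e12)
    stop("fit_rvm: optimizer failed to find a finite likelihood (n = ",
         length(v), ", mean v = ", signif(mean(v), 4), ")")
  structure(
    list(a = exp(best$par[1]), b = exp(best$par[2]), loglik = -best$value,
         n_used = length(v), convergence = best$convergence),
    class = "rvm_hyper")
}

#' @export
print.rvm_hyper <- function(x, ...) {
  cat("RVM hyperparameters: a =", signif(x$a, 5), " b =", signif(x$b, 5),
      " (loglik", signif(x$loglik, 6), "on", x$n_used, "assays)\n")
  invisible(x)
}

#' Shrink a residual variance under the random variance model
#'
#' Combines the assay's pooled variance with the prior by degrees of
#' freedom: `s2_tilde = (d * v + 2/b) / (d + 2a)`.
#'
#' @param v residual variances; `d` residual dfs; `hyper` an `rvm_hyper`.
#' @return shrunken variances.
#' @keywords internal
.rvm_shrink <- function(v, d, hyper) {
  (d * v + 2 / hyper$b) / (d + 2 * hyper$a)
}

#' Random-variance moderated two-sample t-test
#'
#' A two-sided pooled t-test whose variance estimate is shrunk towards the
#' random variance model prior, with augmented degrees of freedom
#' `n1 + n2 - 2 + 2a`. As the prior weight vanishes (`a -> 0`, `b -> Inf`)
#' the statistic reduces to the ordinary pooled t.
#'
#' @param x,y numeric vectors (the two classes); `NA` dropped.
#' @param hyper an `rvm_hyper` from [fit_rvm()].
#' @return named numeric vector `c(t, df, p)`.
#' @export
rvm_t <- function(x, y, hyper) {
  stopifnot(inherits(hyper, "rvm_hyper"))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per class")
  d <- n1 + n2 - 2
  v <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / d
  s2 <- .rvm_shrink(v, d, hyper)
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  tt <- (mean(x) - mean(y)) / se
  dfree <- d + 2 * hyper$a
  c(t = tt, df = dfree, p = 2 * stats::pt(-abs(tt), dfree))
}
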