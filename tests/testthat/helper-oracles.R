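# Independent oracle implementations used to cross-check the package.
# These deliberately use naive, brute-force formulations.

# Benjamini-Hochberg step-up, computed directly from the definition
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# O(n^3) average-linkage agglomeration on a distance matrix; returns the
# sorted merge heights
naive_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  d_full <- matrix(Inf, n + (n - 1), n + (n - 1))
  d_full[seq_len(n), seq_len(n)] <- d
  diag(d_full) <- Inf
  heights <- numeric(n - 1)
  nxt <- n
  for (step in seq_len(n - 1)) {
    idx <- which(active[seq_len(nxt)])
    sub <- d_full[idx, idx, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    i <- idx[k[1]]; j <- idx[k[2]]
    heights[step] <- d_full[i, j]
    nxt <- nxt + 1
    members[[nxt]] <- c(members[[i]], members[[j]])
    active[c(i, j)] <- FALSE
    active[nxt] <- TRUE
    for (m in which(active[seq_len(nxt - 1)])) {
      # average linkage: mean pairwise distance between the merged members
      d_full[nxt, m] <- d_full[m, nxt] <-
        mean(d[members[[nxt]], members[[m]]])
    }
  }
  sort(heights)
}

# exhaustive two-sided permutation p-values for one assay, plain pooled t
naive_exhaustive_perm_p <- function(x, labels) {
  labels <- as.factor(labels)
  n <- length(x)
  idx1 <- which(labels == levels(labels)[1])
  tstat <- function(i1) {
    i2 <- setdiff(seq_len(n), i1)
    abs(unname(two_sample_t(x[i1], x[i2])["t"]))
  }
  obs <- tstat(idx1)
  asg <- utils::combn(n, length(idx1))
  perm <- apply(asg, 2, tstat)
  mean(perm >= obs)
}

# small two-group delta-Ct style matrix with optional planted effects
random_two_group_matrix <- function(n_assays, n_per_group, effect = 0,
                                    n_effect = 0, sd = 1, seed = 1) {
  set.seed(seed)
  mat <- matrix(rnorm(n_assays * 2 * n_per_group, sd = sd), n_assays)
  if (n_effect > 0)
    mat[seq_len(n_effect), seq_len(n_per_group)] <-
      mat[seq_len(n_effect), seq_len(n_per_group)] + effect
  list(mat = mat,
       labels = rep(c("g1", "g2"), each = n_per_group),
       planted = seq_len(n_effect))
}
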