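#' Mantel permutation test between two labeled matrices
#'
#' Correlates the paired off-diagonal upper-triangle entries of two labeled
#' symmetric matrices (labels aligned first) and assesses significance by
#' simultaneously permuting the rows and columns of the second matrix. The
#' p-value uses the +1/+1 correction and can therefore never be zero.
#'
#' Matrices are compared raw; de-meaning ([demean_offdiag()]) is applied
#' before clustering only, not before Mantel comparison.
#'
#' @param a,b Labeled symmetric matrices over identical label sets (at
#'   least 4 labels).
#' @param n_perm Number of permutations (default 10,000; ignored when
#'   `exhaustive`).
#' @param tail `"greater"` (similarity hypothesis, default) or
#'   `"two.sided"`.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all `n!` label permutations instead of
#'   sampling (feasible for n up to about 8); the p-value is then the exact
#'   proportion of permutations (identity included) at least as extreme as
#'   the observed statistic.
#' @return Object of class `mantel_result`: `r`, `p`, `n_perm`, `tail`,
#'   `perm_r` (the permutation distribution).
#' @export
mantel <- function(a, b, n_perm = 10000, tail = c("greater", "two.sided"),
                   seed = 1, exhaustive = FALSE) {
  tail <- match.arg(tail)
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(rownames(a)) || is.null(rownames(b))) stop("matrices must be labeled")
  if (!setequal(rownames(a), rownames(b))) stop("label sets differ")
  n <- nrow(a)
  if (n < 4) stop("need at least 4 regions")
  b <- b[rownames(a), rownames(a)]
  ut <- upper.tri(a)
  av <- a[ut]
  r_obs <- stats::cor(av, b[ut])
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration is limited to 8 regions")
    perms <- all_permutations(n)
    perm_r <- vapply(perms, function(idx) stats::cor(av, b[idx, idx][ut]),
                     numeric(1))
    p <- switch(tail,
                greater = mean(perm_r >= r_obs - 1e-12),
                two.sided = mean(abs(perm_r) >= abs(r_obs) - 1e-12))
    n_perm <- length(perms)
  } else {
    perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n)
      stats::cor(av, b[idx, idx][ut])
    }, numeric(1)))
    p <- perm_p(perm_r, r_obs, tail)
  }
  structure(
    list(r = r_obs, p = p, n_perm = n_perm, tail = tail, perm_r = perm_r),
    class = "mantel_result"
  )
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1
      out[[k]] <- append(s, n, after = pos - 1)
    }
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, %s tail)\n",
              x$r, x$p, x$n_perm, x$tail))
  invisible(x)
}

#' Partition-similarity statistics
#'
#' Compares two partitions of the same region set with three statistics:
#' normalized mutual information `NMI = 2 I(p1; p2) / (H(p1) + H(p2))`
#' (natural log; 1 for identical partitions), variation of information
#' `VI = H(p1) + H(p2) - 2 I(p1; p2)` (a metric, in nats, 0 for identical
#' partitions), and the z-score of the Rand pair-counting coefficient under
#' the hypergeometric model of random partitions with fixed group sizes
#' (closed-form mean and variance). The adjusted Rand index is returned as
#' a convenience. All statistics are invariant to module relabeling.
#'
#' @param p1,p2 Partitions over the same region set.
#' @param nmi_norm Normalization for NMI: arithmetic `"mean"` of the
#'   entropies (default), `"min"`, `"max"`, or `"joint"` entropy.
#' @param vi_base `"nats"` (default) or `"bits"`.
#' @param vi_normalize Divide VI by `log(n)` (same base), mapping it to
#'   `[0, 1]` (default `FALSE`).
#' @return List with `nmi`, `vi`, `zrand`, `ari`.
#' @export
partition_metrics <- function(p1, p2, nmi_norm = c("mean", "min", "max", "joint"),
                              vi_base = c("nats", "bits"),
                              vi_normalize = FALSE) {
  nmi_norm <- match.arg(nmi_norm)
  vi_base <- match.arg(vi_base)
  p1 <- as_partition(p1); p2 <- as_partition(p2)
  if (!setequal(names(p1), names(p2))) stop("partitions cover different regions")
  p2 <- p2[names(p1)]
  n <- length(p1)
  N <- table(p1, p2)
  pj <- N / n
  p_r <- rowSums(pj); p_c <- colSums(pj)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  H1 <- h(p_r); H2 <- h(p_c); H12 <- h(as.vector(pj))
  I <- H1 + H2 - H12
  denom <- switch(nmi_norm,
                  mean = (H1 + H2) / 2,
                  min = min(H1, H2),
                  max = max(H1, H2),
                  joint = H12)
  # both entropies zero <=> both partitions are the single trivial module,
  # hence identical
  nmi <- if (denom <= .Machine$double.eps) 1 else I / denom
  vi <- H1 + H2 - 2 * I
  if (vi_base == "bits") vi <- vi / log(2)
  if (vi_normalize) vi <- vi / (log(n) / if (vi_base == "bits") log(2) else 1)
  list(nmi = nmi, vi = max(vi, 0), zrand = zrand_score(N),
       ari = adjusted_rand(N))
}

# z-score of the Rand pair count w under the hypergeometric model with fixed
# marginals: z = (w - M1*M2/M) / sd(w), with the closed-form variance of the
# pair count.
zrand_score <- function(N) {
  n <- sum(N)
  if (n < 4) stop("zRand needs at least 4 elements")
  M <- n * (n - 1) / 2
  n1 <- rowSums(N); n2 <- colSums(N)
  M1 <- sum(choose(n1, 2)); M2 <- sum(choose(n2, 2))
  w <- sum(choose(N, 2))
  muw <- M1 * M2 / M
  C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * sum(n1^3)
  C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * sum(n2^3)
  vw <- M / 16 -
    (4 * M1 - 2 * M)^2 * (4 * M2 - 2 * M)^2 / (256 * M^2) +
    C1 * C2 / (16 * n * (n - 1) * (n - 2)) +
    ((4 * M1 - 2 * M)^2 - 4 * C1 - 4 * M) *
    ((4 * M2 - 2 * M)^2 - 4 * C2 - 4 * M) /
    (64 * n * (n - 1) * (n - 2) * (n - 3))
  if (vw <= 0) return(NA_real_)
  (w - muw) / sqrt(vw)
}

adjusted_rand <- function(N) {
  n <- sum(N)
  sum_ij <- sum(choose(N, 2))
  sum_i <- sum(choose(rowSums(N), 2))
  sum_j <- sum(choose(colSums(N), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  maxval <- (sum_i + sum_j) / 2
  if (maxval == expected) return(1)
  (sum_ij - expected) / (maxval - expected)
}

#' Intra- versus extra-cluster correlation contrast
#'
#' Tests whether the mean correlation among regions inside a cluster
#' exceeds the mean correlation between in-cluster and out-of-cluster
#' regions, by a pooled-variance two-sample Student's t-test, one-tailed
#' (intra greater). Intra pairs are pairs strictly inside the cluster;
#' extra pairs have exactly one member inside.
#'
#' @param m Labeled symmetric correlation matrix.
#' @param p Partition over the matrix labels.
#' @param cluster_id Module id to contrast.
#' @param fisher_z Apply the Fisher z-transform (`atanh`) to correlations
#'   before the t-test (default `FALSE`).
#' @return List of class `cluster_contrast`: `cluster_id`, `r_i`, `r_e`,
#'   `t`, `df`, `p`, and `n_i`/`n_e` pair counts.
#' @export
intra_extra_test <- function(m, p, cluster_id, fisher_z = FALSE) {
  p <- align_partition_labels(p, m)
  members <- names(p)[p == cluster_id]
  if (length(members) < 2) stop("cluster ", cluster_id,
                                " has fewer than 2 members; contrast undefined")
  if (length(members) >= nrow(m)) stop("cluster covers all regions")
  inside <- rownames(m) %in% members
  intra <- m[inside, inside, drop = FALSE]
  intra <- intra[upper.tri(intra)]
  extra <- as.vector(m[inside, !inside, drop = FALSE])
  r_i <- mean(intra); r_e <- mean(extra)
  xi <- if (fisher_z) atanh(pmin(pmax(intra, -1 + 1e-12), 1 - 1e-12)) else intra
  xe <- if (fisher_z) atanh(pmin(pmax(extra, -1 + 1e-12), 1 - 1e-12)) else extra
  if (length(xi) < 2 && length(xe) < 2) stop("not enough pairs for a t-test")
  df <- length(xi) + length(xe) - 2
  pooled_var <- (sum((xi - mean(xi))^2) + sum((xe - mean(xe))^2)) / df
  if (pooled_var <= .Machine$double.eps^2) {
    # degenerate: both groups (essentially) constant
    t_stat <- if (abs(mean(xi) - mean(xe)) < 1e-14) 0 else
      sign(mean(xi) - mean(xe)) * Inf
    p <- stats::pt(t_stat, df, lower.tail = FALSE)
  } else {
    tt <- stats::t.test(xi, xe, var.equal = TRUE, alternative = "greater")
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(
    list(cluster_id = cluster_id, r_i = r_i, r_e = r_e,
         t = t_stat, df = df, p = p,
         n_i = length(intra), n_e = length(extra)),
    class = "cluster_contrast"
  )
}

#' @export
print.cluster_contrast <- function(x, ...) {
  cat(sprintf(
    "Cluster %s: r_i = %.3f (%d pairs), r_e = %.3f (%d pairs), t(%d) = %.2f, one-tailed p = %.3g\n",
    x$cluster_id, x$r_i, x$n_i, x$r_e, x$n_e, x$df, x$t, x$p))
  invisible(x)
}

#' Contrast every non-singleton cluster of a partition
#'
#' @inheritParams intra_extra_test
#' @return Data frame with one row per cluster having at least two members
#'   and at least one non-member.
#' @export
cluster_contrast_table <- function(m, p, fisher_z = FALSE) {
  p <- align_partition_labels(p, m)
  ids <- sort(unique(p))
  rows <- lapply(ids, function(id) {
    if (sum(p == id) < 2 || sum(p == id) >= length(p)) return(NULL)
    ct <- intra_extra_test(m, p, id, fisher_z = fisher_z)
    data.frame(cluster = id, r_i = ct$r_i, r_e = ct$r_e, t = ct$t,
               df = ct$df, p = ct$p)
  })
  do.call(rbind, rows)
}
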