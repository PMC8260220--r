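# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive independent sub-seeds from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' Degree-preserving rewiring of a signed network
#'
#' Randomizes a signed weighted undirected network while preserving, for
#' every node, the number of positive and of negative incident edges, and
#' preserving the multiset of edge weights exactly. Each attempted swap
#' selects four distinct nodes a, b, c, d and exchanges the weights of the
#' pairs (a,b)/(a,d) and (c,d)/(c,b) when the two edge pairs carry the same
#' sign within pair and opposite signs across pairs, so weights travel with
#' their edges between positions of compatible sign. On a complete signed
#' matrix (no zero entries) this reduces to sign-stratified shuffling of
#' weights; on sparse matrices the zero "sign class" participates and edges
#' genuinely move.
#'
#' @param w Labeled symmetric matrix, zero diagonal (enforced).
#' @param swaps_per_edge Target number of successful swaps per edge
#'   (default 5); total attempts are `swaps_per_edge` times the number of
#'   nonzero edges, each retried a bounded number of times.
#' @param seed Integer seed.
#' @return Rewired labeled symmetric matrix with zero diagonal.
#' @export
rewire_signed <- function(w, swaps_per_edge = 5, seed = 1) {
  R <- as.matrix(w)
  diag(R) <- 0
  n <- nrow(R)
  if (n < 4) stop("need at least 4 nodes to rewire")
  n_edges <- sum(R[upper.tri(R)] != 0)
  n_swaps <- swaps_per_edge * max(n_edges, 1L)
  max_attempts <- ceiling(n / 2)
  with_seed(seed, {
    for (it in seq_len(n_swaps)) {
      for (att in seq_len(max_attempts)) {
        nodes <- sample.int(n, 4)
        a <- nodes[1]; b <- nodes[2]; c <- nodes[3]; d <- nodes[4]
        r_ab <- R[a, b]; r_cd <- R[c, d]
        r_ad <- R[a, d]; r_cb <- R[c, b]
        if (sign(r_ab) == sign(r_cd) && sign(r_ad) == sign(r_cb) &&
            sign(r_ab) != sign(r_ad)) {
          R[a, d] <- r_ab; R[d, a] <- r_ab
          R[a, b] <- r_ad; R[b, a] <- r_ad
          R[c, b] <- r_cd; R[b, c] <- r_cd
          R[c, d] <- r_cb; R[d, c] <- r_cb
          break
        }
      }
    }
  })
  labeled_matrix(R, rownames(w), tol = 0)
}

new_null_test <- function(observed, null_samples, p, tail, metric = "Q") {
  structure(
    list(observed = observed, null_samples = null_samples, p = p,
         percentile_band = stats::quantile(null_samples, c(0.025, 0.975),
                                           names = FALSE),
         tail = tail, metric = metric, n_null = length(null_samples)),
    class = "null_test"
  )
}

#' @export
print.null_test <- function(x, ...) {
  cat(sprintf(
    "Permutation null test (%s, %s tail)\n  observed = %.4f\n  null 2.5-97.5%% = [%.4f, %.4f]\n  p = %.4g (n_null = %d)\n",
    x$metric, x$tail, x$observed, x$percentile_band[1], x$percentile_band[2],
    x$p, x$n_null))
  invisible(x)
}

# +1/+1-corrected permutation p-value; never zero.
perm_p <- function(null, observed, tail) {
  n <- length(null)
  switch(tail,
         greater = (sum(null >= observed) + 1) / (n + 1),
         less = (sum(null <= observed) + 1) / (n + 1),
         two.sided = (sum(abs(null) >= abs(observed)) + 1) / (n + 1),
         stop("unknown tail: ", tail))
}

#' Modularity significance against rewired networks
#'
#' Compares the modularity of the modal partition of `w` with the
#' modularity obtained on networks rewired to preserve the signed degree
#' distribution ([rewire_signed()]). The null hypothesis is that the
#' observed community structure is no stronger than expected from the
#' network's signed degree sequence and weight distribution.
#'
#' @inheritParams louvain_signed
#' @param n_null Number of rewired networks (default 10,000).
#' @param runs_per_null Louvain runs per null network; the best modularity
#'   over the runs is kept (default 1).
#' @param modal_runs Louvain runs for the observed modal partition
#'   (default 10,000).
#' @param swaps_per_edge Rewiring intensity (default 5).
#' @return A `null_test` object (observed Q, null samples, right-tailed p,
#'   2.5/97.5 percentile band).
#' @export
q_null_test <- function(w, gamma = 1, n_null = 10000, runs_per_null = 1,
                        seed = 1, modal_runs = 10000, swaps_per_edge = 5) {
  stopifnot(n_null >= 1)
  p_obs <- modal_partition(w, gamma, n_runs = modal_runs, seed = seed)
  q_obs <- modularity_signed(w, p_obs, gamma)
  seeds <- derive_seeds(seed, 2L * n_null)
  null_q <- vapply(seq_len(n_null), function(k) {
    wr <- rewire_signed(w, swaps_per_edge, seed = seeds[2 * k - 1])
    max(vapply(seq_len(runs_per_null), function(r) {
      louvain_signed(wr, gamma, seed = seeds[2 * k] + r - 1L)$q
    }, numeric(1)))
  }, numeric(1))
  res <- new_null_test(q_obs, null_q, perm_p(null_q, q_obs, "greater"),
                       "greater", metric = "Q")
  res$partition <- p_obs
  res
}

#' Partition-similarity significance against rewired networks
#'
#' Tests whether a reference partition (e.g., the developmental cluster
#' solution) is more similar to the community structure of another matrix
#' than to the community structure of networks rewired from that matrix
#' with preserved signed degree distribution. Similarity is measured by
#' NMI, VI or the z-scored Rand coefficient (see [partition_metrics()]);
#' for VI, *lower* values mean more similar, so the test is left-tailed.
#'
#' @param p_ref Reference partition.
#' @param w_other Labeled symmetric matrix over the same region set.
#' @param metric One of `"nmi"`, `"vi"`, `"zrand"`.
#' @inheritParams q_null_test
#' @param tail `"auto"` (right for nmi/zrand, left for vi) or an explicit
#'   tail.
#' @return A `null_test` object; `observed` is the metric between `p_ref`
#'   and the modal partition of `w_other`.
#' @export
partition_null_test <- function(p_ref, w_other, metric = c("nmi", "vi", "zrand"),
                                gamma = 1, n_null = 10000, seed = 1,
                                modal_runs = 10000, runs_per_null = 1,
                                swaps_per_edge = 5,
                                tail = c("auto", "greater", "less", "two.sided")) {
  metric <- match.arg(metric)
  tail <- match.arg(tail)
  if (tail == "auto") tail <- if (metric == "vi") "less" else "greater"
  p_ref <- align_partition_labels(p_ref, w_other)
  p_obs <- modal_partition(w_other, gamma, n_runs = modal_runs, seed = seed)
  obs <- partition_metrics(p_ref, p_obs)[[metric]]
  seeds <- derive_seeds(seed + 1L, 2L * n_null)
  null_m <- vapply(seq_len(n_null), function(k) {
    wr <- rewire_signed(w_other, swaps_per_edge, seed = seeds[2 * k - 1])
    pr <- louvain_signed(wr, gamma, seed = seeds[2 * k])$partition
    partition_metrics(p_ref, pr)[[metric]]
  }, numeric(1))
  new_null_test(obs, null_m, perm_p(null_m, obs, tail), tail, metric = metric)
}
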