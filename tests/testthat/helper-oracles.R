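# Independent oracles and small constructed fixtures shared across tests.

# All set partitions of n elements as restricted-growth strings.
enum_partitions <- function(n) {
  res <- list()
  rec <- function(pref, m) {
    if (length(pref) == n) {
      res[[length(res) + 1]] <<- pref
      return()
    }
    for (v in 1:(m + 1)) rec(c(pref, v), max(m, v))
  }
  rec(1L, 1L)
  res
}

# Direct evaluation of the asymmetric signed modularity formula with plain
# loops; independent of the package's gain-matrix implementation.
modularity_oracle <- function(w, p, gamma = 1) {
  w <- as.matrix(w)
  diag(w) <- 0
  n <- nrow(w)
  q_sign <- function(ws) {
    v <- sum(ws)
    if (v == 0) return(0)
    s <- unname(rowSums(ws))
    acc <- 0
    for (i in 1:n) {
      for (j in 1:n) {
        if (p[i] == p[j]) acc <- acc + ws[i, j] - gamma * s[i] * s[j] / v
      }
    }
    acc / v
  }
  wp <- pmax(w, 0)
  wn <- pmax(-w, 0)
  vp <- sum(wp); vn <- sum(wn)
  qp <- q_sign(wp); qn <- q_sign(wn)
  if (vp + vn == 0) return(0)
  qp - vn / (vp + vn) * qn
}

random_signed_matrix <- function(n, seed, lo = -1, hi = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2, lo, hi)
  w <- w + t(w)
  dimnames(w) <- list(letters[1:n], letters[1:n])
  w
}

# Block matrix with explicit within/between weights (zero diagonal).
block_matrix <- function(sizes, within = 0.8, between = -0.3,
                         labels = NULL) {
  n <- sum(sizes)
  if (is.null(labels)) labels <- paste0("r", seq_len(n))
  blocks <- rep(seq_along(sizes), sizes)
  w <- ifelse(outer(blocks, blocks, "=="), within, between)
  diag(w) <- 0
  dimnames(w) <- list(labels, labels)
  attr(w, "blocks") <- stats::setNames(blocks, labels)
  w
}

# Small constructed cohort: 3 subjects x 2 sessions over the canonical
# regions, volumes chosen so change values are easy to reason about.
make_toy_cohort <- function() {
  labels <- region_labels()
  k <- length(labels)
  base <- matrix(rep(seq(1000, 4000, length.out = k), each = 6), 6, k)
  colnames(base) <- labels
  growth <- rep(c(1.00, 1.02), 3)  # +2% raw at follow-up
  vols <- base * growth
  df <- data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 2),
    session = rep(1:2, 3),
    age = c(6, 8, 10, 11.5, 14, 17),
    sex = rep(c("F", "M", "F"), each = 2),
    site = "siteA",
    icv = 1.4e6,
    vols, check.names = FALSE, stringsAsFactors = FALSE
  )
  as_cohort(df)
}

# Best relabeling overlap by brute force over all label permutations
# (oracle for the Hungarian alignment).
brute_best_overlap <- function(run, ref) {
  k <- max(max(run), max(ref))
  perms <- covchange:::all_permutations(k)
  best <- -1
  for (pm in perms) {
    ov <- sum(pm[run] == ref)
    if (ov > best) best <- ov
  }
  best
}

# Best Louvain quality over restarts (the algorithm is a greedy heuristic;
# operationally it is always run many times, as in modal_partition).
best_louvain_q <- function(w, gamma = 1, seeds = 1:25) {
  max(vapply(seeds, function(s) louvain_signed(w, gamma, seed = s)$q,
             numeric(1)))
}

# Random partition of n items into at most k modules, canonicalized.
random_partition <- function(n, k, labels = letters[1:n]) {
  as_partition(stats::setNames(sample.int(k, n, replace = TRUE), labels))
}
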