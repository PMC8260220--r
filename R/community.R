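#' Partitions of the region set
#'
#' A partition is a named integer vector mapping each region label to a
#' module id. Module ids are canonicalized to `1..k` in order of first
#' appearance, so two partitions that differ only by module relabeling have
#' identical canonical forms only if the relabeling respects first-appearance
#' order; comparisons should use [partition_metrics()], which is label
#' invariant.
#'
#' @param x Named vector (or factor) of module assignments.
#' @return Named integer vector with module ids `1..k`.
#' @export
as_partition <- function(x) {
  labels <- names(x)
  if (is.null(labels)) stop("partition must be named by region label")
  ids <- as.integer(factor(as.vector(unlist(x)), levels = unique(as.vector(unlist(x)))))
  stats::setNames(ids, labels)
}

#' @rdname as_partition
#' @param p Partition.
#' @return `n_modules`: the number of modules `k`.
#' @export
n_modules <- function(p) max(as_partition(p))

# Split w into positive part, magnitude of negative part; force zero diagonal.
signed_parts <- function(w) {
  w <- as.matrix(w)
  diag(w) <- 0
  list(pos = pmax(w, 0), neg = pmax(-w, 0))
}

# Generalized (signed, asymmetric) modularity gain matrix M such that
# Q(partition) = sum of M over all within-module (i, j) pairs, diagonal
# included. Positive weights contribute at full weight 1/v+; negative
# weights are down-weighted by v-/(v+ + v-), i.e. M gets 1/(v+ + v-).
gain_matrix <- function(w, gamma = 1) {
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  parts <- signed_parts(w)
  n <- nrow(parts$pos)
  M <- matrix(0, n, n, dimnames = dimnames(w))
  vp <- sum(parts$pos); vn <- sum(parts$neg)
  if (vp > 0) {
    sp <- rowSums(parts$pos)
    M <- M + (parts$pos - gamma * tcrossprod(sp) / vp) / vp
  }
  if (vn > 0) {
    sn <- rowSums(parts$neg)
    M <- M - (parts$neg - gamma * tcrossprod(sn) / vn) / (vp + vn)
  }
  M
}

#' Signed modularity of a partition
#'
#' Quality `Q` of a partition of a signed weighted network, with asymmetric
#' treatment of negative weights: `Q = Q+ - v- / (v+ + v-) * Q-`, where for
#' each sign `s`, `Qs = (1/vs) * sum_ij (ws_ij - gamma * ss_i * ss_j / vs)`
#' over within-module pairs, `ws` is the positive part (or magnitude of the
#' negative part) of the weights, `ss_i` the corresponding node strength and
#' `vs` the total strength. Positive within-module weight counts in full;
#' sparing negative weight inside modules is rewarded only in proportion to
#' the negative share of total strength. `Q` lies in `[-1, 1]`; the trivial
#' all-in-one partition has `Q = 0` exactly at `gamma = 1`.
#'
#' The diagonal of `w` is forced to zero (self-weights are excluded from
#' clustering throughout the package).
#'
#' @param w Labeled symmetric matrix of signed weights.
#' @param p Partition over the same labels.
#' @param gamma Resolution parameter (> 0); larger values favor more, smaller
#'   modules.
#' @return Scalar `Q`.
#' @export
modularity_signed <- function(w, p, gamma = 1) {
  p <- align_partition_labels(p, w)
  M <- gain_matrix(w, gamma)
  same <- outer(p, p, "==")
  sum(M[same])
}

# Reorder a partition to a matrix's label order, validating the label sets.
align_partition_labels <- function(p, w) {
  p <- as_partition(p)
  labels <- rownames(w)
  if (is.null(labels)) {
    if (length(p) != nrow(w)) stop("partition length does not match matrix")
    return(p)
  }
  if (!setequal(names(p), labels)) stop("partition labels do not match matrix")
  p[labels]
}

#' Louvain community detection on a signed network
#'
#' Greedy two-phase Louvain optimization of the signed asymmetric modularity
#' (see [modularity_signed()]). The node sweep order is shuffled by `seed`;
#' different seeds can return different local optima on ambiguous networks,
#' which is why [modal_partition()] and [consensus_partition()] aggregate
#' many runs.
#'
#' @inheritParams modularity_signed
#' @param seed Integer seed controlling the sweep order.
#' @return List with `partition` (named integer vector) and `q` (its signed
#'   modularity).
#' @export
louvain_signed <- function(w, gamma = 1, seed = 1) {
  M <- gain_matrix(w, gamma)
  comm <- .louvain_once_cpp(M, as.integer(seed))
  p <- as_partition(stats::setNames(comm, rownames(w)))
  list(partition = p, q = modularity_signed(w, p, gamma))
}

# Relabel a run's modules to maximize overlap with a reference partition.
# Overlap matching is solved exactly (Hungarian assignment on negated
# overlap counts); run modules with no matched reference module keep a
# fresh label.
align_to_reference <- function(run, ref) {
  k <- max(max(run), max(ref))
  overlap <- matrix(0, k, k)
  for (i in seq_along(run)) {
    overlap[run[i], ref[i]] <- overlap[run[i], ref[i]] + 1
  }
  match <- .assignment_cpp(-overlap)
  match[run]
}

#' Modal partition across many Louvain runs
#'
#' Runs the Louvain algorithm `n_runs` times with seeded sweep orders,
#' aligns each run's arbitrary module labels to the first run by
#' maximal-overlap (Hungarian) matching, and assigns each region to the
#' module it is most often associated with (the per-node mode; ties break to
#' the smallest module label). A warning is issued when any region's modal
#' frequency falls below 0.5, signalling an ambiguous assignment.
#'
#' @inheritParams louvain_signed
#' @param n_runs Number of Louvain runs (default 10,000).
#' @return Partition with attributes `modal_freq` (per-region modal
#'   frequency) and `n_runs`.
#' @export
modal_partition <- function(w, gamma = 1, n_runs = 10000, seed = 1) {
  stopifnot(n_runs >= 1)
  M <- gain_matrix(w, gamma)
  runs <- .louvain_runs_cpp(M, as.integer(n_runs), as.integer(seed))
  ref <- runs[1, ]
  aligned <- t(apply(runs, 1, align_to_reference, ref = ref))
  n <- ncol(aligned)
  modal <- integer(n)
  freq <- numeric(n)
  for (i in seq_len(n)) {
    counts <- tabulate(aligned[, i])
    modal[i] <- which.max(counts)
    freq[i] <- counts[modal[i]] / n_runs
  }
  if (any(freq < 0.5)) {
    warning("ambiguous modal assignment: region(s) ",
            paste(rownames(w)[freq < 0.5], collapse = ", "),
            " have modal frequency < 0.5")
  }
  p <- as_partition(stats::setNames(modal, rownames(w)))
  attr(p, "modal_freq") <- stats::setNames(freq, rownames(w))
  attr(p, "n_runs") <- n_runs
  p
}

#' Consensus partition
#'
#' Consensus clustering: `n_runs` Louvain runs produce an agreement matrix
#' `A_ij` (the fraction of runs co-assigning regions i and j); entries below
#' `tau` are zeroed and the thresholded agreement matrix is itself
#' reclustered by `n_runs` Louvain runs, iterating until every run returns
#' one identical partition (the agreement matrix is then binary and
#' block-diagonal). The agreement matrix is reclustered at resolution 1
#' regardless of `gamma`, which applies to the original weights only.
#'
#' @inheritParams modal_partition
#' @param tau Agreement threshold in (0, 1) (default 0.5).
#' @param max_iter Iteration cap (default 100); non-convergence is an error.
#' @return List with `partition`, `agreement` (the final, binary agreement
#'   matrix) and `iterations`.
#' @export
consensus_partition <- function(w, gamma = 1, n_runs = 1000, tau = 0.5,
                                seed = 1, max_iter = 100) {
  if (tau <= 0 || tau >= 1) stop("tau must lie strictly between 0 and 1")
  labels <- rownames(w)
  M <- gain_matrix(w, gamma)
  for (iter in seq_len(max_iter)) {
    res <- .louvain_coassign_cpp(M, as.integer(n_runs),
                                 as.integer(seed) + 7919L * iter)
    A <- res$counts / n_runs
    dimnames(A) <- list(labels, labels)
    # all runs identical <=> every co-assignment frequency is 0 or 1
    if (all(A %in% c(0, 1))) {
      p <- as_partition(stats::setNames(
        match(apply(A > 0.5, 1, paste, collapse = ""),
              unique(apply(A > 0.5, 1, paste, collapse = ""))), labels))
      diag(A) <- 1
      return(list(partition = p, agreement = labeled_matrix(A, labels),
                  iterations = iter))
    }
    A[A < tau] <- 0
    diag(A) <- 0
    M <- gain_matrix(A, 1)
  }
  stop("consensus clustering did not converge within ", max_iter, " iterations")
}

#' Versatility curve over a resolution grid
#'
#' For each resolution `gamma` on the grid, runs the Louvain algorithm
#' `runs` times and measures how ambiguously each region affiliates with a
#' module: region i's versatility is the mean over partners j of
#' `sin(pi * P_ij)`, where `P_ij` is the co-assignment frequency across
#' runs. Versatility is 0 exactly when every co-assignment frequency is 0 or
#' 1 (a fully stable decomposition) and maximal (1) for a partner co-assigned
#' in half of the runs. Local minima of the mean versatility over the grid
#' flag candidate resolutions at which the decomposition is least ambiguous;
#' plateaus are reported at their left-most grid point.
#'
#' @inheritParams louvain_signed
#' @param gamma_min,gamma_max,step Resolution grid (defaults 0.01 to 4.00 in
#'   steps of 0.01).
#' @param runs Louvain runs per grid point (default 1000).
#' @return List of class `versatility_curve` with `gammas`,
#'   `mean_versatility`, `per_node` (region x gamma matrix), `mean_k` (mean
#'   module count per gamma, for flagging degenerate resolutions) and
#'   `local_minima` (data frame of gamma and versatility value).
#' @export
versatility_curve <- function(w, gamma_min = 0.01, gamma_max = 4.00,
                              step = 0.01, runs = 1000, seed = 1) {
  if (gamma_max < gamma_min || step <= 0) stop("empty gamma grid")
  gammas <- seq(gamma_min, gamma_max, by = step)
  n <- nrow(w)
  labels <- rownames(w)
  per_node <- matrix(NA_real_, n, length(gammas),
                     dimnames = list(labels, NULL))
  mean_k <- numeric(length(gammas))
  for (g in seq_along(gammas)) {
    M <- gain_matrix(w, gammas[g])
    res <- .louvain_coassign_cpp(M, as.integer(runs),
                                 as.integer(seed) + 104729L * g)
    per_node[, g] <- versatility_from_coassign(res$counts / runs)
    mean_k[g] <- mean(res$k)
  }
  mean_v <- colMeans(per_node)
  out <- list(gammas = gammas, mean_versatility = mean_v,
              per_node = per_node, mean_k = mean_k,
              local_minima = grid_local_minima(gammas, mean_v))
  class(out) <- "versatility_curve"
  out
}

# Per-node versatility from a co-assignment frequency matrix: node i's value
# is the mean over partners j of sin(pi * P_ij), zero iff P is binary and
# maximal (1) when a partner is co-assigned in exactly half the runs.
versatility_from_coassign <- function(P) {
  n <- nrow(P)
  S <- sin(pi * P)
  S[P == 0 | P == 1] <- 0   # exact zero at binary frequencies (sin(pi*1)
                            # is otherwise ~1e-16 in floating point)
  diag(S) <- 0
  rowSums(S) / (n - 1)
}

# Interior local minima on a grid, collapsing plateaus to their left-most
# point: a candidate's value must be <= the nearest differing values on both
# sides.
grid_local_minima <- function(x, v) {
  n <- length(v)
  if (n < 3) return(data.frame(gamma = numeric(0), versatility = numeric(0)))
  keep <- c(TRUE, diff(v) != 0)       # left-most point of each plateau
  idx <- which(keep)
  vals <- v[idx]
  m <- length(vals)
  is_min <- logical(m)
  if (m >= 3) is_min[2:(m - 1)] <- vals[2:(m - 1)] <= vals[1:(m - 2)] &
    vals[2:(m - 1)] <= vals[3:m]
  sel <- idx[is_min]
  sel <- sel[sel > 1 & sel < n]
  data.frame(gamma = x[sel], versatility = v[sel])
}
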