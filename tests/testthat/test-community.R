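test_that("signed modularity matches the direct-formula oracle", {
  for (s in 1:10) {
    n <- 5 + (s %% 4)
    w <- random_signed_matrix(n, s)
    set.seed(s)
    p <- random_partition(n, 3, labels = rownames(w))
    expect_equal(modularity_signed(w, p), modularity_oracle(w, p),
                 tolerance = 1e-12)
    expect_equal(modularity_signed(w, p, gamma = 1.7),
                 modularity_oracle(w, p, gamma = 1.7), tolerance = 1e-12)
  }
})

test_that("all-in-one partition has exactly zero modularity at gamma 1", {
  for (s in 1:8) {
    w <- random_signed_matrix(4 + s, s)
    p <- as_partition(stats::setNames(rep(1, nrow(w)), rownames(w)))
    expect_lt(abs(modularity_signed(w, p, gamma = 1)), 1e-12)
  }
})

test_that("two disjoint positive triangles give Q = 0.5", {
  w <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  w[1, 2] <- w[2, 3] <- w[1, 3] <- 1
  w[4, 5] <- w[5, 6] <- w[4, 6] <- 1
  w <- w + t(w)
  p <- stats::setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  expect_equal(modularity_signed(w, p, gamma = 1), 0.5, tolerance = 1e-12)
})

test_that("purely negative graph favors singletons with small positive Q", {
  n <- 5
  w <- matrix(-0.4, n, n)
  diag(w) <- 0
  dimnames(w) <- list(letters[1:n], letters[1:n])
  p <- as_partition(stats::setNames(1:n, letters[1:n]))
  q <- modularity_signed(w, p, gamma = 1)
  expect_equal(q, modularity_oracle(w, p), tolerance = 1e-14)
  expect_gt(q, 0)
  expect_lt(q, 0.5)
})

test_that("positive-weight signed modularity reduces to Newman-Girvan", {
  library(igraph)
  for (s in 1:20) {
    n <- 6 + (s %% 5)
    w <- abs(random_signed_matrix(n, 300 + s))
    set.seed(s)
    p <- random_partition(n, 3, labels = rownames(w))
    g <- graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
    expect_equal(modularity_signed(w, p, gamma = 1),
                 modularity(g, membership = p, weights = E(g)$weight),
                 tolerance = 1e-10)
  }
})

test_that("Louvain attains the exhaustive maximum on small signed graphs", {
  # planted 2-block example plus random signed instances
  w <- block_matrix(c(4, 4), within = 0.8, between = -0.3)
  parts <- enum_partitions(8)
  qs <- vapply(parts, function(p)
    modularity_signed(w, stats::setNames(p, rownames(w))), numeric(1))
  res <- louvain_signed(w, seed = 1)
  expect_equal(res$q, max(qs), tolerance = 1e-10)
  expect_equal(partition_metrics(res$partition,
                                 attr(w, "blocks"))$ari, 1)

  for (s in 1:8) {
    n <- 5 + (s %% 4)
    w <- random_signed_matrix(n, 500 + s)
    parts <- enum_partitions(n)
    qmax <- max(vapply(parts, function(p)
      modularity_signed(w, stats::setNames(p, rownames(w))), numeric(1)))
    expect_equal(best_louvain_q(w), qmax, tolerance = 1e-10)
  }
})

test_that("uniform positive complete graph yields a single module", {
  w <- matrix(1, 7, 7)
  diag(w) <- 0
  dimnames(w) <- list(letters[1:7], letters[1:7])
  res <- louvain_signed(w, seed = 2)
  expect_equal(n_modules(res$partition), 1)
  expect_equal(res$q, 0, tolerance = 1e-12)
})

test_that("returned Q matches modularity of the returned partition", {
  for (s in 1:5) {
    w <- random_signed_matrix(10, 40 + s)
    res <- louvain_signed(w, gamma = 1.3, seed = s)
    expect_equal(res$q, modularity_signed(w, res$partition, 1.3),
                 tolerance = 1e-12)
  }
})

test_that("partitions are equivariant under region relabeling", {
  w <- block_matrix(c(3, 3, 4), within = 0.7, between = -0.2)
  res <- louvain_signed(w, seed = 5)
  perm <- c(7, 2, 9, 1, 10, 4, 3, 8, 5, 6)
  wp <- w[perm, perm]
  resp <- louvain_signed(wp, seed = 5)
  expect_equal(resp$q, res$q, tolerance = 1e-12)
  expect_equal(partition_metrics(res$partition, resp$partition)$ari, 1)
})

test_that("Hungarian label alignment equals brute-force matching", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    run <- sample.int(4, n, replace = TRUE)
    ref <- sample.int(4, n, replace = TRUE)
    run <- as.integer(factor(run, levels = unique(run)))
    ref <- as.integer(factor(ref, levels = unique(ref)))
    aligned <- covchange:::align_to_reference(run, ref)
    expect_equal(sum(aligned == ref), brute_best_overlap(run, ref))
    # alignment only relabels: same partition
    expect_equal(as.integer(factor(aligned, levels = unique(aligned))),
                 as.integer(factor(run, levels = unique(run))))
  }
})

test_that("modal partition is stable on strong structure", {
  w <- block_matrix(c(4, 4), within = 0.8, between = -0.3)
  ref <- louvain_signed(w, seed = 9)$partition
  mp1 <- modal_partition(w, n_runs = 300, seed = 1)
  mp2 <- modal_partition(w, n_runs = 300, seed = 77)
  expect_equal(partition_metrics(mp1, ref)$ari, 1)
  expect_equal(partition_metrics(mp1, mp2)$ari, 1)
  expect_true(all(attr(mp1, "modal_freq") == 1))
})

test_that("ambiguous assignments trigger the modal warning", {
  # a node tied equally to three strong triangles is assigned each of them
  # in roughly a third of runs
  labs <- c(paste0("a", 1:3), paste0("b", 1:3), paste0("c", 1:3), "x")
  w <- matrix(0, 10, 10, dimnames = list(labs, labs))
  for (g in c("a", "b", "c")) {
    for (i in 1:2) for (j in (i + 1):3) {
      w[paste0(g, i), paste0(g, j)] <- w[paste0(g, j), paste0(g, i)] <- 1
    }
    w[paste0(g, 1), "x"] <- w["x", paste0(g, 1)] <- 0.5
  }
  expect_warning(p <- modal_partition(w, n_runs = 99, seed = 3),
                 "ambiguous modal assignment.*x")
  expect_length(p, 10)
  expect_lt(attr(p, "modal_freq")["x"], 0.5)
})

test_that("consensus converges immediately on deterministic structure", {
  w <- block_matrix(c(4, 4), within = 0.8, between = -0.3)
  res <- consensus_partition(w, n_runs = 100, seed = 4)
  expect_equal(res$iterations, 1)
  expect_equal(partition_metrics(res$partition,
                                 louvain_signed(w, seed = 1)$partition)$ari, 1)
  A <- res$agreement
  expect_true(all(A %in% c(0, 1)))
  same <- outer(res$partition, res$partition, "==")
  expect_equal(unname(A[rownames(same), colnames(same)] == 1),
               unname(same))
})

test_that("consensus recovers a planted five-block matrix across seeds", {
  w <- block_matrix(c(4, 3, 3, 3, 3), within = 0.8, between = -0.2)
  truth <- attr(w, "blocks")
  hits <- 0
  for (s in 1:50) {
    res <- consensus_partition(w, n_runs = 60, seed = s)
    hits <- hits + (partition_metrics(res$partition, truth)$ari == 1)
  }
  expect_equal(hits, 50)
})

test_that("versatility is exactly zero for stable decompositions", {
  w <- block_matrix(c(3, 3), within = 0.9, between = -0.4)
  vc <- versatility_curve(w, gamma_min = 0.9, gamma_max = 1.1, step = 0.1,
                          runs = 200, seed = 6)
  expect_identical(unname(vc$mean_versatility), rep(0, 3))
  expect_true(all(vc$per_node == 0))
})

test_that("versatility kernel: half-frequency co-assignment contributes one", {
  P <- diag(1, 3)
  P[1, 2] <- P[2, 1] <- 0.5
  v <- covchange:::versatility_from_coassign(P)
  expect_equal(v[1], 0.5)          # one partner at sin(pi/2)=1, one at 0
  expect_equal(v[3], 0)
  binary <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  expect_identical(covchange:::versatility_from_coassign(binary),
                   rep(0, 3))
  # bounded in [0, 1] for arbitrary frequency matrices
  set.seed(2)
  Q <- matrix(runif(25), 5, 5)
  Q <- (Q + t(Q)) / 2
  vv <- covchange:::versatility_from_coassign(Q)
  expect_true(all(vv >= 0 & vv <= 1))
})

test_that("maximally ambiguous ring splits co-assignment at one half", {
  labs <- letters[1:4]
  w <- matrix(0, 4, 4, dimnames = list(labs, labs))
  w["a", "b"] <- w["b", "a"] <- 1; w["c", "d"] <- w["d", "c"] <- 1
  w["b", "c"] <- w["c", "b"] <- 1; w["d", "a"] <- w["a", "d"] <- 1
  vc <- versatility_curve(w, gamma_min = 1, gamma_max = 1, step = 1,
                          runs = 4000, seed = 5)
  # each node pairs with either neighbor in ~half the runs: versatility
  # (sin(pi/2) + sin(pi/2) + 0) / 3 = 2/3
  expect_equal(unname(vc$mean_versatility), 2 / 3, tolerance = 0.02)
})

test_that("local minima are interior with plateaus reported leftmost", {
  lm1 <- covchange:::grid_local_minima(1:7 / 10,
                                       c(3, 1, 2, 2, 1, 1, 5))
  expect_equal(lm1$gamma, c(0.2, 0.5))
  # boundary values are never minima
  lm2 <- covchange:::grid_local_minima(1:4 / 10, c(0, 1, 2, 3))
  expect_equal(nrow(lm2), 0)
})

test_that("gamma controls resolution monotonically on average", {
  w <- block_matrix(c(4, 4, 4), within = 0.7, between = -0.1)
  vc <- versatility_curve(w, gamma_min = 0.5, gamma_max = 3, step = 0.5,
                          runs = 100, seed = 8)
  expect_lte(vc$mean_k[1], vc$mean_k[length(vc$mean_k)])
  expect_error(versatility_curve(w, gamma_min = 2, gamma_max = 1, step = 1),
               "empty gamma grid")
})
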