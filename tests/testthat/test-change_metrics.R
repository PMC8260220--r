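test_that("symmetrized percent change matches the printed formula", {
  expect_equal(apc(100, 102, annualize = FALSE), 2 / 202 * 100,
               tolerance = 1e-12)
  expect_equal(apc(500, 500, 3), 0)
  expect_equal(apc(102, 100, interval = 2), -100 * 2 / 202 / 2,
               tolerance = 1e-12)
  expect_error(apc(-1, 100), "positive")
  expect_error(apc(100, 102, interval = 0), "interval")
})

test_that("symmetrized change is antisymmetric and bounded", {
  set.seed(7)
  v1 <- runif(200, 10, 1e5)
  v2 <- runif(200, 10, 1e5)
  expect_equal(apc(v1, v2, annualize = FALSE),
               -apc(v2, v1, annualize = FALSE), tolerance = 1e-12)
  expect_true(all(abs(apc(v1, v2, annualize = FALSE)) < 100))
})

test_that("change_table uses first and last sessions and drops singletons", {
  labels <- region_labels()
  row <- make_toy_cohort()[1, ]
  df <- row[rep(1, 5), ]
  df$subject_id <- c("a", "a", "a", "b", "c")
  df$session <- c(1, 2, 3, 1, 1)
  df$age <- c(6, 8, 10, 5, 7)
  # middle session has absurd volumes; it must be ignored
  df[2, labels] <- as.numeric(df[2, labels]) * 50
  df[3, labels] <- as.numeric(df[1, labels]) * 1.1
  cohort <- as_cohort(df)
  expect_message(tab <- change_table(cohort), "2 single-session")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$interval, 4)
  expect_equal(as.numeric(tab[1, labels]),
               rep(100 * 0.1 / 2.1 / 4, length(labels)), tolerance = 1e-10)
  only_single <- as_cohort(df[4:5, ])
  expect_error(change_table(only_single), "two or more sessions")
})

test_that("zero-noise synthetic cohorts invert to the drawn rates", {
  spec <- cohort_spec(n_subjects = 60, seed = 5)
  cohort <- simulate_cohort(spec)
  tab <- change_table(cohort)
  recovered <- as.matrix(tab[, region_labels()])
  truth <- attr(cohort, "true_rates")[tab$subject_id, ]
  expect_lt(max(abs(recovered - truth)), 1e-10)
})

test_that("change correlations detect planted blocks and reject degeneracy", {
  labels <- letters[1:6]
  part <- stats::setNames(c(1, 1, 1, 2, 2, 2), labels)
  spec <- cohort_spec(n_subjects = 2000, region_set = labels,
                      planted_partition = part, within_r = 0.6,
                      between_r = 0, seed = 8)
  tab <- change_table(simulate_cohort(spec))
  m <- change_correlation_matrix(tab)
  blocks <- outer(part, part, "==")
  diag(blocks) <- NA
  expect_equal(mean(m[which(blocks)]), 0.6, tolerance = 0.03)
  expect_equal(mean(m[which(!blocks)]), 0, tolerance = 0.03)

  # perfectly collinear regions correlate at exactly 1
  dup <- tab
  dup$b <- dup$a
  expect_equal(change_correlation_matrix(dup)["a", "b"], 1)
  # constant region is a named error
  flat <- tab
  flat$c <- 5
  expect_error(change_correlation_matrix(flat), "zero change variance.*c")
})

test_that("correlation matrix is invariant to row order and affine rescaling", {
  spec <- cohort_spec(n_subjects = 100, seed = 3)
  tab <- change_table(simulate_cohort(spec))
  m <- change_correlation_matrix(tab)
  shuffled <- tab[sample(nrow(tab)), ]
  attr(shuffled, "regions") <- attr(tab, "regions")
  expect_equal(change_correlation_matrix(shuffled), m, tolerance = 1e-12)
  scaled <- tab
  scaled$cortex <- 3 + 2.5 * scaled$cortex
  expect_equal(change_correlation_matrix(scaled), m, tolerance = 1e-12)
})

test_that("de-meaning zeroes the off-diagonal mean and the diagonal", {
  labels <- letters[1:3]
  m <- labeled_matrix(matrix(c(1, 0.4, 0.2, 0.4, 1, 0, 0.2, 0, 1), 3, 3),
                      labels)
  d <- demean_offdiag(m)
  expect_equal(sort(d[upper.tri(d)]), c(-0.2, 0, 0.2))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(mean(d[row(d) != col(d)]), 0, tolerance = 1e-12)
  expect_equal(demean_offdiag(d), d, tolerance = 1e-12)

  allc <- labeled_matrix(matrix(0.3, 3, 3) + diag(0.7, 3), labels)
  expect_true(all(demean_offdiag(allc) == 0))
})

test_that("pipeline recovers singleton-free planted partitions exactly", {
  # planted modules of size >= 2 are an identifiable ground truth for the
  # signed-modularity pipeline; singleton planted modules are not (two
  # regions with identical uniform between-module correlation profiles are
  # exchangeable and pairing them always increases Q)
  p4 <- reference_partition()
  p4[c("caudate", "pallidum")] <- 4L
  p4 <- as_partition(p4)
  hits <- 0
  for (s in 1:15) {
    co <- simulate_cohort(cohort_spec(n_subjects = 500, within_r = 0.6,
                                      between_r = 0, planted_partition = p4,
                                      seed = 100 + s))
    dm <- demean_offdiag(change_correlation_matrix(change_table(co)))
    mp <- modal_partition(dm, n_runs = 100, seed = s)
    hits <- hits + (partition_metrics(mp, p4)$ari == 1)
  }
  expect_gte(hits, 14)
})

test_that("non-singleton planted structure is recovered within the full partition", {
  nons <- setdiff(region_labels(), c("caudate", "pallidum"))
  ref <- as_partition(reference_partition()[nons])
  hits <- 0
  for (s in 1:10) {
    co <- simulate_cohort(cohort_spec(n_subjects = 500, within_r = 0.6,
                                      between_r = 0, seed = 200 + s))
    dm <- demean_offdiag(change_correlation_matrix(change_table(co)))
    mp <- suppressWarnings(modal_partition(dm, n_runs = 100, seed = s))
    hits <- hits + (partition_metrics(as_partition(mp[nons]), ref)$ari == 1)
  }
  expect_gte(hits, 9)
})
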