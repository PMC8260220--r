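make_ace_example <- function() {
  spec <- twin_spec(n_mz = 50, n_dz = 50, seed = 2)
  ace_model(spec$A, spec$C, spec$E, means = c(0.1, -0.2, 0.3, 0),
            residual_var = 0.1)
}

test_that("expected moments implement the twin covariance algebra", {
  fit <- make_ace_example()
  mz <- expected_moments(fit, "MZ")
  dz <- expected_moments(fit, "DZ")
  expect_identical(mz$cov, t(mz$cov))
  expect_gte(min(eigen(mz$cov, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  # mean structure: baseline = muI, follow-up = muI + muS, same both twins
  expect_equal(unname(mz$mean),
               rep(c(0.1, 0.1 - 0.2, 0.3, 0.3), 2))
  # MZ minus DZ cross-twin block isolates half the loading-mapped A
  L <- covchange:::lcs_loading()
  cross_mz <- mz$cov[1:4, 5:8]
  cross_dz <- dz$cov[1:4, 5:8]
  expect_equal(cross_mz - cross_dz, 0.5 * L %*% fit$A %*% t(L),
               tolerance = 1e-12)
  # E-only model: twins are independent
  e_only <- ace_model(matrix(0, 4, 4), matrix(0, 4, 4), diag(4))
  expect_true(all(expected_moments(e_only, "MZ")$cov[1:4, 5:8] == 0))
  expect_error(expected_moments(fit, "XX"))
})

test_that("model -2lnL matches direct multivariate-normal evaluation", {
  spec <- twin_spec(n_mz = 40, n_dz = 40, residual_var = 0, seed = 6)
  data <- simulate_twins(spec)
  fit <- ace_model(spec$A, spec$C, spec$E)
  m2 <- ace_minus2ll(fit, data, spec$regions)
  # independent oracle: per-observation density via determinant and solve
  direct <- 0
  for (z in c("MZ", "DZ")) {
    mom <- expected_moments(fit, z)
    y <- as.matrix(data[data$zygosity == z,
                        covchange:::twin_columns(spec$regions)])
    for (i in seq_len(nrow(y))) {
      d <- y[i, ] - mom$mean
      direct <- direct + 8 * log(2 * pi) +
        determinant(mom$cov, logarithm = TRUE)$modulus +
        drop(t(d) %*% solve(mom$cov, d))
    }
  }
  expect_equal(m2, as.numeric(direct), tolerance = 1e-6)
})

test_that("likelihood is invariant to twin order within pairs", {
  spec <- twin_spec(n_mz = 30, n_dz = 30, seed = 8)
  data <- simulate_twins(spec)
  fit <- ace_model(spec$A, spec$C, spec$E)
  swapped <- data
  c1 <- covchange:::twin_columns(spec$regions)[1:4]
  c2 <- covchange:::twin_columns(spec$regions)[5:8]
  swapped[, c1] <- data[, c2]
  swapped[, c2] <- data[, c1]
  expect_equal(ace_minus2ll(fit, swapped, spec$regions),
               ace_minus2ll(fit, data, spec$regions), tolerance = 1e-9)
})

test_that("the fitter recovers a planted slope genetic correlation", {
  spec <- twin_spec(n_mz = 500, n_dz = 500, rg_slope = 0.6, a2 = 0.5,
                    c2 = 0.1, e2 = 0.4, seed = 5)
  data <- simulate_twins(spec)
  fit <- fit_bivariate_lcs_ace(data, spec$regions, n_starts = 2, seed = 1)
  expect_true(fit$converged)
  expect_false(fit$rg_unstable)
  expect_equal(fit$rg_slope, 0.6, tolerance = 0.25)
  expect_true(all(abs(diag(fit$A)[c(2, 4)] - 0.5) < 0.25))
  # removing A can never improve the likelihood (nesting)
  fit_ce <- fit_bivariate_lcs_ace(data, spec$regions, n_starts = 2, seed = 1,
                                  model = "CE")
  expect_gte(fit_ce$minus2lnL, fit$minus2lnL - 1e-6)
})

test_that("null heritability yields near-zero genetic slope variance", {
  spec <- twin_spec(n_mz = 300, n_dz = 300, a2 = 0, c2 = 0.3, e2 = 0.7,
                    rg_slope = 0.5, seed = 14)
  data <- simulate_twins(spec)
  fit <- fit_bivariate_lcs_ace(data, spec$regions, n_starts = 3, seed = 2)
  tot1 <- fit$A["S1", "S1"] + fit$C["S1", "S1"] + fit$E["S1", "S1"]
  tot2 <- fit$A["S2", "S2"] + fit$C["S2", "S2"] + fit$E["S2", "S2"]
  expect_lt(fit$A["S1", "S1"] / tot1, 0.25)
  expect_lt(fit$A["S2", "S2"] / tot2, 0.25)
  # no detectable genetic component: dropping A barely moves the likelihood
  fit_ce <- fit_bivariate_lcs_ace(data, spec$regions, n_starts = 2, seed = 2,
                                  model = "CE")
  expect_lt(fit_ce$minus2lnL - fit$minus2lnL, 30)
})

test_that("degenerate data and small groups are rejected", {
  spec <- twin_spec(n_mz = 30, n_dz = 30, seed = 3)
  data <- simulate_twins(spec)
  expect_error(fit_bivariate_lcs_ace(data, spec$regions, min_pairs = 40),
               "need >= 40")
  flat <- data
  flat$t1_region_a_bl <- 1
  expect_error(fit_bivariate_lcs_ace(flat, spec$regions, min_pairs = 20),
               "zero variance")
  expect_error(fit_bivariate_lcs_ace(data, "region_a"), "two regions")
})

test_that("bilateral indicators identify the occasion-level residual", {
  spec <- twin_spec(n_mz = 400, n_dz = 400, residual_var = 0.3,
                    bilateral = TRUE, seed = 11)
  data <- simulate_twins(spec)
  fit <- fit_bivariate_lcs_ace(data, spec$regions, n_starts = 2, seed = 2,
                               bilateral = TRUE)
  expect_true(fit$converged)
  expect_equal(fit$residual_var, 0.3, tolerance = 0.08)
})

test_that("simulated twins reproduce the Falconer MZ/DZ covariance ratio", {
  spec <- twin_spec(n_mz = 30000, n_dz = 30000, a2 = 0.6, c2 = 0, e2 = 0.4,
                    seed = 21)
  data <- simulate_twins(spec)
  cov_cross <- function(z) {
    rows <- data$zygosity == z
    stats::cov(data$t1_region_a_fu[rows] - data$t1_region_a_bl[rows],
               data$t2_region_a_fu[rows] - data$t2_region_a_bl[rows])
  }
  # slope cross-twin covariance: a2 * 1 (MZ) vs a2 * 0.5 (DZ)
  se <- 0.6 / sqrt(30000) * 3
  expect_equal(cov_cross("MZ"), 0.6, tolerance = 5 * se + 0.02)
  expect_equal(cov_cross("MZ") / cov_cross("DZ"), 2, tolerance = 0.25)

  e_spec <- twin_spec(n_mz = 20000, n_dz = 100, a2 = 0, c2 = 0, e2 = 1,
                      seed = 22)
  e_data <- simulate_twins(e_spec)
  rows <- e_data$zygosity == "MZ"
  cc <- stats::cov(e_data$t1_region_a_fu[rows] - e_data$t1_region_a_bl[rows],
                   e_data$t2_region_a_fu[rows] - e_data$t2_region_a_bl[rows])
  expect_lt(abs(cc), 0.03)
})

test_that("twin simulation is deterministic and validates proportions", {
  spec <- twin_spec(n_mz = 25, n_dz = 25, seed = 7)
  expect_identical(simulate_twins(spec), simulate_twins(spec))
  expect_error(twin_spec(a2 = 0.7, c2 = 0.5, e2 = 0.4), "sum to 1")
  expect_error(twin_spec(a2 = -0.1, c2 = 0.4, e2 = 0.7), "nonnegative|sum to 1")
})

test_that("duplicated regions have unit genetic slope correlation", {
  spec <- twin_spec(n_mz = 500, n_dz = 400, rg_slope = 1, rg_intercept = 1,
                    rg_is = 0.3, seed = 17)
  data <- simulate_twins(spec)
  fit <- fit_bivariate_lcs_ace(data, spec$regions, n_starts = 2, seed = 3)
  expect_gt(fit$rg_slope, 0.8)
})

test_that("genetic correlation matrix recovers planted block structure", {
  regions <- c("ra", "rb", "rc", "rd")
  part <- stats::setNames(c(1, 1, 2, 2), regions)
  spec <- twin_spec(n_mz = 600, n_dz = 600, regions = regions,
                    partition = part, rg_slope = 0.7, rg_between = 0,
                    a2 = 0.6, c2 = 0.1, e2 = 0.3, seed = 19)
  data <- simulate_twins(spec)
  g <- genetic_change_corr_matrix(data, regions, n_starts = 1, seed = 4)
  expect_identical(g, t(g))
  expect_equal(unname(diag(g)), rep(1, 4))
  within <- c(g["ra", "rb"], g["rc", "rd"])
  between <- c(g["ra", "rc"], g["ra", "rd"], g["rb", "rc"], g["rb", "rd"])
  expect_gt(mean(within, na.rm = TRUE), mean(between, na.rm = TRUE))
  expect_gt(mean(within, na.rm = TRUE), 0.4)
  expect_lt(mean(abs(between), na.rm = TRUE), 0.35)
  # the genetic matrix plugs straight into the Mantel machinery
  g0 <- g
  g0[is.na(g0)] <- 0
  expect_equal(mantel(g0, g0, n_perm = 9, seed = 1)$r, 1)
})
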