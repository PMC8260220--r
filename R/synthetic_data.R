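#' Specification of a synthetic longitudinal cohort
#'
#' Defines the study conditions for a simulated two-session cohort whose
#' per-subject annualized change rates carry a planted cluster structure:
#' rates are drawn from a block-structured multivariate normal whose
#' correlation is `within_r` for region pairs in the same planted module and
#' `between_r` otherwise. Defaults mirror the developmental sample the
#' pipeline targets: 644 subjects, follow-up intervals uniform on 1.0-3.2
#' years, baseline ages under 20, and the reference five-cluster partition
#' of the canonical 16 regions.
#'
#' Rates are generated directly on the annualized symmetrized-percent-change
#' scale and mapped to follow-up volumes by exact inversion of the change
#' formula, so that at zero measurement noise [change_table()] recovers the
#' drawn rates to machine precision.
#'
#' @param n_subjects Number of subjects (default 644).
#' @param region_set Region set data frame.
#' @param planted_partition Partition giving the planted modules (default
#'   [reference_partition()]).
#' @param within_r,between_r Change-rate correlations within/between planted
#'   modules (defaults 0.5 and 0.05); the implied correlation matrix must be
#'   positive semidefinite.
#' @param mean_apc,sd_apc Mean and SD of the annualized change rate (percent
#'   per year) per region; scalars are recycled (defaults 0 and 1).
#' @param interval_range Follow-up interval range in years (default
#'   `c(1.0, 3.2)`).
#' @param baseline_age_range Baseline age range in years (default
#'   `c(4.1, 16.5)`).
#' @param baseline_volume_range Baseline volume range in mm^3 (default
#'   `c(1500, 20000)`).
#' @param measurement_noise_sd SD of additive volume measurement noise in
#'   mm^3, applied to both occasions (default 0).
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 644,
                        region_set = subcortical_regions(),
                        planted_partition = reference_partition(region_set),
                        within_r = 0.5, between_r = 0.05,
                        mean_apc = 0, sd_apc = 1,
                        interval_range = c(1.0, 3.2),
                        baseline_age_range = c(4.1, 16.5),
                        baseline_volume_range = c(1500, 20000),
                        measurement_noise_sd = 0,
                        seed = 1) {
  labels <- region_labels(region_set)
  p <- align_partition_labels(planted_partition,
                              matrix(0, length(labels), length(labels),
                                     dimnames = list(labels, labels)))
  if (any(c(within_r, between_r) <= -1) || any(c(within_r, between_r) >= 1)) {
    stop("within_r and between_r must lie in (-1, 1)")
  }
  same <- outer(p, p, "==")
  R <- ifelse(same, within_r, between_r)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("implied change-rate correlation matrix is not PSD")
  if (any(interval_range <= 0) || diff(interval_range) < 0) {
    stop("invalid interval_range")
  }
  spec <- list(
    n_subjects = n_subjects, region_set = region_set, labels = labels,
    planted_partition = p, within_r = within_r, between_r = between_r,
    target_correlation = labeled_matrix(R, labels),
    mean_apc = rep_len(mean_apc, length(labels)),
    sd_apc = rep_len(sd_apc, length(labels)),
    interval_range = interval_range,
    baseline_age_range = baseline_age_range,
    baseline_volume_range = baseline_volume_range,
    measurement_noise_sd = measurement_noise_sd, seed = seed
  )
  class(spec) <- "cohort_spec"
  spec
}

#' Simulate a longitudinal cohort with planted change structure
#'
#' @param spec A [cohort_spec()].
#' @return A validated cohort data frame (two sessions per subject) with the
#'   drawn per-subject annualized rates attached as attribute
#'   `"true_rates"` (subjects x regions) and the planted partition as
#'   `"planted_partition"`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- spec$labels
  n <- spec$n_subjects
  k <- length(labels)
  seeds <- derive_seeds(spec$seed, 5)
  D <- diag(spec$sd_apc, k)
  sigma <- D %*% spec$target_correlation %*% D
  rates <- with_seed(seeds[1],
                     MASS::mvrnorm(n, mu = spec$mean_apc, Sigma = sigma))
  rates <- matrix(rates, nrow = n, dimnames = list(NULL, labels))
  v1 <- with_seed(seeds[2], matrix(
    stats::runif(n * k, spec$baseline_volume_range[1],
                 spec$baseline_volume_range[2]), n, k,
    dimnames = list(NULL, labels)))
  intervals <- with_seed(seeds[3],
                         stats::runif(n, spec$interval_range[1],
                                      spec$interval_range[2]))
  meta <- with_seed(seeds[4], list(
    age1 = stats::runif(n, spec$baseline_age_range[1],
                        spec$baseline_age_range[2]),
    sex = sample(c("F", "M"), n, replace = TRUE),
    icv = stats::rnorm(n, 1.5e6, 1.2e5)
  ))
  # total symmetrized percent change over the interval; exact inversion of
  # the change formula gives the follow-up volume
  p_total <- rates * intervals
  if (any(abs(p_total) >= 100)) {
    stop("drawn change exceeds the +/-100% bound of symmetrized change")
  }
  v2 <- v1 * (100 + p_total) / (100 - p_total)
  if (spec$measurement_noise_sd > 0) {
    noise <- with_seed(seeds[5],
                       matrix(stats::rnorm(2 * n * k, 0,
                                           spec$measurement_noise_sd),
                              2 * n, k))
    v1 <- v1 + noise[seq_len(n), , drop = FALSE]
    v2 <- v2 + noise[n + seq_len(n), , drop = FALSE]
    if (any(v1 <= 0) || any(v2 <= 0)) {
      stop("measurement noise produced non-positive volumes; reduce ",
           "measurement_noise_sd")
    }
  }
  ids <- sprintf("sub%04d", seq_len(n))
  df <- data.frame(
    subject_id = rep(ids, 2),
    session = rep(c(1L, 2L), each = n),
    age = c(meta$age1, meta$age1 + intervals),
    sex = rep(meta$sex, 2),
    site = "synthetic",
    icv = rep(meta$icv, 2),
    rbind(v1, v2),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  cohort <- as_cohort(df, spec$region_set)
  rownames(rates) <- ids
  attr(cohort, "true_rates") <- rates[sort(ids), , drop = FALSE]
  attr(cohort, "planted_partition") <- spec$planted_partition
  cohort
}

#' Specification of a synthetic twin sample
#'
#' Defines MZ/DZ twin pairs whose latent intercept and slope factors follow
#' an ACE covariance structure. Each of `k` regions contributes an intercept
#' and a slope factor (total variance standardized to
#' `a2 + c2 + e2 = 1` per factor). The genetic correlation between slope
#' (and intercept) factors of two regions is `rg_slope`
#' (resp. `rg_intercept`) when the regions share a planted module and
#' `rg_between` otherwise; within a region, intercept and slope have genetic
#' correlation `rg_is`. Shared- and unique-environment factors are
#' uncorrelated across factors except for an optional within-region
#' intercept-slope E correlation `re_is`. Defaults mirror the twin sample
#' the pipeline targets: 150 MZ and 106 DZ pairs.
#'
#' @param n_mz,n_dz Number of MZ and DZ pairs (defaults 150 and 106).
#' @param regions Character vector of region names (default two regions).
#' @param partition Optional named module assignment for the regions
#'   (default: all in one module).
#' @param a2,c2,e2 Variance proportions per latent factor (scalars or
#'   per-factor; must be nonnegative and sum to 1). Defaults 0.5 / 0.1 /
#'   0.4.
#' @param rg_slope Genetic correlation between slope factors of same-module
#'   region pairs (default 0.6).
#' @param rg_intercept Genetic correlation between intercept factors of
#'   same-module region pairs (default `rg_slope`).
#' @param rg_between Genetic correlation across modules (default 0).
#' @param rg_is Within-region intercept-slope genetic correlation
#'   (default 0.3).
#' @param re_is Within-region intercept-slope unique-environment
#'   correlation (default 0).
#' @param residual_var Occasion-level measurement variance added to each
#'   observed indicator (default 0; use with `bilateral` fitting).
#' @param bilateral Generate left/right indicators per occasion.
#' @param seed Integer seed.
#' @return Object of class `twin_spec` (includes the implied `A`, `C`, `E`
#'   latent covariance matrices).
#' @export
twin_spec <- function(n_mz = 150, n_dz = 106,
                      regions = c("region_a", "region_b"),
                      partition = NULL,
                      a2 = 0.5, c2 = 0.1, e2 = 0.4,
                      rg_slope = 0.6, rg_intercept = rg_slope,
                      rg_between = 0, rg_is = 0.3, re_is = 0,
                      residual_var = 0, bilateral = FALSE, seed = 1) {
  k <- length(regions)
  if (k < 1) stop("need at least one region")
  if (is.null(partition)) partition <- stats::setNames(rep(1L, k), regions)
  partition <- partition[regions]
  nf <- 2 * k
  a2 <- rep_len(a2, nf); c2 <- rep_len(c2, nf); e2 <- rep_len(e2, nf)
  tot <- a2 + c2 + e2
  if (any(a2 < 0 | c2 < 0 | e2 < 0) || any(abs(tot - 1) > 1e-8)) {
    stop("a2, c2, e2 must be nonnegative and sum to 1 per factor")
  }
  # factor order: (I_r1, S_r1, I_r2, S_r2, ...)
  fac_region <- rep(seq_len(k), each = 2)
  fac_type <- rep(c("I", "S"), k)
  Rg <- diag(1, nf)
  for (i in seq_len(nf - 1)) {
    for (j in seq((i + 1), nf) ) {
      same_region <- fac_region[i] == fac_region[j]
      same_module <- partition[fac_region[i]] == partition[fac_region[j]]
      base <- if (same_region) rg_is
      else if (fac_type[i] == fac_type[j]) {
        if (same_module) {
          if (fac_type[i] == "S") rg_slope else rg_intercept
        } else rg_between
      } else {
        # cross region, cross type: attenuated by the within-region I-S link
        rg_is * (if (same_module) (rg_slope + rg_intercept) / 2 else rg_between)
      }
      Rg[i, j] <- Rg[j, i] <- base
    }
  }
  ev <- eigen(Rg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("implied genetic correlation matrix is not PSD")
  A <- diag(sqrt(a2)) %*% Rg %*% diag(sqrt(a2))
  C <- diag(c2, nf)
  Re <- diag(1, nf)
  for (r in seq_len(k)) Re[2 * r - 1, 2 * r] <- Re[2 * r, 2 * r - 1] <- re_is
  E <- diag(sqrt(e2)) %*% Re %*% diag(sqrt(e2))
  fac_names <- paste0(fac_type, fac_region)
  dimnames(A) <- dimnames(C) <- dimnames(E) <- list(fac_names, fac_names)
  for (nm in c("A", "C", "E")) {
    ev <- eigen(get(nm), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("implied ", nm, " matrix is not PSD")
  }
  if (residual_var < 0) stop("residual_var must be >= 0")
  structure(list(n_mz = n_mz, n_dz = n_dz, regions = regions,
                 partition = partition, A = A, C = C, E = E,
                 residual_var = residual_var, bilateral = bilateral,
                 rg_slope = rg_slope, seed = seed),
            class = "twin_spec")
}

# Loading from 2k latent factors to per-twin observed occasions.
lcs_loading_k <- function(k, bilateral = FALSE) {
  nocc <- if (bilateral) 4L else 2L
  per_region <- lcs_loading(bilateral)[seq_len(nocc), 1:2, drop = FALSE]
  L <- matrix(0, nrow(per_region) * k, 2 * k)
  for (r in seq_len(k)) {
    rows <- (r - 1) * nrow(per_region) + seq_len(nrow(per_region))
    L[rows, c(2 * r - 1, 2 * r)] <- per_region
  }
  L
}

#' Simulate MZ/DZ twin pairs under the latent change ACE model
#'
#' Draws latent intercept/slope factors with cross-twin genetic correlation
#' 1 (MZ) or 0.5 (DZ) and cross-twin shared-environment correlation 1, maps
#' them to observed baseline/follow-up values through the latent change
#' measurement model, and adds occasion-level residual noise.
#'
#' @param spec A [twin_spec()].
#' @return Data frame with `pair_id`, `zygosity`, and observed columns
#'   `t{1,2}_<region>_{bl,fu}` (with `_lh`/`_rh` suffixes when bilateral);
#'   the spec is attached as attribute `"twin_spec"`.
#' @export
simulate_twins <- function(spec) {
  stopifnot(inherits(spec, "twin_spec"))
  k <- length(spec$regions)
  nf <- 2 * k
  L <- lcs_loading_k(k, spec$bilateral)
  m <- nrow(L)
  n_total <- spec$n_mz + spec$n_dz
  zyg <- rep(c("MZ", "DZ"), c(spec$n_mz, spec$n_dz))
  seeds <- derive_seeds(spec$seed, 3)
  draw <- function(n, sigma) {
    if (n == 0) return(matrix(0, 0, nf))
    matrix(MASS::mvrnorm(n, mu = rep(0, nf), Sigma = sigma), n, nf)
  }
  out <- with_seed(seeds[1], {
    a_shared <- draw(n_total, spec$A)
    a_ind1 <- draw(n_total, spec$A)
    a_ind2 <- draw(n_total, spec$A)
    c_shared <- draw(n_total, spec$C)
    e1 <- draw(n_total, spec$E)
    e2 <- draw(n_total, spec$E)
    mz <- zyg == "MZ"
    w_sh <- ifelse(mz, 1, sqrt(0.5))
    w_in <- ifelse(mz, 0, sqrt(0.5))
    lat1 <- w_sh * a_shared + w_in * a_ind1 + c_shared + e1
    lat2 <- w_sh * a_shared + w_in * a_ind2 + c_shared + e2
    list(y1 = lat1 %*% t(L), y2 = lat2 %*% t(L))
  })
  if (spec$residual_var > 0) {
    out <- with_seed(seeds[2], {
      sdr <- sqrt(spec$residual_var)
      out$y1 <- out$y1 + matrix(stats::rnorm(n_total * m, 0, sdr), n_total, m)
      out$y2 <- out$y2 + matrix(stats::rnorm(n_total * m, 0, sdr), n_total, m)
      out
    })
  }
  occ_per_region <- m / k
  col_names <- function(t) unlist(lapply(spec$regions, function(r) {
    occ <- if (spec$bilateral) c("bl_lh", "bl_rh", "fu_lh", "fu_rh")
    else c("bl", "fu")
    paste0("t", t, "_", r, "_", occ)
  }))
  colnames(out$y1) <- col_names(1)
  colnames(out$y2) <- col_names(2)
  df <- data.frame(pair_id = sprintf("pair%04d", seq_len(n_total)),
                   zygosity = zyg, out$y1, out$y2,
                   check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "twin_spec") <- spec
  df
}
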