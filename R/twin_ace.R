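#' Bivariate latent change score ACE model
#'
#' Model structure, shared by the simulator, the moment calculator and the
#' fitter. For two regions, each twin carries four latent factors: intercept
#' and slope (change) per region, `(I1, S1, I2, S2)`. Observed variables per
#' twin and region are the baseline and follow-up adjusted volumes, generated
#' as `baseline = I + e` and `follow-up = I + S + e` with occasion-level
#' residual `e`. The 4x4 latent covariance decomposes as `A + C + E`
#' (additive genetic, shared environment, unique environment), each kept
#' positive semidefinite through a lower-triangular Cholesky factor. The
#' cross-twin latent covariance is `alpha * A + C` with `alpha = 1` for MZ
#' pairs and `0.5` for DZ pairs. The genetic correlation of change between
#' the two regions is `rg_slope = A[S1, S2] / sqrt(A[S1, S1] * A[S2, S2])`.
#'
#' With hemisphere-averaged volumes there is a single indicator per latent
#' occasion and the occasion-level residual variance is not identified
#' separately from the E component (it is absorbed into E and fixed to 0 by
#' the fitter); with bilateral left/right indicators (`bilateral = TRUE`)
#' each occasion has two indicators and the residual variance is estimated.
#'
#' @param A,C,E 4x4 positive semidefinite covariance matrices over
#'   `(I1, S1, I2, S2)`.
#' @param means Length-4 latent means `(muI1, muS1, muI2, muS2)`.
#' @param residual_var Occasion-level residual variance (>= 0).
#' @return Object of class `ace_fit`.
#' @export
ace_model <- function(A, C, E, means = rep(0, 4), residual_var = 0) {
  for (nm in c("A", "C", "E")) {
    m <- get(nm)
    if (!isTRUE(all.equal(dim(m), c(4L, 4L)))) stop(nm, " must be 4x4")
    if (max(abs(m - t(m))) > 1e-8) stop(nm, " must be symmetric")
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop(nm, " is not positive semidefinite")
  }
  if (residual_var < 0) stop("residual_var must be >= 0")
  lat <- c("I1", "S1", "I2", "S2")
  dimnames(A) <- dimnames(C) <- dimnames(E) <- list(lat, lat)
  fit <- list(A = A, C = C, E = E, means = stats::setNames(means, lat),
              residual_var = residual_var,
              rg_slope = latent_corr(A, "S1", "S2"),
              minus2lnL = NA_real_, converged = NA)
  class(fit) <- "ace_fit"
  fit
}

latent_corr <- function(m, a, b) {
  va <- m[a, a]; vb <- m[b, b]
  if (va <= 1e-10 || vb <= 1e-10) return(NA_real_)
  max(-1, min(1, m[a, b] / sqrt(va * vb)))
}

# Loading matrix from latent (I1, S1, I2, S2) to observed occasions.
# Averaged: (bl1, fu1, bl2, fu2); bilateral duplicates each row for lh/rh.
lcs_loading <- function(bilateral = FALSE) {
  L <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 1, 1))
  if (bilateral) L <- L[rep(1:4, each = 2), , drop = FALSE]
  L
}

#' Expected observed moments of the twin model
#'
#' Mean vector and covariance matrix of the stacked observed vector
#' (twin 1's occasions then twin 2's) implied by an [ace_model()], for a
#' given zygosity. The within-twin covariance is
#' `Lambda (A + C + E) Lambda' + residual_var * I`; the cross-twin block is
#' `Lambda (alpha A + C) Lambda'` with `alpha` 1 (MZ) or 0.5 (DZ).
#'
#' @param fit An `ace_fit`.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param bilateral Two indicators (left/right) per occasion.
#' @return List with `mean` (length 2m) and `cov` (2m x 2m, symmetric PSD).
#' @export
expected_moments <- function(fit, zygosity = c("MZ", "DZ"), bilateral = FALSE) {
  zygosity <- match.arg(zygosity)
  alpha <- if (zygosity == "MZ") 1 else 0.5
  L <- lcs_loading(bilateral)
  m <- nrow(L)
  W <- L %*% (fit$A + fit$C + fit$E) %*% t(L) + fit$residual_var * diag(m)
  B <- L %*% (alpha * fit$A + fit$C) %*% t(L)
  cov <- rbind(cbind(W, B), cbind(t(B), W))
  cov <- (cov + t(cov)) / 2
  mu <- as.numeric(L %*% fit$means)
  list(mean = c(mu, mu), cov = cov)
}

# Observed column names for a region pair: twin block-major, occasions in
# (bl, fu) order per region.
twin_columns <- function(regions, bilateral = FALSE) {
  occ <- if (bilateral) {
    c(t(outer(c("bl", "fu"), c("lh", "rh"), function(o, h) paste(o, h, sep = "_"))))
  } else c("bl", "fu")
  unlist(lapply(1:2, function(t) {
    unlist(lapply(regions, function(r) paste0("t", t, "_", r, "_", occ)))
  }))
}

extract_twin_matrix <- function(data, regions, zygosity, bilateral = FALSE) {
  cols <- twin_columns(regions, bilateral)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("twin data lacks columns: ", paste(missing, collapse = ", "))
  }
  rows <- data$zygosity == zygosity
  y <- as.matrix(data[rows, cols, drop = FALSE])
  y <- y[stats::complete.cases(y), , drop = FALSE]
  storage.mode(y) <- "double"
  y
}

# -2 log-likelihood of one multivariate-normal group from sufficient
# statistics: n * log|Sigma| + tr(Sigma^-1 S) + n (ybar-mu)' Sigma^-1
# (ybar-mu) + n p log(2 pi), with S the centered scatter matrix.
mvn_m2ll_suffstat <- function(n, ybar, scatter, mu, sigma) {
  p <- length(mu)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  logdet <- 2 * sum(log(diag(ch)))
  d <- ybar - mu
  inv_s <- chol2inv(ch)
  as.numeric(n * p * log(2 * pi) + n * logdet + sum(inv_s * scatter) +
               n * crossprod(d, inv_s %*% d))
}

suff_stats <- function(y) {
  n <- nrow(y)
  ybar <- colMeans(y)
  yc <- sweep(y, 2, ybar)
  list(n = n, ybar = ybar, scatter = crossprod(yc))
}

#' -2 log-likelihood of an ACE model on twin-pair data
#'
#' Sums the MZ and DZ multivariate-normal -2 log-likelihoods of the
#' observed vectors under the model-implied moments.
#'
#' @inheritParams fit_bivariate_lcs_ace
#' @param fit An `ace_fit`.
#' @return Scalar -2 log-likelihood.
#' @export
ace_minus2ll <- function(fit, data, region_pair, bilateral = FALSE) {
  total <- 0
  for (z in c("MZ", "DZ")) {
    y <- extract_twin_matrix(data, region_pair, z, bilateral)
    if (nrow(y) == 0) next
    ss <- suff_stats(y)
    mom <- expected_moments(fit, z, bilateral)
    total <- total + mvn_m2ll_suffstat(ss$n, ss$ybar, ss$scatter,
                                       mom$mean, mom$cov)
  }
  total
}

# --- maximum-likelihood fitting ------------------------------------------

chol_to_vec <- function(m) {
  ch <- tryCatch(t(chol(m + 1e-10 * diag(4))), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen((m + t(m)) / 2, symmetric = TRUE)
    ev$values <- pmax(ev$values, 1e-8)
    ch <- t(chol(ev$vectors %*% diag(ev$values) %*% t(ev$vectors)))
  }
  ch[lower.tri(ch, diag = TRUE)]
}

vec_to_chol <- function(v) {
  ch <- matrix(0, 4, 4)
  ch[lower.tri(ch, diag = TRUE)] <- v
  ch
}

model_components <- function(model) {
  switch(model,
         ACE = c(A = TRUE, C = TRUE, E = TRUE),
         AE = c(A = TRUE, C = FALSE, E = TRUE),
         CE = c(A = FALSE, C = TRUE, E = TRUE),
         E = c(A = FALSE, C = FALSE, E = TRUE),
         stop("unknown model: ", model))
}

theta_to_model <- function(theta, bilateral, model = "ACE") {
  comps <- model_components(model)
  means <- theta[1:4]
  pos <- 5
  mats <- list()
  for (nm in c("A", "C", "E")) {
    if (comps[[nm]]) {
      mats[[nm]] <- tcrossprod(vec_to_chol(theta[pos:(pos + 9)]))
      pos <- pos + 10
    } else {
      mats[[nm]] <- matrix(0, 4, 4)
    }
  }
  resid <- if (bilateral) exp(2 * theta[pos]) else 0
  list(A = mats$A, C = mats$C, E = mats$E, means = means,
       residual_var = resid)
}

make_objective <- function(stats_by_group, bilateral, model = "ACE") {
  L <- lcs_loading(bilateral)
  m <- nrow(L)
  function(theta) {
    par <- theta_to_model(theta, bilateral, model)
    total <- 0
    for (z in names(stats_by_group)) {
      alpha <- if (z == "MZ") 1 else 0.5
      W <- L %*% (par$A + par$C + par$E) %*% t(L) + par$residual_var * diag(m)
      B <- L %*% (alpha * par$A + par$C) %*% t(L)
      sigma <- rbind(cbind(W, B), cbind(t(B), W))
      mu <- rep(as.numeric(L %*% par$means), 2)
      ss <- stats_by_group[[z]]
      total <- total + mvn_m2ll_suffstat(ss$n, ss$ybar, ss$scatter, mu, sigma)
    }
    if (!is.finite(total)) 1e12 else total
  }
}

# Moment-based starting values: solve the latent covariances from the
# empirical within- and cross-twin blocks via the (pseudo)inverse of the
# loading matrix, then clip to PSD.
moment_start <- function(stats_by_group, bilateral) {
  L <- lcs_loading(bilateral)
  m <- nrow(L)
  Linv <- solve(crossprod(L)) %*% t(L)     # left pseudo-inverse
  avg_block <- function(S, n) {
    W <- (S[1:m, 1:m] + S[(m + 1):(2 * m), (m + 1):(2 * m)]) / 2 / n
    B <- (S[1:m, (m + 1):(2 * m)] + t(S[(m + 1):(2 * m), 1:m])) / 2 / n
    list(W = W, B = (B + t(B)) / 2)
  }
  bl <- lapply(stats_by_group, function(ss) avg_block(ss$scatter, ss$n))
  Wbar <- Reduce(`+`, lapply(bl, `[[`, "W")) / length(bl)
  P <- Linv %*% Wbar %*% t(Linv)
  Bmz <- if (!is.null(bl$MZ)) Linv %*% bl$MZ$B %*% t(Linv) else 0.5 * P
  Bdz <- if (!is.null(bl$DZ)) Linv %*% bl$DZ$B %*% t(Linv) else 0.25 * P
  A0 <- 2 * (Bmz - Bdz)
  C0 <- 2 * Bdz - Bmz
  E0 <- P - A0 - C0
  ybar <- Reduce(`+`, lapply(stats_by_group, `[[`, "ybar")) / length(stats_by_group)
  obs_mu <- (ybar[1:m] + ybar[(m + 1):(2 * m)]) / 2
  mu0 <- as.numeric(Linv %*% obs_mu)
  list(means = mu0, A = psd_clip(A0), C = psd_clip(C0), E = psd_clip(E0, floor = 0.05))
}

psd_clip <- function(m, floor = 1e-4) {
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  ev$values <- pmax(ev$values, floor)
  ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
}

#' Fit the bivariate latent change score ACE model
#'
#' Maximum-likelihood fit of the twin model described in [ace_model()] to
#' MZ and DZ pairs for one pair of regions, by quasi-Newton optimization
#' over Cholesky-parameterized A, C, E matrices and latent means, with
#' multiple jittered starts around moment-based estimates. The fit never
#' raises on optimization failure; `converged` is `FALSE` when no start
#' converged.
#'
#' @param data Twin-pair data frame: one row per pair, a `zygosity` column
#'   (`"MZ"`/`"DZ"`), and per-twin observed columns
#'   `t{1,2}_<region>_{bl,fu}` (or `..._{bl,fu}_{lh,rh}` when
#'   `bilateral = TRUE`). Volumes are assumed adjusted (site/ICV
#'   residualized, standardized).
#' @param region_pair Character vector of two region names.
#' @param n_starts Number of optimization starts (default 10).
#' @param seed Integer seed for the start jitter.
#' @param bilateral Fit left/right hemisphere indicators with a free
#'   occasion-level residual variance.
#' @param min_pairs Minimum complete pairs required per zygosity group
#'   (default 20).
#' @param model `"ACE"` (default) or a nested submodel: `"AE"` (no shared
#'   environment), `"CE"` (no genetic component), `"E"`.
#' @return An `ace_fit` with `A`, `C`, `E`, `means`, `residual_var`,
#'   `rg_slope`, `minus2lnL`, `converged`, and group sizes `n_mz`, `n_dz`.
#' @export
fit_bivariate_lcs_ace <- function(data, region_pair, n_starts = 10, seed = 1,
                                  bilateral = FALSE, min_pairs = 20,
                                  model = "ACE") {
  comps <- model_components(model)
  if (length(region_pair) != 2) stop("region_pair must name two regions")
  stats_by_group <- list()
  for (z in c("MZ", "DZ")) {
    y <- extract_twin_matrix(data, region_pair, z, bilateral)
    if (nrow(y) < min_pairs) {
      stop("only ", nrow(y), " complete ", z, " pairs; need >= ", min_pairs)
    }
    if (any(apply(y, 2, stats::sd) < 1e-12)) {
      stop("zero variance in an observed variable for group ", z)
    }
    stats_by_group[[z]] <- suff_stats(y)
  }
  objective <- make_objective(stats_by_group, bilateral, model)
  start0 <- moment_start(stats_by_group, bilateral)
  base_theta <- start0$means
  for (nm in c("A", "C", "E")) {
    if (comps[[nm]]) base_theta <- c(base_theta, chol_to_vec(start0[[nm]]))
  }
  if (bilateral) base_theta <- c(base_theta, 0.5 * log(0.3))
  jitters <- with_seed(seed, lapply(seq_len(n_starts), function(s) {
    if (s == 1) rep(0, length(base_theta))
    else stats::rnorm(length(base_theta), 0, 0.15)
  }))
  best <- NULL
  any_converged <- FALSE
  for (s in seq_len(n_starts)) {
    theta0 <- base_theta * (1 + jitters[[s]]) +
      0.02 * jitters[[s]]          # move zero entries too
    res <- tryCatch(
      stats::nlminb(theta0, objective,
                    control = list(iter.max = 2000, eval.max = 4000)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    ok <- res$convergence == 0
    any_converged <- any_converged || ok
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) {
    fit <- ace_model(diag(4), matrix(0, 4, 4), diag(4), rep(0, 4), 0)
    fit$converged <- FALSE
    fit$minus2lnL <- NA_real_
    fit$regions <- region_pair
    return(fit)
  }
  par <- theta_to_model(best$par, bilateral, model)
  fit <- ace_model(par$A, par$C, par$E, par$means, par$residual_var)
  fit$minus2lnL <- best$objective
  fit$converged <- any_converged
  fit$model <- model
  fit$regions <- region_pair
  fit$n_mz <- stats_by_group$MZ$n
  fit$n_dz <- stats_by_group$DZ$n
  # rg is ill-conditioned when a slope has (near-)zero genetic variance
  slope_share <- function(s) {
    tot <- fit$A[s, s] + fit$C[s, s] + fit$E[s, s]
    if (tot <= 0) 0 else fit$A[s, s] / tot
  }
  fit$rg_unstable <- is.na(fit$rg_slope) ||
    slope_share("S1") < 0.05 || slope_share("S2") < 0.05
  fit
}

#' @export
print.ace_fit <- function(x, ...) {
  cat("Bivariate latent change score ACE fit\n")
  if (!is.null(x$regions)) cat("  regions:", paste(x$regions, collapse = " vs "), "\n")
  cat(sprintf("  rg_slope = %s%s\n",
              ifelse(is.na(x$rg_slope), "NA", sprintf("%.3f", x$rg_slope)),
              if (isTRUE(x$rg_unstable)) " (unstable: near-zero genetic slope variance)" else ""))
  if (is.finite(x$minus2lnL)) cat(sprintf("  -2 lnL = %.3f (converged: %s)\n",
                                          x$minus2lnL, x$converged))
  invisible(x)
}

#' Genetic change-change correlation matrix
#'
#' Fits the bivariate latent change score ACE model to every pair of
#' regions and assembles the genetic correlations of the slope (change)
#' factors into a labeled symmetric matrix with unit diagonal. Cells whose
#' fit did not converge (or whose genetic slope variance is degenerate) are
#' `NA`; the per-pair fit summaries are attached as attribute `"fits"`.
#'
#' @inheritParams fit_bivariate_lcs_ace
#' @param regions Character vector of region names to cover (default: all
#'   regions found in the data columns, in canonical order when they match
#'   the canonical set).
#' @return Labeled symmetric matrix of slope genetic correlations.
#' @export
genetic_change_corr_matrix <- function(data, regions = NULL, n_starts = 10,
                                       seed = 1, bilateral = FALSE,
                                       min_pairs = 20) {
  if (is.null(regions)) {
    canon <- region_labels()
    found <- canon[vapply(canon, function(r)
      all(twin_columns(r, bilateral)[1:2] %in% names(data)), logical(1))]
    regions <- if (length(found) >= 2) found else
      stop("cannot infer regions from data columns; pass `regions`")
  }
  k <- length(regions)
  out <- diag(1, k)
  dimnames(out) <- list(regions, regions)
  fits <- list()
  seeds <- derive_seeds(seed, k * k)
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      fit <- fit_bivariate_lcs_ace(data, c(regions[i], regions[j]),
                                   n_starts = n_starts,
                                   seed = seeds[(i - 1) * k + j],
                                   bilateral = bilateral,
                                   min_pairs = min_pairs)
      val <- if (isTRUE(fit$converged) && !isTRUE(fit$rg_unstable))
        fit$rg_slope else NA_real_
      out[i, j] <- out[j, i] <- val
      fits[[paste(regions[i], regions[j], sep = ":")]] <-
        list(rg = fit$rg_slope, converged = fit$converged,
             unstable = isTRUE(fit$rg_unstable), minus2lnL = fit$minus2lnL)
    }
  }
  attr(out, "fits") <- fits
  out
}
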