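#' Symmetrized percent change between two volumes
#'
#' The per-subject change metric: `(v2 - v1) / (v2 + v1) * 100`, a percent
#' change relative to the mean of the two occasions, bounded in (-100, 100)
#' for positive volumes and antisymmetric in its arguments. With
#' `annualize = TRUE` (the default throughout the pipeline) the value is
#' divided by the follow-up interval in years, giving percent per year, so
#' that subjects with heterogeneous intervals are comparable.
#'
#' @param vol_t1,vol_t2 Volumes (mm^3) at the first and last used sessions;
#'   strictly positive. Vectorized.
#' @param interval Follow-up interval in years (> 0; required when
#'   `annualize`).
#' @param annualize Divide by `interval` (default `TRUE`).
#' @return Percent (or percent per year) change.
#' @examples
#' apc(100, 102)              # 0.990 %/yr over a 1-year interval
#' apc(102, 100, interval = 2) # -0.495 %/yr
#' @export
apc <- function(vol_t1, vol_t2, interval = 1, annualize = TRUE) {
  if (any(vol_t1 <= 0) || any(vol_t2 <= 0)) {
    stop("volumes must be strictly positive")
  }
  raw <- (vol_t2 - vol_t1) / (vol_t2 + vol_t1) * 100
  if (!annualize) return(raw)
  if (any(interval <= 0)) stop("interval must be strictly positive")
  raw / interval
}

#' Per-subject change table
#'
#' Computes, for every subject with at least two sessions, the symmetrized
#' percent change of each region between the subject's first and last
#' sessions (intermediate sessions are ignored), together with the interval
#' in years. Single-session subjects are dropped; their count is reported via
#' `message()` and the `"n_dropped"` attribute.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param annualize Divide changes by each subject's interval (default
#'   `TRUE`).
#' @return Data frame with `subject_id`, `interval`, and one APC column per
#'   region; attribute `"regions"` carries the region labels.
#' @export
change_table <- function(cohort, annualize = TRUE) {
  labels <- cohort_regions(cohort)
  split_rows <- split(seq_len(nrow(cohort)), cohort$subject_id)
  multi <- Filter(function(ix) length(ix) >= 2, split_rows)
  n_dropped <- length(split_rows) - length(multi)
  if (length(multi) == 0) stop("no subject has two or more sessions")
  if (n_dropped > 0) {
    message(n_dropped, " single-session subject(s) dropped from change table")
  }
  rows <- lapply(multi, function(ix) {
    first <- ix[1]; last <- ix[length(ix)]   # cohort rows sorted by age
    interval <- cohort$age[last] - cohort$age[first]
    v1 <- as.numeric(cohort[first, labels])
    v2 <- as.numeric(cohort[last, labels])
    c(interval, apc(v1, v2, interval, annualize = annualize))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("interval", labels)
  out <- cbind(subject_id = names(multi), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "regions") <- labels
  attr(out, "n_dropped") <- n_dropped
  attr(out, "annualized") <- annualize
  out
}

#' Change-change correlation matrix
#'
#' Correlates per-region change values across subjects, for every pair of
#' regions, yielding the region-by-region "change-change" matrix on which
#' community detection and matrix comparison operate.
#'
#' @param table Change table (see [change_table()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Labeled symmetric correlation matrix with unit diagonal.
#' @export
change_correlation_matrix <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  labels <- cohort_regions(table)
  x <- as.matrix(table[, labels, drop = FALSE])
  if (nrow(x) < 3) stop("need at least 3 subjects to correlate changes")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero change variance in region(s): ",
         paste(labels[sds == 0], collapse = ", "))
  }
  m <- stats::cor(x, method = method)
  diag(m) <- 1
  labeled_matrix(m, labels, correlation = TRUE)
}

#' De-mean the off-diagonal entries of a correlation matrix
#'
#' Subtracts the mean off-diagonal correlation from every off-diagonal entry
#' and zeroes the diagonal. This removes the global (brain-wide) component of
#' coordinated change before clustering, so that modules reflect covariation
#' beyond the common factor; it is applied to matrices entering community
#' detection but not to matrices entering Mantel comparisons.
#'
#' @param m Labeled symmetric (correlation) matrix.
#' @return Labeled symmetric matrix with zero diagonal and zero-mean
#'   off-diagonal.
#' @export
demean_offdiag <- function(m) {
  off <- row(m) != col(m)
  out <- m
  out[off] <- m[off] - mean(m[off])
  diag(out) <- 0
  labeled_matrix(out, rownames(m), tol = 1e-8)
}
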