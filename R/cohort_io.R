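#' Read and validate a longitudinal volume cohort
#'
#' The cohort is long-format delimited text (comma or tab, auto-detected):
#' one row per MRI session with columns `subject_id`, `session`, `age`
#' (years), `sex`, `icv` (mm^3), optionally `site`, and one column per region
#' in the region set. Hemisphere-specific columns `<region>_lh`/`<region>_rh`
#' are accepted and averaged at read time when `hemi_mean = TRUE`.
#'
#' Validation enforces: all required columns present, volumes and ICV strictly
#' positive, no duplicated (subject, session), and strictly increasing age
#' within subject. Rows are returned sorted by subject then age.
#'
#' @param path File path to the delimited cohort table.
#' @param region_set Region set (see [subcortical_regions()]).
#' @param hemi_mean Average `<region>_lh`/`<region>_rh` columns into a single
#'   bilateral column when per-hemisphere columns are present.
#' @return A `data.frame` with attribute `"regions"` holding the region labels
#'   in canonical order.
#' @export
read_cohort <- function(path, region_set = subcortical_regions(),
                        hemi_mean = TRUE) {
  sep <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  labels <- region_labels(region_set)
  if (hemi_mean) {
    for (lab in labels) {
      lh <- paste0(lab, "_lh"); rh <- paste0(lab, "_rh")
      if (!lab %in% names(df) && all(c(lh, rh) %in% names(df))) {
        df[[lab]] <- (df[[lh]] + df[[rh]]) / 2
        df[[lh]] <- NULL; df[[rh]] <- NULL
      }
    }
  }
  as_cohort(df, region_set)
}

#' Validate a data frame as a longitudinal cohort
#'
#' @param df Data frame with the cohort columns (see [read_cohort()]).
#' @inheritParams read_cohort
#' @return Validated cohort data frame, sorted by subject then age.
#' @export
as_cohort <- function(df, region_set = subcortical_regions()) {
  labels <- region_labels(region_set)
  required <- c("subject_id", "session", "age", "sex", "icv", labels)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  for (col in c("session", "age", "icv", labels)) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]])) {
      stop("non-numeric or missing values in column '", col, "' (row ",
           which(is.na(df[[col]]))[1], ")")
    }
  }
  for (col in c("icv", labels)) {
    bad <- which(df[[col]] <= 0)
    if (length(bad)) {
      stop("non-positive value in column '", col, "' at row ", bad[1],
           " (subject ", df$subject_id[bad[1]], ")")
    }
  }
  if (any(df$age <= 0)) {
    stop("non-positive age at row ", which(df$age <= 0)[1])
  }
  key <- paste(df$subject_id, df$session)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, session) at row ", which(duplicated(key))[1],
         ": ", key[which(duplicated(key))[1]])
  }
  df <- df[order(df$subject_id, df$age), , drop = FALSE]
  rownames(df) <- NULL
  for (sid in unique(df$subject_id)) {
    ages <- df$age[df$subject_id == sid]
    if (length(ages) > 1 && any(diff(ages) <= 0)) {
      stop("ages not strictly increasing for subject ", sid)
    }
  }
  attr(df, "regions") <- labels
  df
}

#' @param cohort Cohort data frame.
#' @param sep Field delimiter (default comma).
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(cohort, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Region labels attached to a cohort or change table
#' @param x Cohort or change table.
#' @return Character vector of region labels.
#' @export
cohort_regions <- function(x) {
  regions <- attr(x, "regions")
  if (is.null(regions)) stop("object carries no region attribute")
  regions
}

#' Split a cohort into developmental and adult/aging subsamples
#'
#' Subjects are assigned by their baseline (first-session) age: strictly below
#' `cutoff` goes to the developmental sample, at or above to the adult/aging
#' sample. A subject's sessions are never split across the two groups.
#'
#' @param cohort Cohort data frame.
#' @param cutoff Age cutoff in years (default 20).
#' @return List with elements `development` and `aging`, each a cohort.
#' @export
split_by_age <- function(cohort, cutoff = 20) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  baseline <- tapply(cohort$age, cohort$subject_id, min)
  dev_ids <- names(baseline)[baseline < cutoff]
  dev <- cohort[cohort$subject_id %in% dev_ids, , drop = FALSE]
  old <- cohort[!cohort$subject_id %in% dev_ids, , drop = FALSE]
  rownames(dev) <- NULL; rownames(old) <- NULL
  attr(dev, "regions") <- attr(cohort, "regions")
  attr(old, "regions") <- attr(cohort, "regions")
  list(development = dev, aging = old)
}

#' Least-squares residualization against covariates
#'
#' Adjusts a response (e.g., a regional volume) for nuisance covariates such
#' as scanner site and intracranial volume by ordinary least squares: an
#' intercept is always included and the residuals are returned. Residuals are
#' orthogonal to every covariate column and the operation is idempotent.
#'
#' @param values Numeric vector, one value per subject.
#' @param covariates Numeric matrix or data frame (rows matching `values`);
#'   factors are expanded to dummy columns.
#' @return Numeric vector of residuals.
#' @export
residualize <- function(values, covariates) {
  values <- as.numeric(values)
  if (is.data.frame(covariates)) {
    covariates <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != length(values)) {
    stop("covariate rows (", nrow(covariates), ") do not match values (",
         length(values), ")")
  }
  # constant columns duplicate the intercept; drop them rather than error
  keep <- apply(covariates, 2, function(x) stats::sd(x) > 0)
  design <- cbind(1, covariates[, keep, drop = FALSE])
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    stop("covariate design is rank deficient (rank ", qr_d$rank, " < ",
         ncol(design), " columns)")
  }
  as.numeric(qr.resid(qr_d, values))
}
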