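#' Construct a labeled symmetric matrix
#'
#' Square symmetric matrices with region labels are the package's exchange
#' currency: change-change correlation matrices, agreement matrices, genetic
#' correlation matrices. Symmetry is enforced by averaging `(m + t(m))/2` when
#' the maximum absolute asymmetry is at most `tol`, and is an error beyond it.
#'
#' @param values Square numeric matrix.
#' @param labels Character vector of row/column labels; defaults to existing
#'   dimnames.
#' @param tol Maximum tolerated absolute asymmetry (default `1e-6`).
#' @param correlation If `TRUE`, off-diagonal entries must lie in `[-1, 1]`.
#' @return A base matrix with matching row/column names, exactly symmetric.
#' @export
labeled_matrix <- function(values, labels = rownames(values), tol = 1e-6,
                           correlation = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("matrix must be square, got ", nrow(values), " x ", ncol(values))
  }
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) stop("label length does not match matrix")
  if (anyDuplicated(labels)) stop("duplicate labels: ",
                                  paste(unique(labels[duplicated(labels)]), collapse = ", "))
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol))
  }
  values <- (values + t(values)) / 2
  if (correlation) {
    off <- values[row(values) != col(values)]
    if (any(off < -1 - 1e-12 | off > 1 + 1e-12)) {
      stop("off-diagonal entries of a correlation matrix must lie in [-1, 1]")
    }
  }
  dimnames(values) <- list(labels, labels)
  values
}

#' Reorder a labeled matrix to a region-set order
#'
#' @param m Labeled symmetric matrix.
#' @param region_set Region set (or label vector) giving the target order;
#'   label sets must agree exactly.
#' @return The matrix with rows and columns permuted to canonical order.
#' @export
align_matrix <- function(m, region_set = subcortical_regions()) {
  labels <- region_labels(region_set)
  have <- rownames(m)
  if (is.null(have)) stop("matrix has no labels")
  missing <- setdiff(labels, have)
  extra <- setdiff(have, labels)
  if (length(missing) || length(extra)) {
    stop("label mismatch; missing: [", paste(missing, collapse = ", "),
         "], unknown: [", paste(extra, collapse = ", "), "]")
  }
  m[labels, labels, drop = FALSE]
}

#' Read / write a labeled square matrix as delimited text
#'
#' The on-disk format is a full square table with a header row and a first
#' label column (comma or tab delimited, auto-detected). On reading, symmetry
#' is enforced within `1e-6` by averaging, and rows/columns are reordered to
#' the region-set order when a region set is supplied.
#'
#' @param path File path.
#' @param region_set Optional region set to align labels to (`NULL` keeps file
#'   order).
#' @param correlation Validate off-diagonals in `[-1, 1]`.
#' @return `read_matrix`: a labeled symmetric matrix.
#' @export
read_matrix <- function(path, region_set = NULL, correlation = FALSE) {
  sep <- detect_delimiter(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) {
    stop("matrix file is not square: ", nrow(m), " rows, ", ncol(m), " columns")
  }
  if (!all(rownames(m) == colnames(m))) {
    if (!setequal(rownames(m), colnames(m))) {
      stop("row and column labels differ in file ", path)
    }
    m <- m[, rownames(m), drop = FALSE]
  }
  m <- labeled_matrix(m, correlation = correlation)
  if (!is.null(region_set)) m <- align_matrix(m, region_set)
  m
}

#' @param m Labeled symmetric matrix to write.
#' @param sep Field delimiter (default comma).
#' @rdname read_matrix
#' @export
write_matrix <- function(m, path, sep = ",") {
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop regions from a labeled matrix
#'
#' Used, e.g., to re-run Mantel tests excluding the ventricular structures.
#'
#' @param m Labeled symmetric matrix.
#' @param drop Character vector of labels to remove.
#' @param min_remaining Minimum number of labels that must remain (default 4,
#'   the smallest size on which a Mantel permutation test is meaningful).
#' @return The submatrix with row/column order otherwise preserved.
#' @export
subset_matrix <- function(m, drop, min_remaining = 4) {
  labels <- rownames(m)
  unknown <- setdiff(drop, labels)
  if (length(unknown)) stop("unknown labels: ", paste(unknown, collapse = ", "))
  keep <- setdiff(labels, drop)
  if (length(keep) < min_remaining) {
    stop("only ", length(keep), " labels would remain; need >= ", min_remaining)
  }
  m[keep, keep, drop = FALSE]
}

#' The four ventricular region labels
#' @return Character vector.
#' @export
ventricle_labels <- function() {
  c("third_ventricle", "fourth_ventricle", "lateral_ventricle",
    "inf_lateral_ventricle")
}

# Guess comma vs tab from the first line of a delimited file.
detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

# Strict upper-triangle values (excluding diagonal) in a fixed order.
upper_tri_values <- function(m) m[upper.tri(m)]
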