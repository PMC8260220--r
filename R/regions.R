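#' Canonical subcortical region set
#'
#' The 16 bilateral (hemisphere-averaged) brain structures used throughout the
#' package, in canonical order, together with region metadata: the reference
#' five-cluster developmental partition and, where meaningful, the embryonic
#' origin and a rank along the cranial vertical axis (0 = most caudal,
#' 4 = most rostral; `NA` for ventricles and cortical white matter, which have
#' no single placement).
#'
#' The order is fixed: all cohorts, change tables, matrices and partitions in
#' the pipeline are aligned to it, so that matrices from different samples are
#' directly comparable entry by entry.
#'
#' @return A data frame with one row per region and columns `label`,
#'   `cluster` (integer reference cluster id), `embryonic_origin` (character),
#'   `cranial_axis_rank` (integer or `NA`).
#' @examples
#' rs <- subcortical_regions()
#' rs$label
#' @export
subcortical_regions <- function() {
  data.frame(
    label = c(
      "third_ventricle", "fourth_ventricle", "lateral_ventricle",
      "inf_lateral_ventricle", "brainstem", "cerebellum_cortex",
      "cerebellum_wm", "thalamus", "hippocampus", "cortical_wm",
      "caudate", "pallidum", "putamen", "accumbens", "amygdala", "cortex"
    ),
    cluster = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L,
                4L, 5L, 3L, 3L, 3L, 3L),
    embryonic_origin = c(
      "prosencephalon_posterior", "rhombencephalon", "prosencephalon_anterior",
      "prosencephalon_anterior", "rhombencephalon", "rhombencephalon",
      "rhombencephalon", "prosencephalon_posterior", "prosencephalon_anterior",
      "prosencephalon_anterior", "prosencephalon_anterior",
      "prosencephalon_anterior", "prosencephalon_anterior",
      "prosencephalon_anterior", "prosencephalon_anterior",
      "prosencephalon_anterior"
    ),
    cranial_axis_rank = c(NA, NA, NA, NA, 0L, 1L, 1L, 2L, 4L, NA,
                          3L, 3L, 3L, 3L, 4L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Region labels of a region set
#'
#' @param region_set A data frame as returned by [subcortical_regions()], or a
#'   character vector of labels.
#' @return Character vector of region labels in canonical order.
#' @export
region_labels <- function(region_set = subcortical_regions()) {
  labels <- if (is.data.frame(region_set)) region_set$label else as.character(region_set)
  if (anyDuplicated(labels)) stop("region labels must be unique")
  labels
}

#' Reference developmental partition of the canonical region set
#'
#' The five-cluster assignment (ventricles; hindbrain/WM/thalamus/hippocampus;
#' cortex-putamen-amygdala-accumbens; caudate; pallidum) used as the planted
#' ground truth by the synthetic-data generator.
#'
#' @param region_set Region set data frame with `label` and `cluster` columns.
#' @return A named integer vector (a partition, see [as_partition()]).
#' @export
reference_partition <- function(region_set = subcortical_regions()) {
  as_partition(stats::setNames(region_set$cluster, region_set$label))
}
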