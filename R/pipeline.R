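#' Pipeline configuration
#'
#' Assembles and validates the configuration for the full analysis:
#' cohort to change tables to correlation matrices to clusters to
#' stability/nulls to matrix comparisons. Either `cohort_path` (a delimited
#' cohort table) or `cohort_spec` (a [cohort_spec()] for a simulated cohort)
#' must be supplied.
#'
#' @param cohort_path Path to a cohort file (see [read_cohort()]), or `NULL`.
#' @param cohort_spec A [cohort_spec()] to simulate from, or `NULL`.
#' @param out_dir Output directory (created if absent).
#' @param age_cutoff Development / adult-aging baseline-age cutoff in years
#'   (default 20).
#' @param annualize Annualize symmetrized percent change (default `TRUE`).
#' @param method Correlation estimator (default `"pearson"`).
#' @param gamma Louvain resolution (default 1).
#' @param modal_runs,consensus_runs,n_null,n_perm Run counts (defaults:
#'   10,000 modal; 1000 consensus; 10,000 nulls; 10,000 Mantel
#'   permutations).
#' @param run_versatility Compute the versatility curve (default `FALSE`;
#'   it is the most expensive stage).
#' @param versatility_args List of overrides passed to
#'   [versatility_curve()].
#' @param seed Master seed.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = NULL, cohort_spec = NULL,
                            out_dir = "covchange_out", age_cutoff = 20,
                            annualize = TRUE, method = "pearson", gamma = 1,
                            modal_runs = 10000, consensus_runs = 1000,
                            n_null = 10000, n_perm = 10000,
                            run_versatility = FALSE,
                            versatility_args = list(), seed = 1) {
  if (is.null(cohort_path) && is.null(cohort_spec)) {
    stop("one of cohort_path or cohort_spec is required")
  }
  counts <- c(modal_runs = modal_runs, consensus_runs = consensus_runs,
              n_null = n_null, n_perm = n_perm)
  bad <- names(counts)[counts < 1]
  if (length(bad)) stop("run counts must be >= 1; offending: ",
                        paste(bad, collapse = ", "))
  if (age_cutoff <= 0) stop("age_cutoff must be positive")
  if (!is.null(cohort_path) && !file.exists(cohort_path)) {
    stop("cohort file not found: ", cohort_path)
  }
  structure(list(cohort_path = cohort_path, cohort_spec = cohort_spec,
                 out_dir = out_dir, age_cutoff = age_cutoff,
                 annualize = annualize, method = method, gamma = gamma,
                 modal_runs = modal_runs, consensus_runs = consensus_runs,
                 n_null = n_null, n_perm = n_perm,
                 run_versatility = run_versatility,
                 versatility_args = versatility_args, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level YAML keys are the arguments of [pipeline_config()]; a
#' `cohort_spec` block holds [cohort_spec()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cohort_spec)) {
    raw$cohort_spec <- do.call(cohort_spec, raw$cohort_spec)
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full change-clustering pipeline
#'
#' Executes every stage on one cohort: reads or simulates the cohort,
#' splits it at the baseline-age cutoff, computes annualized change tables
#' and change-change correlation matrices (raw and de-meaned) for both
#' subsamples, derives the development modal partition and its modularity
#' significance against rewired networks, compares the development and
#' adult/aging matrices (Mantel) and partitions (NMI/VI/zRand null tests),
#' contrasts intra- versus extra-cluster correlations, and optionally
#' computes the versatility curve. All outputs are written to
#' `config$out_dir` as delimited text/JSON, stamped with the configuration
#' hash and master seed; a summary list is returned invisibly.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[covchange] ", sprintf(...))

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_path)) read_cohort(config$cohort_path)
    else simulate_cohort(config$cohort_spec)
  })
  log_msg("cohort: %d rows, %d subjects, %d regions", nrow(cohort),
          length(unique(cohort$subject_id)), length(cohort_regions(cohort)))

  halves <- stage("split_by_age", split_by_age(cohort, config$age_cutoff))
  log_msg("split at %g y: %d development / %d aging subjects",
          config$age_cutoff, length(unique(halves$development$subject_id)),
          length(unique(halves$aging$subject_id)))

  results <- list(config = config)
  matrices <- list()
  for (nm in c("development", "aging")) {
    half <- halves[[nm]]
    if (length(unique(half$subject_id)) < 3) {
      log_msg("subsample '%s' too small; skipped", nm)
      next
    }
    tab <- stage(paste0("change_table_", nm),
                 change_table(half, annualize = config$annualize))
    utils::write.csv(tab, file.path(config$out_dir, paste0("apc_", nm, ".csv")),
                     row.names = FALSE)
    raw <- stage(paste0("correlation_", nm),
                 change_correlation_matrix(tab, method = config$method))
    dem <- demean_offdiag(raw)
    write_matrix(raw, file.path(config$out_dir, paste0("corr_", nm, ".csv")))
    write_matrix(dem, file.path(config$out_dir,
                                paste0("corr_", nm, "_demeaned.csv")))
    matrices[[nm]] <- list(raw = raw, demeaned = dem)
    log_msg("%s: %d subjects in change table (%d dropped)", nm, nrow(tab),
            attr(tab, "n_dropped"))
  }
  results$matrices <- matrices
  if (is.null(matrices$development)) {
    stop("pipeline stage 'clustering' failed: no development matrix")
  }

  dev_dem <- matrices$development$demeaned
  partition <- stage("modal_partition",
                     modal_partition(dev_dem, config$gamma,
                                     n_runs = config$modal_runs,
                                     seed = config$seed))
  results$partition <- partition
  jsonlite::write_json(as.list(partition),
                       file.path(config$out_dir, "partition_development.json"),
                       auto_unbox = TRUE)
  log_msg("development partition: %d modules", n_modules(partition))

  results$q_test <- stage("q_null_test",
                          q_null_test(dev_dem, config$gamma,
                                      n_null = config$n_null,
                                      seed = config$seed + 1,
                                      modal_runs = config$modal_runs))
  log_msg("development Q = %.3f, null band [%.3f, %.3f], p = %.2g",
          results$q_test$observed, results$q_test$percentile_band[1],
          results$q_test$percentile_band[2], results$q_test$p)

  if (!is.null(matrices$aging)) {
    results$mantel_dev_aging <- stage("mantel",
      mantel(matrices$development$raw, matrices$aging$raw,
             n_perm = config$n_perm, seed = config$seed + 2))
    log_msg("Mantel dev vs aging: r = %.3f, p = %.2g",
            results$mantel_dev_aging$r, results$mantel_dev_aging$p)
    results$partition_tests <- lapply(
      stats::setNames(c("nmi", "vi", "zrand"), c("nmi", "vi", "zrand")),
      function(metric) stage(paste0("partition_null_", metric),
        partition_null_test(partition, matrices$aging$demeaned,
                            metric = metric, gamma = config$gamma,
                            n_null = config$n_null,
                            seed = config$seed + 3,
                            modal_runs = config$modal_runs)))
    results$contrasts <- stage("cluster_contrasts",
      cluster_contrast_table(matrices$aging$raw, partition))
    utils::write.csv(results$contrasts,
                     file.path(config$out_dir, "cluster_contrasts_aging.csv"),
                     row.names = FALSE)
  }

  if (isTRUE(config$run_versatility)) {
    results$versatility <- stage("versatility", do.call(
      versatility_curve,
      c(list(w = dev_dem, seed = config$seed + 4), config$versatility_args)))
    utils::write.csv(
      data.frame(gamma = results$versatility$gammas,
                 mean_versatility = results$versatility$mean_versatility,
                 mean_k = results$versatility$mean_k),
      file.path(config$out_dir, "versatility_curve.csv"), row.names = FALSE)
  }

  cfg_file <- file.path(config$out_dir, "config.yaml")
  cfg_out <- config
  cfg_out$cohort_spec <- if (!is.null(config$cohort_spec))
    utils::modifyList(unclass(config$cohort_spec),
                      list(region_set = NULL, target_correlation = NULL,
                           planted_partition = NULL, labels = NULL))
  cfg_list <- lapply(unclass(cfg_out), function(x)
    if (is.atomic(x) || is.list(x)) x else NULL)
  yaml::write_yaml(cfg_list, cfg_file)
  # the hash identifies the analysis (inputs, parameters, seeds), not where
  # its outputs land
  hash_file <- tempfile(fileext = ".yaml")
  cfg_list$out_dir <- NULL
  yaml::write_yaml(cfg_list, hash_file)
  results$config_hash <- unname(tools::md5sum(hash_file))
  unlink(hash_file)

  summary <- list(
    config_hash = results$config_hash, seed = config$seed,
    n_modules = n_modules(partition),
    q_observed = results$q_test$observed,
    q_p = results$q_test$p,
    mantel_r = if (!is.null(results$mantel_dev_aging))
      results$mantel_dev_aging$r else NA,
    mantel_p = if (!is.null(results$mantel_dev_aging))
      results$mantel_dev_aging$p else NA
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
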