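#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates the stages end to end: coverage QC, error filtering,
#' depth-normalized entropy profiling, SMEP standardization, case/control
#' site statistics, iterative ReliefF site selection, and random-forest
#' cross-validation. All stage outputs are written as plain TSV files
#' under `out_dir`, together with a run-metadata file recording the seed,
#' configuration and package version, so a re-run with the same inputs
#' and seed reproduces identical outputs.
#'
#' @param cohort List of `sample_profile` objects (e.g. from
#'   [load_cohort()] or [simulate_cohort()]), or the path of a cohort
#'   manifest TSV.
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; every stochastic stage derives its stream
#'   from it.
#' @param model An [error_model()].
#' @param params A [resample_params()] (its seed is overridden by
#'   `seed`).
#' @param relief_fraction Fraction of sites kept by selection
#'   (default 0.01).
#' @param relief_k,relief_iterations ReliefF neighbors and iterations.
#' @param cfg An [rf_config()].
#' @param n_folds Cross-validation folds (default 10).
#' @param min_coverage QC threshold (default 0.95).
#' @return Invisibly, a list with the QC partition sizes, the cohort
#'   matrix, site statistics, relief weights, selected positions and the
#'   CV report.
#' @export
run_pipeline <- function(cohort, out_dir, seed = 1L,
                         model = error_model(),
                         params = resample_params(),
                         relief_fraction = 0.01, relief_k = 10,
                         relief_iterations = 20,
                         cfg = rf_config(seed = seed), n_folds = 10,
                         min_coverage = 0.95) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  if (length(cohort) == 0) stop("stage qc: empty cohort")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params$seed <- seed

  qc <- qc_filter(cohort, min_coverage)
  utils::write.table(
    data.frame(sample_id = vapply(cohort, function(p) p$sample_id, character(1)),
               fraction_covered = vapply(cohort, function(p)
                 coverage_summary(p)$fraction_covered, numeric(1)),
               kept = vapply(cohort, function(p) p$sample_id, character(1)) %in%
                 vapply(qc$kept, function(p) p$sample_id, character(1))),
    file.path(out_dir, "qc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(qc$kept) == 0) stop("stage qc: no samples pass coverage QC")

  eps <- lapply(qc$kept, function(p) {
    tryCatch(entropy_profile(p, model, params),
             error = function(e) stop(sprintf("stage entropy (sample %s): %s",
                                              p$sample_id, conditionMessage(e))))
  })
  cm <- cohort_matrix(eps)
  utils::write.table(
    data.frame(sample_id = cm$sample_id, group = cm$group, cm$X,
               check.names = FALSE),
    file.path(out_dir, "smep_matrix.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  groups <- unique(cm$group)
  stats_out <- NULL
  if (length(groups) == 2) {
    a <- eps[cm$group == groups[[1]]]
    b <- eps[cm$group == groups[[2]]]
    if (length(a) >= 2 && length(b) >= 2) {
      stats_out <- unpaired_site_tests(a, b)
      utils::write.table(stats_out$sites, file.path(out_dir, "site_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  rw <- NULL; selected <- NULL; cv <- NULL
  if (length(groups) == 2 && min(table(cm$group)) >= 2) {
    rw <- relief_weights(cm, k_neighbors = relief_k,
                         n_iterations = relief_iterations)
    write_relief_table(rw, file.path(out_dir, "relief_weights.tsv"),
                       relief_fraction)
    selected <- top_fraction(rw, relief_fraction)
    if (min(table(cm$group)) >= n_folds) {
      cv <- crossval_classify(cm$X[, selected, drop = FALSE], cm$group,
                              cfg, n_folds, seed = seed)
      utils::write.table(
        data.frame(fold = seq_along(cv$fold_accuracy),
                   accuracy = cv$fold_accuracy),
        file.path(out_dir, "cv_report.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
  }

  meta <- c(
    sprintf("package_version\t%s", as.character(utils::packageVersion("mtentropy"))),
    sprintf("seed\t%d", seed),
    sprintf("n_samples_in\t%d", length(cohort)),
    sprintf("n_samples_kept\t%d", length(qc$kept)),
    sprintf("error_rate\t%g", model$error_rate),
    sprintf("removal_threshold\t%g", model$removal_threshold),
    sprintf("n_resamples\t%d", params$n_resamples),
    sprintf("reads_per_draw\t%d", params$reads_per_draw),
    sprintf("relief_fraction\t%g", relief_fraction),
    sprintf("relief_k\t%d", relief_k),
    sprintf("relief_iterations\t%d", relief_iterations),
    sprintf("rf_trees\t%d", cfg$n_trees),
    sprintf("rf_max_depth\t%d", cfg$max_depth),
    sprintf("n_folds\t%d", n_folds),
    sprintf("min_coverage\t%g", min_coverage))
  writeLines(meta, file.path(out_dir, "run_metadata.tsv"))

  invisible(list(n_kept = length(qc$kept), n_dropped = length(qc$dropped),
                 matrix = cm, site_stats = stats_out, relief = rw,
                 selected = selected, cv = cv))
}
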