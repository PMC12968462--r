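# End-to-end orchestration: a single config object drives all stages and
# every run writes its resolved configuration, a log, and checksums next
# to its outputs, so identical config + inputs give identical outputs.

#' Pipeline configuration
#'
#' @param input_dir Directory containing `series/*.tsv`, `atlas.tsv`, and
#'   optionally `coverage.tsv` and `phenotypes.tsv` (the layout written
#'   by [simulate_fixture()]).
#' @param output_dir Directory for all stage outputs (created if needed).
#' @param tr_seconds Repetition time of the series files.
#' @param window_seconds,step_seconds Sliding-window geometry.
#' @param max_iterations Community-detection iteration cap.
#' @param clip Correlation clip before the Fisher transform.
#' @param coverage_threshold,subject_fraction Voxel-coverage exclusion
#'   rule (see [exclude_low_coverage()]).
#' @param null_runs Surrogate runs per subject; 0 disables the null stage.
#' @param null_mode,phase_mode See [surrogate_spec()].
#' @param family_size Bonferroni family size for the statistics stage.
#' @param run_stats Run the group-statistics stage (needs
#'   `phenotypes.tsv` and both groups).
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            tr_seconds = 1, window_seconds = 60,
                            step_seconds = 10, max_iterations = 1000,
                            clip = 1 - 1e-7, coverage_threshold = 0.30,
                            subject_fraction = 0.10, null_runs = 0,
                            null_mode = "average_series",
                            phase_mode = "multivariate_common_phase",
                            family_size = 4, run_stats = TRUE, seed = 1L) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 tr_seconds = tr_seconds, window_seconds = window_seconds,
                 step_seconds = step_seconds, max_iterations = max_iterations,
                 clip = clip, coverage_threshold = coverage_threshold,
                 subject_fraction = subject_fraction, null_runs = null_runs,
                 null_mode = null_mode, phase_mode = phase_mode,
                 family_size = family_size, run_stats = run_stats,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' JSON round-trip of a [pipeline_config()]; every pipeline run writes
#' its resolved config beside its outputs.
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @return `write_pipeline_config`: `path` invisibly;
#'   `read_pipeline_config`: a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the full time-varying reconfiguration pipeline
#'
#' Stages: (1) read and validate inputs; (2) voxel-coverage region
#' exclusion; (3) per subject, windowed connectivity, community
#' detection and reconfiguration metrics via [reconfig()]; (4) optional
#' surrogate nulls; (5) group statistics (metric-fatigue correlations,
#' covariate-adjusted group comparison, and a null-adjusted comparison
#' when nulls were run).  Outputs are written under
#' `config$output_dir`: per-subject assignment and metric TSVs, a
#' subject-summary TSV, statistics TSVs, a log, MD5 checksums and the
#' resolved config.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summaries`, `null_summaries`,
#'   `stats` and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (d in c("assignments", "metrics", "stats"))
    dir.create(file.path(out, d), showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  atlas <- stage("inputs", read_atlas(file.path(config$input_dir, "atlas.tsv")))
  series_files <- sort(list.files(file.path(config$input_dir, "series"),
                                  pattern = "\\.tsv$", full.names = TRUE))
  if (!length(series_files)) stopf("stage 'inputs' failed: no series files")

  retained <- names(atlas)
  cov_path <- file.path(config$input_dir, "coverage.tsv")
  if (file.exists(cov_path)) {
    coverage <- read_coverage(cov_path)
    retained <- stage("coverage",
                      exclude_low_coverage(coverage,
                                           config$coverage_threshold,
                                           config$subject_fraction))
    log("coverage filter: %d of %d regions retained",
        length(retained), ncol(coverage))
  }
  atlas <- atlas[names(atlas) %in% retained]

  spec <- window_spec(config$window_seconds, config$step_seconds)
  summaries <- list(); null_summaries <- list()
  for (f in series_files) {
    series <- stage(paste0("read:", basename(f)),
                    read_series(f, tr_seconds = config$tr_seconds))
    keep <- region_ids(series) %in% names(atlas)
    series <- parcellated_series(series$signals[keep, , drop = FALSE],
                                 tr_seconds = series$tr_seconds,
                                 subject_id = series$subject_id)
    fit <- stage(paste0("reconfig:", series$subject_id),
                 reconfig(series, atlas,
                          window_seconds = config$window_seconds,
                          step_seconds = config$step_seconds,
                          max_iterations = config$max_iterations,
                          clip = config$clip))
    tr <- attr(fit$assignments, "trace")
    log("subject %s: %d x %d assignments, %.1f detection iterations/window, %d/%d converged",
        fit$subject_id, nrow(fit$assignments), ncol(fit$assignments),
        mean(tr$iterations), sum(tr$converged), nrow(tr))
    write_assignments(fit$assignments,
                      file.path(out, "assignments",
                                paste0(fit$subject_id, ".tsv")))
    write_metrics(fit$node_metrics, atlas,
                  file.path(out, "metrics", paste0(fit$subject_id, ".tsv")))
    summaries[[fit$subject_id]] <-
      data.frame(subject_id = fit$subject_id, t(fit$global),
                 stringsAsFactors = FALSE)
    if (config$null_runs > 0) {
      nul <- stage(paste0("null:", series$subject_id),
                   build_null(series, atlas,
                              surrogate_spec(n_runs = config$null_runs,
                                             mode = config$null_mode,
                                             phase_mode = config$phase_mode,
                                             seed = config$seed),
                              window = spec, clip = config$clip,
                              max_iterations = config$max_iterations))
      null_summaries[[fit$subject_id]] <-
        data.frame(subject_id = fit$subject_id, t(nul$global),
                   stringsAsFactors = FALSE)
    }
  }
  summaries <- do.call(rbind, c(summaries, make.row.names = FALSE))
  write_tsv(summaries, file.path(out, "subject_summaries.tsv"),
            params = list(window_seconds = config$window_seconds,
                          step_seconds = config$step_seconds))
  if (length(null_summaries)) {
    null_summaries <- do.call(rbind, c(null_summaries, make.row.names = FALSE))
    nul_out <- null_summaries
    names(nul_out)[-1] <- paste0("null_", names(nul_out)[-1])
    write_tsv(nul_out, file.path(out, "null_summaries.tsv"),
              params = list(n_runs = config$null_runs, mode = config$null_mode,
                            phase_mode = config$phase_mode, seed = config$seed))
  } else null_summaries <- NULL

  stats_out <- NULL
  phen_path <- file.path(config$input_dir, "phenotypes.tsv")
  if (config$run_stats && file.exists(phen_path)) {
    phen <- read_phenotypes(phen_path)
    stats_out <- stage("stats", {
      corr <- correlate_metrics_fatigue(summaries, phen,
                                        family_size = config$family_size)
      anc <- group_comparison_ancova(summaries, phen,
                                     family_size = config$family_size)
      res <- list(correlations = corr, ancova = anc)
      if (!is.null(null_summaries))
        res$null_adjusted <- null_adjusted_group_test(summaries, null_summaries,
                                                      phen,
                                                      family_size = config$family_size)
      res
    })
    write_tsv(stats_out$correlations, file.path(out, "stats", "correlations.tsv"))
    write_tsv(stats_out$ancova, file.path(out, "stats", "ancova.tsv"))
    if (!is.null(stats_out$null_adjusted))
      write_tsv(stats_out$null_adjusted,
                file.path(out, "stats", "null_adjusted_ancova.tsv"))
    log("stats: %d correlation cells, %d ANCOVA rows",
        nrow(stats_out$correlations), nrow(stats_out$ancova))
  }

  write_pipeline_config(config, file.path(out, "config.json"))
  writeLines(log_lines, file.path(out, "pipeline.log"))
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("checksums\\.txt$", files)]
  sums <- tools::md5sum(files)
  writeLines(paste(unname(sums), substring(files, nchar(out) + 2)),
             file.path(out, "checksums.txt"))
  invisible(list(summaries = summaries, null_summaries = null_summaries,
                 stats = stats_out, output_dir = out))
}
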