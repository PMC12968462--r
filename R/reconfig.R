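#' Fit the time-varying reconfiguration pipeline to one subject
#'
#' The central fitting function of the package.  Given a parcellated BOLD
#' series and an atlas of literature-based network labels it (1) segments
#' the scan into sliding windows, (2) builds the absolute Fisher-z
#' connectivity matrix of every window, (3) reassigns regions to networks
#' per window by iterative quality-driven reallocation seeded from the
#' atlas, and (4) derives node-level promiscuity, flexibility, cohesion
#' and disjointedness with global and per-network summaries.
#'
#' @param series A [parcellated_series()] (or a numeric matrix, regions x
#'   timepoints, in which case `tr_seconds` must be given).
#' @param atlas Named character vector mapping every region of `series`
#'   to one of the eight networks (see [read_atlas()]).
#' @param window_seconds,step_seconds Sliding-window geometry in seconds
#'   (defaults 60 and 10).
#' @param max_iterations Per-window cap on detection iterations.
#' @param clip Correlation clip applied before the Fisher transform.
#' @param tr_seconds Repetition time, only used when `series` is a bare
#'   matrix.
#' @return An object of class `reconfig`: list with elements
#'   `assignments` (regions x windows `assignment_matrix`),
#'   `connectivity` (`windowed_connectivity`), `node_metrics`
#'   (per-node data frame), `global`, `network` (aggregates), `atlas`,
#'   `spec` and `subject_id`.  Methods: `print`, `summary`, `coef`
#'   (global metric vector), `plot`.
#' @export
#' @examples
#' truth <- plant_truth(example_atlas(24), n_windows = 7, seed = 1)
#' x <- generate_subject(truth, n_timepoints = 120, seed = 1)
#' fit <- reconfig(x, truth$atlas)
#' coef(fit)
reconfig <- function(series, atlas, window_seconds = 60, step_seconds = 10,
                     max_iterations = 1000, clip = 1 - 1e-7,
                     tr_seconds = NULL) {
  if (is.matrix(series)) {
    if (is.null(tr_seconds))
      stopf("'tr_seconds' is required when 'series' is a bare matrix")
    series <- parcellated_series(series, tr_seconds = tr_seconds)
  }
  stopifnot(inherits(series, "parcellated_series"))
  validate_atlas(atlas, regions = region_ids(series))
  spec <- window_spec(window_seconds, step_seconds)
  wc <- windowed_correlation(series, spec, clip = clip)
  assignments <- detect_all(wc, atlas, max_iterations = max_iterations)
  node_metrics <- reconfig_metrics(assignments)
  agg <- aggregate_metrics(node_metrics, atlas)
  structure(
    list(subject_id = series$subject_id,
         assignments = assignments,
         connectivity = wc,
         node_metrics = node_metrics,
         global = agg$global,
         network = agg$network,
         atlas = atlas,
         spec = spec),
    class = "reconfig"
  )
}

#' @export
print.reconfig <- function(x, digits = 3, ...) {
  cat(sprintf("Time-varying reconfiguration fit: subject '%s'\n", x$subject_id))
  cat(sprintf("  %d regions x %d windows, %d communities (window %g s, step %g s)\n",
              nrow(x$assignments), ncol(x$assignments),
              length(attr(x$assignments, "communities")),
              x$spec$window_seconds, x$spec$step_seconds))
  cat("  Global metrics:\n")
  print(round(x$global, digits))
  invisible(x)
}

#' @export
summary.reconfig <- function(object, ...) {
  structure(list(fit = object), class = "summary.reconfig")
}

#' @export
print.summary.reconfig <- function(x, digits = 3, ...) {
  fit <- x$fit
  print(fit, digits = digits)
  cat("\n  Per-network means:\n")
  print(round(fit$network, digits))
  tr <- attr(fit$assignments, "trace")
  if (!is.null(tr))
    cat(sprintf("\n  Detection: %.1f iterations/window on average, %d/%d windows converged\n",
                mean(tr$iterations), sum(tr$converged), nrow(tr)))
  invisible(x)
}

#' @export
coef.reconfig <- function(object, ...) object$global

#' Plot a reconfiguration fit
#'
#' Left panel: the assignment matrix as an image (regions x windows,
#' coloured by community).  Right panel: per-network flexibility.
#'
#' @param x A `reconfig` object.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.reconfig <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  K <- length(attr(x$assignments, "communities"))
  graphics::image(t(unclass(x$assignments)), axes = FALSE,
                  col = grDevices::hcl.colors(K, "Spectral"),
                  xlab = "window", ylab = "region",
                  main = "Community assignments", ...)
  flex <- x$network[, "flexibility"]
  graphics::barplot(flex, las = 2, ylab = "flexibility",
                    main = "Per-network flexibility")
  invisible(x)
}

# One-subject pipeline on an existing windowed_connectivity (used by the
# surrogate machinery so nulls share code with the real-data path).
metrics_from_series <- function(series, atlas, spec, clip = 1 - 1e-7,
                                max_iterations = 1000) {
  wc <- windowed_correlation(series, spec, clip = clip)
  assignments <- detect_all(wc, atlas, max_iterations = max_iterations)
  node_metrics <- reconfig_metrics(assignments)
  agg <- aggregate_metrics(node_metrics, atlas)
  list(assignments = assignments, node_metrics = node_metrics,
       global = agg$global, network = agg$network)
}
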