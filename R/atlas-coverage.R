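# Atlas labels, coverage tables and the voxel-coverage exclusion filter.

#' Read an atlas label table
#'
#' Two-column TSV mapping each region to one of the eight canonical
#' resting-state networks (see [rsn_networks()]).
#'
#' @param path Path to a TSV with columns `region_id` and `network`.
#' @return Named character vector: names are region ids, values network
#'   labels.
#' @export
read_atlas <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2) stopf("atlas file '%s' needs two columns", path)
  atlas <- as.character(df[[2]])
  names(atlas) <- as.character(df[[1]])
  validate_atlas(atlas)
  atlas
}

#' Write an atlas label table
#'
#' @param atlas Named character vector (region id -> network label).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  write_tsv(data.frame(region_id = names(atlas), network = unname(atlas),
                       stringsAsFactors = FALSE), path)
}

validate_atlas <- function(atlas, regions = NULL) {
  if (is.null(names(atlas)) || anyDuplicated(names(atlas)))
    stopf("atlas must be a named vector with unique region ids")
  unknown <- setdiff(unique(atlas), rsn_networks())
  if (length(unknown))
    stopf("unknown network label%s: %s", if (length(unknown) > 1) "s" else "",
          paste(unknown, collapse = ", "))
  if (!is.null(regions)) {
    missing <- setdiff(regions, names(atlas))
    if (length(missing))
      stopf("atlas lacks label%s for region%s %s",
            if (length(missing) > 1) "s" else "",
            if (length(missing) > 1) "s" else "",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  invisible(atlas)
}

#' Read / write a region voxel-coverage table
#'
#' Subjects-by-regions table of voxel-coverage fractions in \[0, 1\]:
#' the proportion of each parcel's voxels retaining usable signal for a
#' subject.  First column is the subject id; remaining columns are regions.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, subjects x regions, with dimnames.
#' @export
read_coverage <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stopf("coverage fractions must lie in [0, 1]")
  m
}

#' @rdname read_coverage
#' @param coverage Subjects x regions matrix of fractions in \[0, 1\].
#' @export
write_coverage <- function(coverage, path) {
  df <- data.frame(subject_id = rownames(coverage), coverage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Exclude regions with insufficient voxel coverage
#'
#' A region is dropped when it has coverage below `coverage_threshold` in
#' strictly more than `subject_fraction` of subjects; with the defaults,
#' regions with < 30% voxel coverage in more than 10% of all participants
#' are excluded.  The boundary cases follow the rule literally: a region
#' failing in exactly 10% of subjects is retained, and coverage exactly at
#' the threshold does not count as failing.
#'
#' @param coverage Subjects x regions numeric matrix of fractions in
#'   \[0, 1\] (as from [read_coverage()]).
#' @param coverage_threshold Coverage below which a subject counts as a
#'   failure for that region (default 0.30).
#' @param subject_fraction Maximum tolerated fraction of failing subjects
#'   (default 0.10).
#' @return Character vector of retained region ids, in input column order.
#' @export
#' @examples
#' cov <- matrix(1, 5, 4, dimnames = list(NULL, paste0("r", 1:4)))
#' cov[1:2, "r3"] <- 0.1   # fails in 40% of subjects -> excluded
#' exclude_low_coverage(cov)
exclude_low_coverage <- function(coverage, coverage_threshold = 0.30,
                                 subject_fraction = 0.10) {
  if (!is.matrix(coverage) || nrow(coverage) == 0 || ncol(coverage) == 0)
    stopf("'coverage' must be a non-empty subjects x regions matrix")
  if (is.null(colnames(coverage)))
    colnames(coverage) <- paste0("region_", seq_len(ncol(coverage)))
  fail_frac <- colMeans(coverage < coverage_threshold)
  retained <- fail_frac <= subject_fraction
  colnames(coverage)[retained]
}
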