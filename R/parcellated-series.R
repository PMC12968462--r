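#' Parcellated BOLD time series
#'
#' Container for one subject's region-by-timepoint signal matrix, the raw
#' input of the reconfiguration pipeline.  Rows are brain regions (parcels),
#' columns are fMRI volumes acquired every `tr_seconds` seconds.
#'
#' @param signals Numeric matrix, regions x timepoints.  Row names are used
#'   as region identifiers when `region_ids` is not given.
#' @param tr_seconds Positive scalar, repetition time in seconds.
#' @param subject_id Subject identifier string.
#' @param region_ids Character vector of unique region identifiers aligned
#'   with the rows of `signals`.
#' @return An object of class `parcellated_series`: a list with elements
#'   `subject_id`, `signals` (with region ids as row names) and
#'   `tr_seconds`.
#' @export
#' @examples
#' x <- parcellated_series(matrix(rnorm(30), 3, 10), tr_seconds = 1,
#'                         region_ids = c("r1", "r2", "r3"))
#' x
parcellated_series <- function(signals, tr_seconds, subject_id = "subject",
                               region_ids = rownames(signals)) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stopf("'signals' must be a numeric matrix (regions x timepoints)")
  if (ncol(signals) < 2)
    stopf("a parcellated series needs at least 2 timepoints, got %d", ncol(signals))
  if (anyNA(signals) || any(!is.finite(signals)))
    stopf("'signals' contains missing or non-finite values")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stopf("'tr_seconds' must be a single positive number")
  if (is.null(region_ids)) region_ids <- paste0("region_", seq_len(nrow(signals)))
  region_ids <- as.character(region_ids)
  if (length(region_ids) != nrow(signals))
    stopf("%d region ids for %d signal rows", length(region_ids), nrow(signals))
  dup <- region_ids[duplicated(region_ids)]
  if (length(dup))
    stopf("duplicate region ids: %s", paste(unique(dup), collapse = ", "))
  rownames(signals) <- region_ids
  colnames(signals) <- NULL
  structure(
    list(subject_id = as.character(subject_id)[1],
         signals = signals,
         tr_seconds = as.numeric(tr_seconds)),
    class = "parcellated_series"
  )
}

#' @export
print.parcellated_series <- function(x, ...) {
  cat(sprintf("<parcellated_series> subject '%s': %d regions x %d timepoints, TR = %g s\n",
              x$subject_id, nrow(x$signals), ncol(x$signals), x$tr_seconds))
  invisible(x)
}

n_regions <- function(x) nrow(x$signals)
n_timepoints <- function(x) ncol(x$signals)
region_ids <- function(x) rownames(x$signals)

#' Read a parcellated time-series table
#'
#' Reads a delimited text table of BOLD signals.  The canonical layout has
#' regions as rows with the region identifier in the first column and one
#' column per timepoint; the transposed layout (timepoints as rows) is
#' recognised automatically and can be forced with `orientation`.
#'
#' @param path Path to a TSV/CSV file.  Lines starting with `#` are ignored.
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id Subject identifier; defaults to the file name.
#' @param orientation `"auto"` (decide from the header), `"regions_in_rows"`
#'   or `"regions_in_cols"`.
#' @param sep Field separator, `"\t"` by default (use `","` for CSV).
#' @return A [parcellated_series()].  Regions whose signal is constant over
#'   the whole series are permitted but flagged with a warning; the
#'   correlation step rejects them where the arithmetic actually breaks.
#' @export
read_series <- function(path, tr_seconds, subject_id = NULL,
                        orientation = c("auto", "regions_in_rows", "regions_in_cols"),
                        sep = "\t") {
  orientation <- match.arg(orientation)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]+$", "", basename(path))
  fields <- utils::count.fields(path, sep = sep, comment.char = "#")
  if (length(unique(fields)) > 1)
    stopf("ragged table in '%s': rows have %s fields", path,
          paste(unique(fields), collapse = "/"))
  df <- utils::read.delim(path, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("'%s' has fewer than 2 columns", path)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stopf("non-numeric cells in '%s' (column%s %s)", path,
          if (sum(bad) > 1) "s" else "", paste(names(vals)[bad], collapse = ", "))
  mat <- as.matrix(vals)
  if (orientation == "auto") {
    first_name <- tolower(names(df)[1])
    orientation <- if (first_name %in% c("time", "timepoint", "t", "volume"))
      "regions_in_cols" else "regions_in_rows"
  }
  if (orientation == "regions_in_cols") {
    mat <- t(mat)
    region <- colnames(vals)
    rownames(mat) <- region
  } else {
    dup <- ids[duplicated(ids)]
    if (length(dup))
      stopf("duplicate region id%s in '%s': %s",
            if (length(unique(dup)) > 1) "s" else "", path,
            paste(unique(dup), collapse = ", "))
    rownames(mat) <- ids
  }
  const <- apply(mat, 1, function(r) max(r) == min(r))
  if (any(const))
    warnf("constant signal in region%s %s",
          if (sum(const) > 1) "s" else "",
          paste(rownames(mat)[const], collapse = ", "))
  parcellated_series(mat, tr_seconds = tr_seconds, subject_id = subject_id)
}

#' Write a parcellated time-series table
#'
#' Writes the canonical regions-in-rows TSV layout read by [read_series()]:
#' first column `region_id`, remaining columns `t1 ... tN`, preceded by a
#' commented provenance line.
#'
#' @param x A [parcellated_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  stopifnot(inherits(x, "parcellated_series"))
  df <- data.frame(region_id = region_ids(x), x$signals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("region_id", paste0("t", seq_len(n_timepoints(x))))
  write_tsv(df, path, params = list(tr_seconds = x$tr_seconds,
                                    subject = x$subject_id))
}
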