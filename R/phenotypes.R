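# Subject phenotype table: group membership, fatigue scores (FSMC scale),
# demographics, and - for the patient group - clinical and structural fields.

phenotype_columns <- function() {
  c("subject_id", "group", "fatigue_total", "fatigue_motor",
    "fatigue_cognitive", "age", "sex", "education", "edss",
    "disease_duration", "dmt", "nbv", "t2_ll")
}

#' Dispensed disease-modifying treatment categories
#'
#' The nine treatment categories used in the phenotype table; `"none"` is
#' the reference category in regression models.
#'
#' @return Character vector of length 9.
#' @export
dmt_categories <- function() {
  c("none", "dimethyl_fumarate", "fingolimod", "glatiramer", "interferon",
    "natalizumab", "ocrelizumab", "siponimod", "teriflunomid")
}

#' Read / write a subject phenotype table
#'
#' TSV with one row per subject.  Expected columns: `subject_id`, `group`
#' (`pwMS` or `HC`), `fatigue_total` (FSMC total, maximum 100),
#' `fatigue_motor` and `fatigue_cognitive` (maxima 50), `age`, `sex`
#' (0/1), `education` (years), and - possibly missing for healthy
#' controls - `edss`, `disease_duration`, `dmt` (one of
#' [dmt_categories()]), `nbv` and `t2_ll` (cm^3).
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with validated columns.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv(path)
  validate_phenotypes(df)
}

#' @rdname read_phenotypes
#' @param phenotypes Phenotype `data.frame`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  validate_phenotypes(phenotypes)
  write_tsv(phenotypes, path)
}

validate_phenotypes <- function(df) {
  need <- c("subject_id", "group")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("phenotype table lacks column%s %s",
          if (length(missing) > 1) "s" else "", paste(missing, collapse = ", "))
  if (nrow(df) == 0) stopf("phenotype table is empty")
  bad_group <- setdiff(unique(df$group), c("pwMS", "HC"))
  if (length(bad_group))
    stopf("unknown group label%s: %s", if (length(bad_group) > 1) "s" else "",
          paste(bad_group, collapse = ", "))
  if ("fatigue_total" %in% names(df) &&
      any(df$fatigue_total > 100 | df$fatigue_total < 0, na.rm = TRUE))
    stopf("fatigue_total must lie in [0, 100]")
  for (col in c("fatigue_motor", "fatigue_cognitive"))
    if (col %in% names(df) && any(df[[col]] > 50 | df[[col]] < 0, na.rm = TRUE))
      stopf("%s must lie in [0, 50]", col)
  if ("dmt" %in% names(df)) {
    bad <- setdiff(unique(stats::na.omit(df$dmt)), dmt_categories())
    if (length(bad))
      stopf("unknown DMT categor%s: %s", if (length(bad) > 1) "ies" else "y",
            paste(bad, collapse = ", "))
  }
  df
}
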