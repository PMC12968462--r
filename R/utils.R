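# Internal helpers shared across the package.

#' Canonical resting-state network labels
#'
#' The eight network labels used throughout the package: seven
#' literature-based cortical resting-state networks (default mode,
#' fronto-parietal, dorsal attention, ventral attention, visual,
#' sensorimotor, limbic) plus one deep grey matter group.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' rsn_networks()
rsn_networks <- function() {
  c("DMN", "FPN", "DAN", "VAN", "VN", "SMN", "LN", "DGM")
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Commented provenance line placed at the top of every file the package
# writes: records the package version and the parameters of the run.
provenance_line <- function(params = list()) {
  ver <- as.character(utils::packageVersion("netreconfig"))
  extra <- if (length(params)) {
    paste0("; ", paste(names(params), unlist(params), sep = "=", collapse = "; "))
  } else ""
  paste0("# netreconfig ", ver, extra)
}

write_tsv <- function(df, path, params = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_line(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
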