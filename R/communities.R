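# Per-window community detection: iterative reassignment of regions to
# networks, seeded from literature-based resting-state labels.

check_weights <- function(weights) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stopf("'weights' must be a square matrix")
  if (any(weights < 0)) stopf("'weights' must be nonnegative")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-12)))
    stopf("'weights' must be symmetric")
  invisible(weights)
}

# Mean connectivity of every region to every community, excluding self.
# labels: integer vector in 1..K.  Returns regions x K matrix; communities
# in which a region has no *other* member give -Inf.
community_means <- function(weights, labels, K) {
  n <- nrow(weights)
  M <- matrix(0, n, K)
  M[cbind(seq_len(n), labels)] <- 1
  sums <- weights %*% M                     # diagonal is 0, so self drops out
  counts <- matrix(tabulate(labels, K), n, K, byrow = TRUE)
  counts <- counts - M                      # exclude self from own community
  means <- ifelse(counts > 0, sums / pmax(counts, 1), -Inf)
  means
}

# Assignment quality of every region: mean connectivity to its own
# community minus the best mean connectivity to any other community.
quality_all <- function(means, labels) {
  n <- nrow(means)
  own <- means[cbind(seq_len(n), labels)]
  tmp <- means
  tmp[cbind(seq_len(n), labels)] <- -Inf
  best_other <- apply(tmp, 1, max)
  q <- own - best_other
  # own community has no other member -> quality -Inf by convention
  q[own == -Inf] <- -Inf
  q
}

#' Assignment quality of a region
#'
#' How well a region is embedded in its current community: the mean edge
#' weight from the region to the other members of its own community minus
#' the maximal mean weight to any other community.  Positive values mean
#' the region is better connected to its own community than to any
#' alternative; a region alone in its community has quality `-Inf`.
#'
#' @param weights Symmetric nonnegative region x region matrix with zero
#'   diagonal (one window's connectivity).
#' @param labels Integer vector of community labels in `1..K`, one per
#'   region.
#' @param region Region index (or `NULL` to return the quality of every
#'   region).
#' @param K Number of communities (defaults to `max(labels)`).
#' @return Numeric scalar (or vector if `region` is `NULL`).
#' @export
assignment_quality <- function(weights, labels, region = NULL, K = max(labels)) {
  check_weights(weights)
  labels <- as.integer(labels)
  if (length(labels) != nrow(weights))
    stopf("%d labels for %d regions", length(labels), nrow(weights))
  q <- quality_all(community_means(weights, labels, K), labels)
  if (is.null(region)) return(q)
  if (!is.numeric(region) || region < 1 || region > nrow(weights))
    stopf("region index %s out of range 1..%d", as.character(region), nrow(weights))
  q[region]
}

#' Detect communities in one window
#'
#' Iterative reassignment seeded from the initial (literature-based)
#' labels: at each iteration the region with the lowest assignment quality
#' is selected (ties broken by lowest region index) and reallocated to the
#' community with which it has maximal mean connectivity (on ties the
#' current label is kept if tied, otherwise the lowest community index
#' wins).  Iteration stops when the same region is selected in two
#' consecutive iterations - the saturation point of the optimisation -
#' or when a reallocation changes nothing, or at `max_iterations`.  No new
#' communities are created: labels are drawn from the initial label set,
#' and a community emptied by a move simply becomes an unused label.
#'
#' @inheritParams assignment_quality
#' @param initial_labels Integer vector of seed labels in `1..K`.
#' @param max_iterations Hard iteration cap (default 1000).
#' @return List with `labels` (final integer labels), `converged`
#'   (logical) and `trace` (data.frame with one row per iteration:
#'   `iteration`, `region`, `old`, `new`, `quality`).
#' @export
detect_window_communities <- function(weights, initial_labels,
                                      K = max(initial_labels),
                                      max_iterations = 1000) {
  check_weights(weights)
  labels <- as.integer(initial_labels)
  if (length(labels) != nrow(weights))
    stopf("%d initial labels for %d regions", length(labels), nrow(weights))
  if (any(labels < 1 | labels > K))
    stopf("initial labels must lie in 1..%d", K)
  n <- nrow(weights)
  means <- community_means(weights, labels, K)
  trace <- vector("list", 0L)
  prev_selected <- NA_integer_
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    q <- quality_all(means, labels)
    sel <- which.min(q)                      # ties -> lowest index
    cand <- means[sel, ]
    best <- max(cand)
    tied <- which(cand == best)
    new_label <- if (labels[sel] %in% tied) labels[sel] else min(tied)
    old_label <- labels[sel]
    trace[[iter]] <- data.frame(iteration = iter, region = sel,
                                old = old_label, new = new_label,
                                quality = q[sel])
    if (new_label != old_label) {
      labels[sel] <- new_label
      # incremental update: only the two touched communities change
      means[, old_label] <- recompute_mean(weights, labels, old_label)
      means[, new_label] <- recompute_mean(weights, labels, new_label)
    }
    if (!is.na(prev_selected) && sel == prev_selected) { converged <- TRUE; break }
    if (new_label == old_label) { converged <- TRUE; break }
    prev_selected <- sel
  }
  list(labels = labels, converged = converged,
       trace = do.call(rbind, trace))
}

recompute_mean <- function(weights, labels, k) {
  members <- which(labels == k)
  n <- nrow(weights)
  out <- rep(-Inf, n)
  if (length(members) == 0) return(out)
  sums <- if (length(members) == 1) weights[, members]
          else rowSums(weights[, members, drop = FALSE])
  counts <- length(members) - (labels == k)   # exclude self
  ifelse(counts > 0, sums / pmax(counts, 1), -Inf)
}

#' Detect communities in every window
#'
#' Runs [detect_window_communities()] independently on each window of a
#' [windowed_correlation()] result, every window seeded afresh from the
#' literature-based atlas labels, and collects the final labels into the
#' regions x windows assignment matrix that all reconfiguration metrics
#' read.
#'
#' @param wc A `windowed_connectivity` object.
#' @param atlas Named character vector mapping the regions of `wc` to
#'   network labels (see [read_atlas()]), or an integer vector of seed
#'   labels.
#' @param max_iterations Per-window iteration cap.
#' @return An object of class `assignment_matrix`: integer matrix
#'   (regions x windows) with attributes `communities` (the label legend)
#'   and `trace` (per-window iteration counts and convergence flags).
#' @export
detect_all <- function(wc, atlas, max_iterations = 1000) {
  stopifnot(inherits(wc, "windowed_connectivity"))
  ids <- wc$region_ids
  if (is.character(atlas)) {
    validate_atlas(atlas, regions = ids)
    communities <- rsn_networks()[rsn_networks() %in% unique(atlas)]
    init <- match(atlas[ids], communities)
  } else {
    init <- as.integer(atlas)
    if (length(init) != length(ids))
      stopf("%d seed labels for %d regions", length(init), length(ids))
    communities <- as.character(seq_len(max(init)))
  }
  K <- length(communities)
  W <- dim(wc$weights)[3]
  out <- matrix(NA_integer_, length(ids), W, dimnames = list(ids, NULL))
  iters <- integer(W); conv <- logical(W)
  for (k in seq_len(W)) {
    res <- detect_window_communities(wc$weights[, , k], init, K = K,
                                     max_iterations = max_iterations)
    out[, k] <- res$labels
    iters[k] <- if (is.null(res$trace)) 0L else nrow(res$trace)
    conv[k] <- res$converged
  }
  structure(out, class = c("assignment_matrix", class(out)),
            communities = communities,
            trace = data.frame(window = seq_len(W), iterations = iters,
                               converged = conv))
}

#' @export
print.assignment_matrix <- function(x, ...) {
  cat(sprintf("<assignment_matrix> %d regions x %d windows, %d communities (%s)\n",
              nrow(x), ncol(x), length(attr(x, "communities")),
              paste(attr(x, "communities"), collapse = ", ")))
  invisible(x)
}

#' Read / write an assignment matrix
#'
#' TSV with regions as rows and windows as columns, integer community
#' labels, plus commented legend lines mapping each integer to its
#' network name.
#'
#' @param assignments An `assignment_matrix` (from [detect_all()]).
#' @param path File path.
#' @return `write_assignments`: `path` invisibly; `read_assignments`: an
#'   `assignment_matrix`.
#' @export
write_assignments <- function(assignments, path) {
  communities <- attr(assignments, "communities")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_line(), con)
  writeLines(paste0("# legend: ", paste(seq_along(communities), communities,
                                        sep = "=", collapse = "; ")), con)
  df <- data.frame(region_id = rownames(assignments),
                   unclass(assignments), check.names = FALSE)
  names(df) <- c("region_id", paste0("w", seq_len(ncol(assignments))))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  lines <- readLines(path, n = 10)
  legend <- grep("^# legend:", lines, value = TRUE)
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  colnames(m) <- NULL
  communities <- as.character(seq_len(max(m)))
  if (length(legend)) {
    parts <- strsplit(sub("^# legend: ", "", legend[1]), "; ")[[1]]
    kv <- strsplit(parts, "=")
    communities <- vapply(kv, `[`, "", 2)
  }
  structure(m, class = c("assignment_matrix", class(m)),
            communities = communities)
}
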