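# Node-level reconfiguration metrics computed on the assignment matrix:
# promiscuity, flexibility, and the cohesion/disjointedness split of
# flexible switches into mutual and independent reconfigurations.

#' Promiscuity of a node
#'
#' Fraction of all available communities a node is assigned to at least
#' once across windows: `(#distinct labels) / K`.  The denominator is the
#' total number of communities K (8 networks by default in the pipeline),
#' whether or not every community is used in a given subject's windows,
#' so a node that never switches still has promiscuity `1/K`.
#'
#' @param node_row Integer vector of community labels over windows.
#' @param K Total number of communities.
#' @return Numeric scalar in `[1/K, 1]`.
#' @export
#' @examples
#' promiscuity(c(1, 2, 1, 3), K = 4)  # 3 of 4 networks -> 0.75
promiscuity <- function(node_row, K) {
  node_row <- as.integer(node_row)
  if (length(node_row) < 1) stopf("empty label sequence")
  if (K < 1) stopf("'K' must be >= 1")
  if (any(node_row < 1 | node_row > K))
    stopf("labels must lie in 1..%d", K)
  length(unique(node_row)) / K
}

#' Flexibility of a node
#'
#' Fraction of between-window transitions at which the node changes
#' community: `(#switches) / (T - 1)` for T windows.
#'
#' @param node_row Integer vector of community labels over windows
#'   (length T >= 2).
#' @return Numeric scalar in `[0, 1]`.
#' @export
#' @examples
#' flexibility(c(1, 2, 1, 3))  # switches at all 3 transitions -> 1
#' flexibility(c(2, 2, 3, 3))  # one switch in 3 transitions -> 1/3
flexibility <- function(node_row) {
  T <- length(node_row)
  if (T < 2) stopf("flexibility needs at least 2 windows, got %d", T)
  t_from <- node_row[-T]
  t_to <- node_row[-1]
  sum(t_from != t_to) / (T - 1)
}

#' Classify every switch as cohesive or disjoint
#'
#' A node's switch at transition `t -> t+1` is *cohesive* (mutual) when at
#' least one other node switches at the same transition from the same
#' source community to the same destination community, and *disjoint*
#' (independent) otherwise.  Unchanged labels are classified `"none"`;
#' each switch is classified exactly once, so cohesive and disjoint
#' fractions add up to flexibility.
#'
#' @param assignments Integer matrix, regions x windows (T >= 2 columns),
#'   e.g. an `assignment_matrix` from [detect_all()].
#' @return List of class `switch_classification` with `kind` (character
#'   matrix regions x (T-1): `"none"`, `"cohesive"` or `"disjoint"`) and
#'   `partners` (list of co-moving partner index vectors, indexed
#'   `[[transition]][[node]]`, empty for non-cohesive switches).
#' @export
classify_switches <- function(assignments) {
  m <- as.matrix(assignments)
  n <- nrow(m); T <- ncol(m)
  if (T < 2) stopf("switch classification needs at least 2 windows, got %d", T)
  kind <- matrix("none", n, T - 1L,
                 dimnames = list(rownames(m), NULL))
  partners <- vector("list", T - 1L)
  for (t in seq_len(T - 1L)) {
    from <- m[, t]; to <- m[, t + 1L]
    moved <- which(from != to)
    partners[[t]] <- rep(list(integer(0)), n)
    if (length(moved)) {
      key <- paste(from[moved], to[moved], sep = ">")
      tab <- table(key)
      cohesive <- tab[key] >= 2
      kind[moved, t] <- ifelse(cohesive, "cohesive", "disjoint")
      for (i in which(cohesive)) {
        node <- moved[i]
        partners[[t]][[node]] <- setdiff(moved[key == key[i]], node)
      }
    }
  }
  structure(list(kind = kind, partners = partners),
            class = "switch_classification")
}

#' Per-node cohesion and disjointedness fractions
#'
#' Cohesion is the fraction of transitions at which the node makes a
#' mutual switch; disjointedness the fraction with an independent switch.
#' By construction `cohesion + disjointedness = flexibility` for every
#' node.
#'
#' @param cls A `switch_classification` from [classify_switches()].
#' @return Data frame with columns `cohesion` and `disjointedness`, one
#'   row per node.
#' @export
cohesion_disjointedness <- function(cls) {
  stopifnot(inherits(cls, "switch_classification"))
  n_trans <- ncol(cls$kind)
  data.frame(
    cohesion = rowSums(cls$kind == "cohesive") / n_trans,
    disjointedness = rowSums(cls$kind == "disjoint") / n_trans,
    row.names = rownames(cls$kind)
  )
}

#' All four reconfiguration metrics per node
#'
#' @param assignments Integer matrix, regions x windows.
#' @param K Total number of communities (defaults to the
#'   `assignment_matrix` legend length, else `max(assignments)`).
#' @return Data frame with columns `region_id`, `promiscuity`,
#'   `flexibility`, `cohesion`, `disjointedness`; attributes `K` and
#'   `n_windows`.
#' @export
reconfig_metrics <- function(assignments, K = NULL) {
  m <- as.matrix(assignments)
  if (is.null(K)) {
    communities <- attr(assignments, "communities")
    K <- if (!is.null(communities)) length(communities) else max(m)
  }
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("region_", seq_len(nrow(m)))
  cls <- classify_switches(m)
  cd <- cohesion_disjointedness(cls)
  out <- data.frame(
    region_id = ids,
    promiscuity = apply(m, 1, promiscuity, K = K),
    flexibility = apply(m, 1, flexibility),
    cohesion = cd$cohesion,
    disjointedness = cd$disjointedness,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "K") <- K
  attr(out, "n_windows") <- ncol(m)
  out
}

#' Global and per-network metric summaries
#'
#' Aggregates node metrics to the whole brain (unweighted mean over all
#' nodes) and to each network, where network membership is the *static*
#' literature-based atlas label, not the time-resolved assignment.  A
#' network with no member nodes yields `NA` (flagged absent, never 0).
#'
#' @param node_metrics Data frame from [reconfig_metrics()].
#' @param atlas Named character vector (region id -> network label).
#' @return List with `global` (named numeric vector over the four
#'   metrics) and `network` (networks x metrics matrix).
#' @export
aggregate_metrics <- function(node_metrics, atlas) {
  validate_atlas(atlas, regions = node_metrics$region_id)
  cols <- c("promiscuity", "flexibility", "cohesion", "disjointedness")
  vals <- as.matrix(node_metrics[, cols])
  global <- colMeans(vals)
  networks <- rsn_networks()[rsn_networks() %in% unique(atlas)]
  net <- matrix(NA_real_, length(networks), length(cols),
                dimnames = list(networks, cols))
  labels <- atlas[node_metrics$region_id]
  for (nw in networks) {
    members <- which(labels == nw)
    if (length(members))
      net[nw, ] <- colMeans(vals[members, , drop = FALSE])
  }
  list(global = global, network = net)
}

#' Write per-node metrics to TSV
#'
#' Columns: `region_id`, `network`, and the four metric values.
#'
#' @param node_metrics Data frame from [reconfig_metrics()].
#' @param atlas Named character vector of network labels.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(node_metrics, atlas, path) {
  df <- data.frame(region_id = node_metrics$region_id,
                   network = unname(atlas[node_metrics$region_id]),
                   node_metrics[, c("promiscuity", "flexibility",
                                    "cohesion", "disjointedness")],
                   stringsAsFactors = FALSE)
  write_tsv(df, path, params = list(K = attr(node_metrics, "K"),
                                    n_windows = attr(node_metrics, "n_windows")))
}
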