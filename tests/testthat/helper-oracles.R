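# Deliberately naive brute-force oracles, independent of the package
# internals, used to freeze expected values.

oracle_promiscuity <- function(row, K) length(unique(row)) / K

oracle_flexibility <- function(row) {
  s <- 0L
  for (t in seq_len(length(row) - 1))
    if (row[t] != row[t + 1]) s <- s + 1L
  s / (length(row) - 1)
}

# Per-node cohesive / disjoint switch fractions by direct triple loop.
oracle_cohesion_disjointedness <- function(m) {
  n <- nrow(m); T <- ncol(m)
  coh <- dis <- numeric(n)
  for (i in seq_len(n)) for (t in seq_len(T - 1)) {
    if (m[i, t] != m[i, t + 1]) {
      partner <- FALSE
      for (j in seq_len(n)) {
        if (j != i && m[j, t] != m[j, t + 1] &&
            m[j, t] == m[i, t] && m[j, t + 1] == m[i, t + 1])
          partner <- TRUE
      }
      if (partner) coh[i] <- coh[i] + 1 else dis[i] <- dis[i] + 1
    }
  }
  list(cohesion = coh / (T - 1), disjointedness = dis / (T - 1))
}

oracle_window_starts <- function(N, L, S) {
  starts <- integer(0); s <- 0L
  while (s + L <= N) { starts <- c(starts, s); s <- s + S }
  starts
}

# Retained regions by direct double loop over subjects and regions.
oracle_retained <- function(cov, thr = 0.30, frac = 0.10) {
  keep <- character(0)
  for (j in seq_len(ncol(cov))) {
    fails <- 0L
    for (i in seq_len(nrow(cov))) if (cov[i, j] < thr) fails <- fails + 1L
    if (fails / nrow(cov) <= frac) keep <- c(keep, colnames(cov)[j])
  }
  keep
}

# Total within-community edge weight of a labelling.
partition_score <- function(W, labels) {
  s <- 0
  for (i in seq_len(nrow(W) - 1)) for (j in (i + 1):nrow(W))
    if (labels[i] == labels[j]) s <- s + W[i, j]
  s
}

# Exhaustive search over all K^n labelings that use every community,
# for the maximal total within-community weight; returns the best score.
oracle_best_partition_score <- function(W, K) {
  n <- nrow(W)
  best <- -Inf
  for (idx in 0:(K^n - 1)) {
    labels <- integer(n); x <- idx
    for (i in seq_len(n)) { labels[i] <- x %% K + 1L; x <- x %/% K }
    if (length(unique(labels)) < K) next
    s <- partition_score(W, labels)
    if (s > best) best <- s
  }
  best
}

# The idx-th (0-based) label matrix of the K^(n*T) enumeration.
label_matrix_from_index <- function(idx, n, T, K) {
  out <- matrix(0L, n, T)
  x <- idx
  for (k in seq_len(n * T)) { out[k] <- x %% K + 1L; x <- x %/% K }
  out
}
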