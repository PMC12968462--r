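# Small in-code fixtures shared across test files.

# Perfectly modular weight matrix: within-community weight `win`,
# between-community weight `bwn`, zero diagonal.
modular_weights <- function(labels, win = 1, bwn = 0) {
  n <- length(labels)
  W <- matrix(bwn, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (labels[i] == labels[j]) W[i, j] <- win
  diag(W) <- 0
  W
}

# A tiny deterministic parcellated series.
toy_series <- function(n_regions = 3, n_timepoints = 10, tr = 1) {
  set.seed(99)
  parcellated_series(matrix(rnorm(n_regions * n_timepoints),
                            n_regions, n_timepoints),
                     tr_seconds = tr,
                     region_ids = sprintf("r%02d", seq_len(n_regions)))
}

# The stylised worked example: 7 regions over 4 windows with 4 networks.
# Region 1 visits 3 of 4 networks via two independent switches (t2->t3,
# t3->t4); regions 2 and 4 move together at t1->t2 and t2->t3; regions 5
# and 7 move together at every transition; regions 3 and 6 change once /
# never.
figure_assignments <- function() {
  m <- rbind(
    c(1, 1, 2, 3),   # region 1: disjoint switches at t2->t3 and t3->t4
    c(1, 2, 3, 1),   # region 2: switches at all 3 transitions
    c(2, 2, 4, 4),   # region 3: one switch, no co-mover
    c(1, 2, 3, 3),   # region 4: moves with region 2 at t1->t2, t2->t3
    c(3, 4, 1, 2),   # region 5: moves with region 7 at every transition
    c(4, 4, 4, 4),   # region 6: never switches
    c(3, 4, 1, 2)    # region 7: moves with region 5 at every transition
  )
  rownames(m) <- paste0("region", 1:7)
  m
}
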