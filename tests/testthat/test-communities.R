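# Per-window iterative community detection.

test_that("assignment quality separates embedded from indifferent regions", {
  labels <- rep(1:2, each = 3)
  W <- modular_weights(labels, win = 1, bwn = 0.1)
  q <- assignment_quality(W, labels)
  expect_true(all(q > 0))

  # all weights equal: every region is indifferent, quality exactly 0
  W_eq <- modular_weights(labels, win = 0.5, bwn = 0.5)
  expect_equal(assignment_quality(W_eq, labels), rep(0, 6))

  expect_error(assignment_quality(W, labels, region = 9), "out of range")
})

test_that("quality equals the own-mean minus best-other-mean arithmetic", {
  # 6 nodes, 2 communities {1,2,3} and {4,5,6}, hand-set weights
  W <- matrix(0, 6, 6)
  W[1, 2] <- 0.9; W[1, 3] <- 0.7; W[2, 3] <- 0.8
  W[4, 5] <- 0.6; W[4, 6] <- 0.5; W[5, 6] <- 0.9
  W[1, 4] <- 0.2; W[2, 5] <- 0.3; W[3, 6] <- 0.4
  W <- W + t(W)
  labels <- c(1, 1, 1, 2, 2, 2)
  # node 1: own mean (0.9 + 0.7)/2 = 0.8; other mean (0.2 + 0 + 0)/3
  expect_equal(assignment_quality(W, labels, region = 1), 0.8 - 0.2 / 3)
  # node 5: own mean (0.6 + 0.9)/2 = 0.75; other mean (0 + 0.3 + 0)/3
  expect_equal(assignment_quality(W, labels, region = 5), 0.75 - 0.1)
  # a region alone in its community has quality -Inf
  expect_equal(assignment_quality(W, c(1, 1, 1, 2, 2, 3), region = 6), -Inf)
})

test_that("perfectly modular weights are a fixed point reached immediately", {
  labels <- rep(1:3, each = 4)
  W <- modular_weights(labels, win = 1, bwn = 0.05)
  res <- detect_window_communities(W, labels)
  expect_identical(res$labels, as.integer(labels))
  expect_true(res$converged)
  expect_lte(nrow(res$trace), 2)
})

test_that("a misplaced node is reallocated to the partition a brute-force search finds", {
  # node 3 is labelled with community 1 but connects maximally to community 2
  W <- matrix(0, 6, 6)
  W[1, 2] <- 0.9
  W[3, 4] <- 0.8; W[3, 5] <- 0.9; W[3, 6] <- 0.7
  W[4, 5] <- 0.8; W[4, 6] <- 0.9; W[5, 6] <- 0.8
  W[1, 3] <- 0.1; W[2, 3] <- 0.1; W[1, 4] <- 0.05
  W <- W + t(W)
  init <- c(1, 1, 1, 2, 2, 2)
  res <- detect_window_communities(W, init)
  expect_identical(res$labels, c(1L, 1L, 2L, 2L, 2L, 2L))
  # the found partition attains the exhaustive-search optimum
  expect_equal(partition_score(W, res$labels),
               oracle_best_partition_score(W, 2))
})

test_that("degenerate all-equal weights terminate with labels kept", {
  labels <- c(1, 1, 2, 2, 3, 3)
  W <- modular_weights(labels, win = 0.4, bwn = 0.4)
  res <- detect_window_communities(W, labels)
  expect_true(res$converged)
  expect_identical(res$labels, as.integer(labels))
})

test_that("invalid weight matrices are rejected", {
  W <- matrix(runif(16), 4, 4)
  expect_error(detect_window_communities(W, rep(1:2, 2)), "symmetric")
  W2 <- modular_weights(c(1, 1, 2, 2)); W2[1, 2] <- W2[2, 1] <- -0.5
  expect_error(detect_window_communities(W2, c(1, 1, 2, 2)), "nonnegative")
})

test_that("detection is deterministic, label-conserving, and a fixed point of itself", {
  set.seed(31)
  for (rep in 1:10) {
    labels <- sample(1:4, 12, replace = TRUE)
    labels[1:4] <- 1:4                      # every community present
    A <- matrix(runif(144), 12, 12); W <- (A + t(A)) / 2; diag(W) <- 0
    r1 <- detect_window_communities(W, labels)
    r2 <- detect_window_communities(W, labels)
    expect_identical(r1$labels, r2$labels)
    expect_true(all(r1$labels %in% labels))
    # rerunning from the final labels does not move anything
    r3 <- detect_window_communities(W, r1$labels, K = 4)
    expect_identical(r3$labels, r1$labels)
  }
})

test_that("accepted reallocations never decrease the moved region's quality", {
  set.seed(32)
  for (rep in 1:10) {
    labels <- rep(1:3, each = 4)
    A <- matrix(runif(144), 12, 12); W <- (A + t(A)) / 2; diag(W) <- 0
    res <- detect_window_communities(W, labels)
    cur <- as.integer(labels)
    for (k in seq_len(nrow(res$trace))) {
      step <- res$trace[k, ]
      if (step$old != step$new) {
        q_before <- assignment_quality(W, cur, region = step$region, K = 3)
        cur[step$region] <- step$new
        q_after <- assignment_quality(W, cur, region = step$region, K = 3)
        expect_gte(q_after, q_before)
      }
    }
    expect_identical(cur, res$labels)
  }
})

test_that("detect_all stacks per-window results seeded from the atlas", {
  atlas <- example_atlas(24)
  truth <- plant_truth(atlas, n_windows = 7, n_cohesive = 2, n_disjoint = 2,
                       sojourn_range = c(2, 3), seed = 3)
  x <- generate_subject(truth, n_timepoints = 120, seed = 4)
  wc <- windowed_correlation(x)
  am <- detect_all(wc, atlas)
  expect_s3_class(am, "assignment_matrix")
  expect_equal(dim(am), c(24, 7))
  expect_length(attr(am, "communities"), 8)

  # single window: column equals the per-window result
  wc1 <- wc
  wc1$weights <- wc$weights[, , 1, drop = FALSE]
  wc1$windows <- wc$windows[1, , drop = FALSE]
  am1 <- detect_all(wc1, atlas)
  init <- match(atlas[wc$region_ids], attr(am, "communities"))
  direct <- detect_window_communities(wc$weights[, , 1], init, K = 8)
  expect_equal(unname(am1[, 1]), direct$labels)
  expect_equal(am1[, 1], am[, 1])
})

test_that("assignment matrices round-trip through TSV with their legend", {
  atlas <- example_atlas(24)
  truth <- plant_truth(atlas, n_windows = 7, n_cohesive = 2, n_disjoint = 2,
                       sojourn_range = c(2, 3), seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assignments(truth$assignments, path)
  back <- read_assignments(path)
  expect_equal(unclass(back)[, ], unclass(truth$assignments)[, ])
  expect_identical(attr(back, "communities"),
                   attr(truth$assignments, "communities"))
})

test_that("the fitted object exposes the standard model methods", {
  atlas <- example_atlas(24)
  truth <- plant_truth(atlas, n_windows = 7, n_cohesive = 2, n_disjoint = 2,
                       sojourn_range = c(2, 3), seed = 6)
  x <- generate_subject(truth, n_timepoints = 120, seed = 7)
  fit <- reconfig(x, atlas)
  expect_s3_class(fit, "reconfig")
  expect_named(coef(fit), c("promiscuity", "flexibility", "cohesion",
                            "disjointedness"))
  expect_true(all(coef(fit) >= 0 & coef(fit) <= 1))
  expect_output(print(fit), "Global metrics")
  expect_output(print(summary(fit)), "Per-network means")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
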