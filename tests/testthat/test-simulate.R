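# Synthetic generator: planted truths, BOLD-like series, cohorts.

test_that("planted truths are seed-deterministic and consistent with their events", {
  atlas <- example_atlas(60)
  t1 <- plant_truth(atlas, n_cohesive = 4, n_disjoint = 6, seed = 7)
  t2 <- plant_truth(atlas, n_cohesive = 4, n_disjoint = 6, seed = 7)
  expect_identical(t1$assignments[, ], t2$assignments[, ])
  expect_identical(t1$events$transition, t2$events$transition)

  ev <- t1$events
  expect_true(all(ev$kind %in% c("cohesive", "disjoint")))
  sizes <- lengths(ev$nodes)
  expect_true(all(sizes[ev$kind == "cohesive"] >= 2))
  expect_true(all(sizes[ev$kind == "disjoint"] == 1))

  # the truth matrix realises every event: the listed nodes move from
  # source to dest at the listed transition
  m <- t1$assignments
  for (k in seq_len(nrow(ev))) {
    nodes <- ev$nodes[[k]]
    expect_true(all(m[nodes, ev$transition[k]] == ev$source[k]))
    expect_true(all(m[nodes, ev$transition[k] + 1] == ev$dest[k]))
  }
  # and the switch classifier recovers exactly the planted kinds
  cls <- classify_switches(m)
  for (k in seq_len(nrow(ev)))
    expect_true(all(cls$kind[ev$nodes[[k]], ev$transition[k]] == ev$kind[k]))
  # no switches besides the planted ones
  expect_equal(sum(cls$kind != "none"), sum(lengths(ev$nodes)))
})

test_that("zero-propensity nodes never take part in events", {
  atlas <- example_atlas(80)
  truth <- plant_truth(atlas, seed = 9)
  vn <- which(unname(atlas) == "VN")
  expect_true(all(truth$assignments[vn, ] ==
                    truth$assignments[vn, 1]))
  expect_true(all(switch_propensity(atlas)[vn] == 0))
})

test_that("the planted metric oracle equals direct brute force on the truth", {
  atlas <- example_atlas(40)
  truth <- plant_truth(atlas, n_cohesive = 3, n_disjoint = 5, seed = 11)
  orc <- planted_metric_oracle(truth)
  m <- truth$assignments
  ora <- oracle_cohesion_disjointedness(m)
  expect_equal(orc$node_metrics$flexibility,
               unname(apply(m, 1, oracle_flexibility)))
  expect_equal(orc$node_metrics$cohesion, ora$cohesion)
  expect_equal(orc$node_metrics$disjointedness, ora$disjointedness)

  quiet <- plant_truth(atlas, n_cohesive = 0, n_disjoint = 0, seed = 1)
  expect_equal(planted_metric_oracle(quiet)$node_metrics$flexibility,
               rep(0, 40))
})

test_that("generated series honour the window geometry of their truth", {
  atlas <- example_atlas(24)
  truth <- plant_truth(atlas, n_windows = 7, n_cohesive = 2, n_disjoint = 2,
                       sojourn_range = c(2, 3), seed = 2)
  x <- generate_subject(truth, n_timepoints = 120, seed = 3)
  expect_equal(nrow(make_windows(120, 1, window_spec())), 7)
  expect_equal(dim(x$signals), c(24, 120))
  expect_error(generate_subject(truth, n_timepoints = 300, seed = 3),
               "windows")
  # same seed, same subject
  y <- generate_subject(truth, n_timepoints = 120, seed = 3)
  expect_identical(x$signals, y$signals)
})

test_that("the coupling parameter controls community structure as expected", {
  atlas <- example_atlas(16, networks = c("DMN", "FPN"))
  quiet <- plant_truth(atlas, n_cohesive = 0, n_disjoint = 0,
                       node_weights = NULL, seed = 4)
  # noiseless limit: within-community correlations near 1, between small
  x1 <- generate_subject(quiet, rho = 1, seed = 5)
  r1 <- cor(t(x1$signals))
  same <- outer(unname(atlas), unname(atlas), "==")
  off <- !diag(16)
  expect_true(all(r1[same & off] > 0.99))
  expect_true(max(abs(r1[!same])) < max(r1[same & off]))

  # uncoupled limit: all pairwise correlations stay modest
  x0 <- generate_subject(quiet, rho = 0, seed = 6)
  r0 <- cor(t(x0$signals))
  expect_lt(mean(abs(r0[off])), 0.2)

  expect_error(generate_subject(quiet, rho = 1.4, seed = 1), "rho")
})

test_that("generated series are variance-stationary across halves", {
  atlas <- example_atlas(40)
  truth <- plant_truth(atlas, seed = 12)
  x <- generate_subject(truth, seed = 13)
  v1 <- apply(x$signals[, 1:150], 1, var)
  v2 <- apply(x$signals[, 151:300], 1, var)
  ratio <- v1 / v2
  # band-limited signals carry ~27 effective dof per half, so individual
  # ratios fluctuate; the bulk and the mean must stay near unity
  expect_gt(mean(ratio), 0.5)
  expect_lt(mean(ratio), 2)
  expect_true(all(ratio > 0.25 & ratio < 4))
})

test_that("cohorts are reproducible and respect the FSMC scale limits", {
  spec <- cohort_spec(n_pwms = 30, n_hc = 10)
  c1 <- generate_cohort(spec, atlas = example_atlas(40), seed = 21)
  c2 <- generate_cohort(spec, atlas = example_atlas(40), seed = 21)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$planted, c2$planted)

  ph <- c1$phenotypes
  expect_true(all(ph$fatigue_total >= 0 & ph$fatigue_total <= 100))
  expect_true(all(ph$fatigue_motor <= 50 & ph$fatigue_cognitive <= 50))
  expect_true(all(ph$group == c(rep("pwMS", 30), rep("HC", 10))))
  expect_true(all(is.na(ph$edss[ph$group == "HC"])))
  expect_true(all(ph$dmt[ph$group == "pwMS"] %in% dmt_categories()))

  expect_error(cohort_spec(effects = list(disjointedness = c(fatigue_total = 1.2))),
               "absolute value")
  expect_error(cohort_spec(effects = list(banana = c(fatigue_total = 0.2))),
               "banana")
})

test_that("declared metric-fatigue effects are planted at the declared size", {
  atlas <- example_atlas(100)
  # null effect: correlation stays near zero
  null_spec <- cohort_spec(effects = list(disjointedness = c(fatigue_total = 0)))
  rs0 <- sapply(1:3, function(s) {
    co <- generate_cohort(null_spec, atlas = atlas, seed = s)
    ms <- co$phenotypes$group == "pwMS"
    cor(co$planted$disjointedness[ms], co$phenotypes$fatigue_total[ms])
  })
  expect_true(all(abs(rs0) < 0.2))

  # declared effect 0.24 at n = 155: the mean recovered correlation lies
  # within the 95% sampling interval of r = 0.24 (Fisher-z interval)
  rs <- sapply(1:20, function(s) {
    co <- generate_cohort(cohort_spec(), atlas = atlas, seed = 100 + s)
    ms <- co$phenotypes$group == "pwMS"
    cor(co$planted$disjointedness[ms], co$phenotypes$fatigue_total[ms])
  })
  interval <- tanh(atanh(0.24) + c(-1, 1) * 1.96 / sqrt(155 - 3))
  expect_gt(mean(rs), interval[1])
  expect_lt(mean(rs), interval[2])
})

test_that("fixture directories contain every pipeline input", {
  dir <- withr::local_tempdir()
  man <- simulate_fixture(dir, seed = 8)
  expect_true(file.exists(file.path(dir, "atlas.tsv")))
  expect_true(file.exists(file.path(dir, "coverage.tsv")))
  expect_true(file.exists(file.path(dir, "phenotypes.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(file.path(dir, "series")), man$n_pwms + man$n_hc)
  expect_length(list.files(file.path(dir, "truth")), man$n_pwms + man$n_hc)
  expect_equal(man$seed, 8)
  x <- read_series(file.path(dir, "series", "sub001.tsv"), man$tr_seconds)
  expect_equal(dim(x$signals), c(man$n_regions, man$n_timepoints))
})
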