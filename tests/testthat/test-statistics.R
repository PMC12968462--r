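# Correlation, ANCOVA and hierarchical regression layer.
# (data builders live in helper-statistics.R)

test_that("correlations follow the product-moment formula and Bonferroni rule", {
  ph <- make_stats_data(20)
  summ <- data.frame(subject_id = ph$subject_id,
                     flexibility = ph$fatigue_total)  # y = x exactly
  out <- correlate_metrics_fatigue(summ, ph, metrics = "flexibility",
                                   scales = "fatigue_total", family_size = 1)
  expect_equal(out$r, c(1, 1))
  expect_true(all(out$p < 1e-12))

  # printed toy pair: r = 0.8 by hand computation
  ph5 <- make_stats_data(5)
  ph5$group <- "pwMS"
  ph5$fatigue_total <- c(2, 1, 4, 3, 5)
  s5 <- data.frame(subject_id = ph5$subject_id, flexibility = c(1, 2, 3, 4, 5))
  out5 <- correlate_metrics_fatigue(s5, ph5, metrics = "flexibility",
                                    scales = "fatigue_total", family_size = 4)
  expect_equal(out5$r, 0.8)
  expect_equal(out5$p_adj, min(1, out5$p * 4))

  # family of one: adjustment is the identity; larger families cap at 1
  expect_equal(
    correlate_metrics_fatigue(s5, ph5, metrics = "flexibility",
                              scales = "fatigue_total", family_size = 1)$p_adj,
    out5$p)
  big <- correlate_metrics_fatigue(s5, ph5, metrics = "flexibility",
                                   scales = "fatigue_total",
                                   family_size = 1e6)
  expect_equal(big$p_adj, 1)
})

test_that("correlation output is invariant to affine rescaling", {
  ph <- make_stats_data(30)
  summ <- data.frame(subject_id = ph$subject_id,
                     flexibility = rnorm(30, 0.25, 0.05))
  a <- correlate_metrics_fatigue(summ, ph, metrics = "flexibility",
                                 scales = "fatigue_total", family_size = 1)
  summ2 <- summ
  summ2$flexibility <- 3 * summ2$flexibility + 2
  b <- correlate_metrics_fatigue(summ2, ph, metrics = "flexibility",
                                 scales = "fatigue_total", family_size = 1)
  expect_equal(a$r, b$r)
  expect_equal(a$p, b$p)
})

test_that("degenerate correlation cells are flagged, small cells error", {
  ph <- make_stats_data(12)
  summ <- data.frame(subject_id = ph$subject_id, flexibility = 0.25)
  out <- correlate_metrics_fatigue(summ, ph, metrics = "flexibility",
                                   scales = "fatigue_total", family_size = 1)
  expect_true(all(out$flag == "zero_variance"))
  expect_true(all(is.na(out$r)))

  ph2 <- make_stats_data(4)      # 2 per group < 3 complete pairs
  summ2 <- data.frame(subject_id = ph2$subject_id, flexibility = rnorm(4))
  expect_error(correlate_metrics_fatigue(summ2, ph2, metrics = "flexibility",
                                         scales = "fatigue_total",
                                         family_size = 1),
               "fewer than 3")
})

test_that("the covariate-free ANCOVA reduces to the squared two-sample t", {
  ph <- make_stats_data(50)
  summ <- data.frame(subject_id = ph$subject_id,
                     flexibility = rnorm(50, 0.25, 0.05))
  out <- group_comparison_ancova(summ, ph, metrics = "flexibility",
                                 covariates = character(0), family_size = 1)
  tt <- t.test(flexibility ~ group,
               data = merge(summ, ph, by = "subject_id"), var.equal = TRUE)
  expect_equal(out$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$p, tt$p.value, tolerance = 1e-10)
})

test_that("collinear covariates are rejected by name", {
  ph <- make_stats_data(40)
  ph$age_copy <- ph$age
  summ <- data.frame(subject_id = ph$subject_id, flexibility = rnorm(40))
  expect_error(group_comparison_ancova(summ, ph, metrics = "flexibility",
                                       covariates = c("age", "age_copy"),
                                       family_size = 1),
               "age_copy")
  expect_error(group_comparison_ancova(summ, ph[ph$group == "pwMS", ],
                                       metrics = "flexibility",
                                       family_size = 1),
               "both groups")
})

test_that("hierarchical regression nests correctly and standardizes the predictor", {
  df <- make_regression_data(160, beta = 0, seed = 61)
  hr <- hierarchical_regression(df, "fatigue_total", "disjointedness",
                                blocks = regression_blocks())
  # a predictor orthogonal to the response stays near zero
  expect_lt(abs(hr$beta_std), 2.5 / sqrt(160))
  # R2 never decreases as blocks enter
  expect_true(all(diff(hr$steps$r2) >= -1e-12))
  # DMT enters as dummies with "none" as reference
  expect_true("dmtinterferon" %in% names(coef(hr$fit)))
  expect_false("dmtnone" %in% names(coef(hr$fit)))

  # single-block model reproduces the simple-regression R2 exactly
  hr1 <- hierarchical_regression(df, "fatigue_total", "disjointedness",
                                 blocks = list(demographics = "age"))
  direct <- summary(lm(fatigue_total ~ age, data = df))$r.squared
  expect_equal(hr1$steps$r2[1], direct)
})

test_that("hierarchical regression guards its preconditions", {
  df <- make_regression_data(40, seed = 62)
  expect_error(hierarchical_regression(df[1:10, ], "fatigue_total",
                                       "disjointedness"),
               "observations")
  expect_error(hierarchical_regression(df[, -1], "fatigue_total",
                                       "disjointedness"),
               "age")
  df$nbv[1:3] <- NA
  hr <- hierarchical_regression(df, "fatigue_total", "disjointedness")
  expect_equal(hr$n_dropped, 3)
  expect_equal(hr$n, 37)
})

test_that("a planted standardized effect is recovered without bias", {
  set.seed(63)
  betas <- replicate(60, {
    df <- make_regression_data(155, beta = 0.2)
    hierarchical_regression(df, "fatigue_total", "disjointedness")$beta_std
  })
  expect_lt(abs(mean(betas) - 0.2), 2 * sd(betas) / sqrt(length(betas)))
})
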