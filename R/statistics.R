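# Group-level statistics: Bonferroni-corrected Pearson correlations
# between reconfiguration metrics and fatigue, covariate-adjusted group
# comparisons (ANCOVA), and hierarchical ENTER regression with
# demographic / clinical / structural covariate blocks.

#' Pearson correlations between metrics and fatigue scales
#'
#' Product-moment correlations between each reconfiguration metric and
#' each fatigue scale, computed separately per group, with two-sided
#' p-values from the t transform on n - 2 degrees of freedom and
#' Bonferroni adjustment over the declared family size.  The family size
#' is an explicit argument (default: the number of metrics) because the
#' appropriate family depends on which tests a study declares, not on
#' what happens to be in the table.
#'
#' @param summaries Data frame of per-subject metrics (`subject_id` +
#'   metric columns).
#' @param phenotypes Phenotype data frame with `subject_id`, `group` and
#'   the fatigue columns.
#' @param metrics Metric columns to correlate.
#' @param scales Fatigue columns to correlate.
#' @param family_size Bonferroni multiplier m; adjusted p = min(1, p * m).
#' @return Data frame: `group`, `metric`, `scale`, `n`, `r`, `p`,
#'   `p_adj`, `flag` (`"zero_variance"` when a cell could not be
#'   computed, else `""`).
#' @export
correlate_metrics_fatigue <- function(summaries, phenotypes,
                                      metrics = c("promiscuity", "flexibility",
                                                  "cohesion", "disjointedness"),
                                      scales = c("fatigue_total", "fatigue_motor",
                                                 "fatigue_cognitive"),
                                      family_size = length(metrics)) {
  df <- merge(summaries, phenotypes, by = "subject_id")
  rows <- list()
  for (g in unique(df$group)) {
    sub <- df[df$group == g, ]
    for (m in metrics) for (s in scales) {
      ok <- stats::complete.cases(sub[, c(m, s)])
      x <- sub[[m]][ok]; y <- sub[[s]][ok]
      n <- length(x)
      if (n < 3)
        stopf("fewer than 3 complete pairs for %s vs %s in group %s", m, s, g)
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, metric = m, scale = s, n = n, r = NA_real_,
          p = NA_real_, flag = "zero_variance", stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(x, y, method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, scale = s, n = n,
        r = unname(ct$estimate), p = ct$p.value, flag = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p * family_size, 1)
  out[, c("group", "metric", "scale", "n", "r", "p", "p_adj", "flag")]
}

# Shared ANCOVA core: metric ~ group + covariates, F test for group.
ancova_fit <- function(df, metric, covariates) {
  for (v in covariates) {
    if (is.numeric(df[[v]]) && stats::sd(df[[v]]) == 0)
      stopf("covariate '%s' is constant", v)
  }
  rhs <- paste(c("group", covariates), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste(metric, "~", rhs)), data = df)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stopf("collinear covariate%s in ANCOVA: %s",
          if (length(bad) > 1) "s" else "", paste(bad, collapse = ", "))
  }
  reduced <- stats::update(full, stats::as.formula(paste(". ~ . - group")))
  an <- stats::anova(reduced, full)
  cf <- stats::coef(full)
  gcoef <- unname(cf[grep("^group", names(cf))][1])
  list(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2], p = an$`Pr(>F)`[2],
       group_coef = gcoef)
}

#' Covariate-adjusted group comparison of metrics
#'
#' Linear model `metric ~ group + age + sex + education` per metric; the
#' group effect is tested with the nested-model F test (equal to the
#' squared t of the group coefficient for a two-level group) and
#' Bonferroni-adjusted over the metric family.
#'
#' @inheritParams correlate_metrics_fatigue
#' @param covariates Covariate columns (default age, sex, education; use
#'   `character(0)` for an unadjusted comparison).
#' @return Data frame: `metric`, `n`, `F`, `df1`, `df2`, `p`,
#'   `group_coef` (the adjusted group-difference estimate) and `p_adj`.
#' @export
group_comparison_ancova <- function(summaries, phenotypes,
                                    metrics = c("promiscuity", "flexibility",
                                                "cohesion", "disjointedness"),
                                    covariates = c("age", "sex", "education"),
                                    family_size = length(metrics)) {
  df <- merge(summaries, phenotypes, by = "subject_id")
  if (length(unique(df$group)) < 2)
    stopf("both groups must be represented")
  rows <- lapply(metrics, function(m) {
    sub <- df[stats::complete.cases(df[, c(m, "group", covariates)]), ]
    fit <- ancova_fit(sub, m, covariates)
    data.frame(metric = m, n = nrow(sub), F = fit$F, df1 = fit$df1,
               df2 = fit$df2, p = fit$p, group_coef = fit$group_coef,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p * family_size, 1)
  out
}

#' Default covariate blocks for hierarchical regression
#'
#' Demographics (age, sex, education), clinical (EDSS, disease duration,
#' DMT category) and structural MRI (normalized brain volume, T2 lesion
#' load), entered in that order before the reconfiguration metric.
#'
#' @return Named list of character vectors.
#' @export
regression_blocks <- function() {
  list(demographics = c("age", "sex", "education"),
       clinical = c("edss", "disease_duration", "dmt"),
       structural = c("nbv", "t2_ll"))
}

#' Hierarchical (ENTER) regression of fatigue on a metric
#'
#' Ordinary least squares refit at each block entry: covariate blocks are
#' entered cumulatively in their declared order and the reconfiguration
#' metric enters last.  Reports R-squared and adjusted R-squared per
#' step, and the standardized coefficient (beta) of the metric in the
#' full model, obtained by z-scoring the response and all continuous
#' predictors before the final fit (binary sex and the DMT dummy columns
#' are left on their original scale).  DMT is expanded to dummy columns
#' with `"none"` as the reference category.  Incomplete cases are dropped
#' listwise and the dropped count reported.
#'
#' @param data Data frame containing the response, predictor and all
#'   block columns (typically merged metric summaries + phenotypes,
#'   patient group only).
#' @param response Fatigue column name.
#' @param predictor Reconfiguration metric column name.
#' @param blocks Named list of covariate blocks (default
#'   [regression_blocks()]).
#' @return An object of class `hier_reg`: list with `steps` (data frame:
#'   `step`, `terms`, `r2`, `adj_r2`, `p_model`), `beta_std`, `p_beta`,
#'   `n`, `n_dropped`, and `fit` (the final `lm`).
#' @export
hierarchical_regression <- function(data, response, predictor,
                                    blocks = regression_blocks()) {
  vars <- unique(c(response, unlist(blocks), predictor))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stopf("missing column%s: %s", if (length(missing_cols) > 1) "s" else "",
          paste(missing_cols, collapse = ", "))
  df <- data[, vars]
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, ]
  if ("dmt" %in% names(df))
    df$dmt <- stats::relevel(factor(df$dmt, levels = dmt_categories()
                                    [dmt_categories() %in% unique(df$dmt)]),
                             ref = if ("none" %in% df$dmt) "none"
                                   else levels(factor(df$dmt))[1])
  terms_so_far <- character(0)
  steps <- list()
  entry <- c(blocks, list(predictor = predictor))
  for (b in names(entry)) {
    terms_so_far <- c(terms_so_far, entry[[b]])
    k_params <- sum(vapply(terms_so_far, function(v)
      if (is.factor(df[[v]])) nlevels(df[[v]]) - 1L else 1L, integer(1)))
    if (k_params + 1L >= nrow(df))
      stopf("%d parameters for %d observations at step '%s'",
            k_params + 1L, nrow(df), b)
    fml <- stats::as.formula(paste(response, "~",
                                   paste(terms_so_far, collapse = " + ")))
    fit <- stats::lm(fml, data = df)
    sm <- summary(fit)
    p_model <- if (is.null(sm$fstatistic)) NA_real_ else
      stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
    steps[[b]] <- data.frame(step = b,
                             terms = paste(entry[[b]], collapse = "+"),
                             r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                             p_model = unname(p_model),
                             stringsAsFactors = FALSE)
  }
  # standardized final fit: z-score response and continuous predictors
  zdf <- df
  for (v in c(response, terms_so_far)) {
    if (is.numeric(zdf[[v]]) && length(unique(zdf[[v]])) > 2 &&
        stats::sd(zdf[[v]]) > 0)
      zdf[[v]] <- as.numeric(base::scale(zdf[[v]]))
  }
  zfit <- stats::lm(stats::as.formula(paste(response, "~",
                    paste(terms_so_far, collapse = " + "))), data = zdf)
  zc <- summary(zfit)$coefficients
  structure(list(steps = do.call(rbind, c(steps, make.row.names = FALSE)),
                 beta_std = unname(zc[predictor, "Estimate"]),
                 p_beta = unname(zc[predictor, "Pr(>|t|)"]),
                 n = nrow(df), n_dropped = n_dropped, fit = fit),
            class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, digits = 3, ...) {
  cat("Hierarchical (ENTER) regression\n")
  print(cbind(x$steps[, c("step", "terms")],
              round(x$steps[, c("r2", "adj_r2", "p_model")], digits)))
  cat(sprintf("Final-model standardized beta (predictor): %.3f (p = %.4g), n = %d (%d dropped)\n",
              x$beta_std, x$p_beta, x$n, x$n_dropped))
  invisible(x)
}
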