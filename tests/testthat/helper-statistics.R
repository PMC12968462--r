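# Data builders for the statistics tests.

make_stats_data <- function(n = 40, seed = 51) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%03d", 1:n),
             group = rep(c("pwMS", "HC"), length.out = n),
             fatigue_total = runif(n, 20, 90),
             fatigue_motor = runif(n, 10, 45),
             fatigue_cognitive = runif(n, 10, 45),
             age = rnorm(n, 39, 10), sex = rbinom(n, 1, 0.6),
             education = round(rnorm(n, 15, 3)),
             stringsAsFactors = FALSE)
}

# Full-block regression data with a known standardized predictor effect:
# unit-variance response, predictor independent of the covariates.
make_regression_data <- function(n = 155, beta = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dmt <- sample(dmt_categories(), n, replace = TRUE)
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.6),
                     education = rnorm(n), edss = rnorm(n),
                     disease_duration = rnorm(n), dmt = dmt,
                     nbv = rnorm(n), t2_ll = rnorm(n))
  x <- rnorm(n)
  lin <- as.numeric(scale(0.25 * covs$age - 0.2 * covs$nbv + 0.15 * covs$edss))
  y <- beta * x + 0.3 * lin + rnorm(n, sd = sqrt(1 - beta^2 - 0.09))
  cbind(covs, disjointedness = x, fatigue_total = y)
}
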