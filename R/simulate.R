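# Synthetic-data generator: parcellated BOLD-like series with planted
# community structure and switching events, plus phenotype tables with
# configurable metric-fatigue effects.  Everything is seed-deterministic
# so every pipeline stage is testable without any external data.

#' Evenly populated example atlas
#'
#' Assigns `n_regions` synthetic region ids to the eight canonical
#' networks (or a subset) in contiguous, nearly equal blocks, mimicking
#' the 200-region parcellation the pipeline consumes.
#'
#' @param n_regions Number of regions (default 200).
#' @param networks Network labels to use (default all eight).
#' @return Named character vector (region id -> network).
#' @export
example_atlas <- function(n_regions = 200, networks = rsn_networks()) {
  ids <- sprintf("R%03d", seq_len(n_regions))
  sizes <- diff(round(seq(0, n_regions, length.out = length(networks) + 1)))
  stats::setNames(rep(networks, times = sizes), ids)
}

#' Per-node switching propensity profile
#'
#' Real cohorts show node flexibility as a stable spatial trait: highest
#' in association (control / attention) cortex, lowest in primary sensory
#' regions.  The generator emulates this with a fixed per-node propensity
#' used to select which nodes take part in planted switching events:
#' a network-level base (FPN/DAN/VAN 5, DMN/LN 2, SMN/DGM 0.5, VN 0)
#' multiplied by a deterministic within-network gradient from 0.4 to 1.6.
#' Zero-propensity nodes never switch.  Because the profile is a fixed
#' function of the atlas, the planted spatial pattern is shared by all
#' subjects of a simulated cohort, as a trait should be.
#'
#' @param atlas Named character vector (region id -> network label).
#' @return Numeric vector of nonnegative weights, one per region.
#' @export
switch_propensity <- function(atlas) {
  base <- c(DMN = 2, FPN = 5, DAN = 5, VAN = 5, VN = 0, SMN = 0.5,
            LN = 2, DGM = 0.5)
  w <- base[unname(atlas)]
  for (nw in unique(atlas)) {
    idx <- which(atlas == nw)
    w[idx] <- w[idx] * seq(0.4, 1.6, length.out = length(idx))
  }
  unname(w)
}

#' Plant a ground-truth assignment matrix with switching events
#'
#' Builds a regions x windows ground-truth assignment matrix that starts
#' from the atlas labels and plants *sojourns*: a set of nodes leaves its
#' home network at one transition and returns at a later one.  Cohesive
#' events move two or more nodes together (same source, same destination,
#' same transition); disjoint events move exactly one node with no
#' co-mover.  Event (transition, source, destination) triples are kept
#' unique so the planted event kinds are exactly what the switch
#' classifier must recover.
#'
#' @param atlas Named character vector (region id -> network label).
#' @param n_windows Number of windows T (default 25).
#' @param n_cohesive,n_disjoint Number of cohesive / disjoint sojourns
#'   (defaults 12 and 25).
#' @param sojourn_range Range of sojourn lengths in transitions
#'   (default 4 to 8).
#' @param cohesive_size Possible cohesive group sizes (default 2:3).
#' @param node_weights Nonnegative per-node weights governing which nodes
#'   take part in events (default [switch_propensity()]; `NULL` for
#'   uniform).  The event's seed node is drawn proportional to weight and
#'   its home network becomes the source community; zero-weight nodes
#'   never switch.
#' @param seed Integer seed; the truth is fully determined by it.
#' @return An object of class `planted_truth`: list with `assignments`
#'   (an `assignment_matrix` of ground-truth labels), `events` (data
#'   frame: `transition`, `nodes` (list column of region indices),
#'   `source`, `dest`, `kind`), `atlas`, `init` (seed labels) and `seed`.
#' @export
plant_truth <- function(atlas, n_windows = 25, n_cohesive = 12, n_disjoint = 25,
                        sojourn_range = c(4, 8), cohesive_size = 2:3,
                        node_weights = switch_propensity(atlas), seed = NULL) {
  validate_atlas(atlas)
  n <- length(atlas)
  if (is.null(node_weights)) node_weights <- rep(1, n)
  if (length(node_weights) != n || any(node_weights < 0))
    stopf("'node_weights' must be %d nonnegative values", n)
  with_seed(seed, {
    communities <- rsn_networks()[rsn_networks() %in% unique(atlas)]
    K <- length(communities)
    if (K < 2) stopf("planting switches needs at least 2 networks")
    init <- match(unname(atlas), communities)
    truth <- matrix(rep(init, n_windows), n, n_windows,
                    dimnames = list(names(atlas), NULL))
    # transitions already claimed per node, padded by a guard band of 3
    busy <- matrix(FALSE, n, n_windows)
    used_tsd <- character(0)
    ev_transition <- integer(0); ev_source <- integer(0)
    ev_dest <- integer(0); ev_kind <- character(0); ev_nodes <- list()
    plan <- c(rep("cohesive", n_cohesive), rep("disjoint", n_disjoint))
    for (kind in plan) {
      placed <- FALSE
      for (attempt in 1:400) {
        size <- if (kind == "cohesive") sample(cohesive_size, 1) else 1L
        len <- sample(seq(sojourn_range[1], sojourn_range[2]), 1)
        if (n_windows - 2 - len < 2) stopf("too few windows for sojourns of length %d", len)
        t_out <- sample(seq(2L, n_windows - 1L - len), 1)
        t_back <- t_out + len
        free <- which(node_weights > 0 &
                        rowSums(busy[, t_out:t_back, drop = FALSE]) == 0)
        if (!length(free)) next
        seed_node <- if (length(free) == 1) free else
          sample(free, 1, prob = node_weights[free])
        s <- init[seed_node]
        d <- sample(setdiff(seq_len(K), s), 1)
        key_out <- paste(t_out, s, d); key_back <- paste(t_back, d, s)
        if (key_out %in% used_tsd || key_back %in% used_tsd) next
        nodes <- seed_node
        if (size > 1L) {
          mates <- setdiff(free[init[free] == s], seed_node)
          if (length(mates) < size - 1L) next
          nodes <- sort(c(seed_node, if (length(mates) == 1) mates else
            sample(mates, size - 1L, prob = node_weights[mates])))
        }
        truth[nodes, (t_out + 1L):t_back] <- d
        busy[nodes, max(1L, t_out - 3L):min(n_windows, t_back + 3L)] <- TRUE
        used_tsd <- c(used_tsd, key_out, key_back)
        ev_transition <- c(ev_transition, t_out, t_back)
        ev_source <- c(ev_source, s, d)
        ev_dest <- c(ev_dest, d, s)
        ev_kind <- c(ev_kind, kind, kind)
        ev_nodes <- c(ev_nodes, list(nodes), list(nodes))
        placed <- TRUE
        break
      }
      if (!placed)
        stopf("could not place a %s sojourn after 400 attempts; reduce event counts", kind)
    }
    ord <- order(ev_transition)
    events <- data.frame(transition = ev_transition[ord],
                         nodes = I(ev_nodes[ord]),
                         source = ev_source[ord], dest = ev_dest[ord],
                         kind = ev_kind[ord], stringsAsFactors = FALSE)
    assignments <- structure(truth,
                             class = c("assignment_matrix", class(truth)),
                             communities = communities)
    structure(list(assignments = assignments, events = events,
                   atlas = atlas, init = init, seed = seed),
              class = "planted_truth")
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %d regions x %d windows, %d events (%d cohesive, %d disjoint switches)\n",
              nrow(x$assignments), ncol(x$assignments), nrow(x$events),
              sum(x$events$kind == "cohesive"), sum(x$events$kind == "disjoint")))
  invisible(x)
}

# Draw K community latents one at a time, accepting a candidate only if
# its windowed correlation with every already-accepted latent stays below
# rmax in every sliding window.  Band-limited signals have few effective
# degrees of freedom per 60-s window, so unconstrained latent pairs can
# transiently align almost perfectly - in which case the planted labels
# would no longer describe the generated data and "recovery" would be
# ill-defined.  The constraint keeps the planted truth identifiable.
constrained_latents <- function(K, n_timepoints, tr_seconds, band, windows,
                                rmax, max_draws = 50 * K) {
  acc <- NULL
  for (draw in seq_len(max_draws)) {
    cand <- band_limited_noise(1, n_timepoints, tr_seconds, band)
    ok <- TRUE
    if (!is.null(acc)) {
      for (k in seq_len(nrow(windows))) {
        idx <- (windows[k, "start"] + 1L):windows[k, "end"]
        if (any(abs(stats::cor(cand[idx, 1], acc[idx, , drop = FALSE])) > rmax)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      acc <- cbind(acc, cand)
      if (ncol(acc) == K) return(acc)
    }
  }
  stopf("could not draw %d latents with windowed |r| <= %g in %d attempts",
        K, rmax, max_draws)
}

# Band-limited unit-variance noise: white Gaussian noise filtered to the
# given frequency band (Hz) in the Fourier domain.  Returns T x n matrix.
band_limited_noise <- function(n_series, n_timepoints, tr_seconds,
                               band = c(0.01, 0.1)) {
  T <- n_timepoints
  x <- matrix(stats::rnorm(T * n_series), T, n_series)
  f <- (seq_len(T) - 1) / (T * tr_seconds)
  f <- pmin(f, 1 / tr_seconds - f)          # fold negative frequencies
  mask <- f >= band[1] & f <= band[2]
  if (!any(mask)) stopf("band [%g, %g] Hz contains no Fourier bins for T = %d",
                        band[1], band[2], T)
  F <- stats::mvfft(x)
  F[!mask, ] <- 0
  y <- Re(stats::mvfft(F, inverse = TRUE)) / T
  sweep(y, 2, apply(y, 2, stats::sd), "/")
}

#' Generate one subject's BOLD-like series from a planted truth
#'
#' Every community gets its own band-limited latent signal (drawn under a
#' windowed cross-correlation bound, see `max_latent_cor`); region
#' i at time t emits `sqrt(rho)` times the latent of its ground-truth
#' community at t plus `sqrt(1 - rho)` times independent band-limited
#' noise.  Community membership changes exactly at the planted
#' transitions, mapped to the sample midway between the centres of the
#' two adjacent windows, so each window's majority content matches its
#' truth column.
#'
#' @param truth A [plant_truth()] object.
#' @param n_timepoints Samples per region (default 300).
#' @param tr_seconds Repetition time (default 1).
#' @param rho Coupling between a region and its community latent, in
#'   \[0, 1\] (default 0.8).
#' @param band Frequency band in Hz for latents and noise
#'   (default `c(0.01, 0.1)`, matching the pipeline's high-pass regime).
#' @param spec Window geometry the truth columns refer to (default
#'   60 s / 10 s).
#' @param max_latent_cor Upper bound on the windowed correlation between
#'   any two community latents (default 0.6); candidate latents violating
#'   it are redrawn so the planted assignment stays identifiable in every
#'   window.
#' @param subject_id Subject identifier.
#' @param seed Integer seed.
#' @return A [parcellated_series()].
#' @export
generate_subject <- function(truth, n_timepoints = 300, tr_seconds = 1,
                             rho = 0.8, band = c(0.01, 0.1),
                             spec = window_spec(), max_latent_cor = 0.6,
                             subject_id = "sim", seed = NULL) {
  stopifnot(inherits(truth, "planted_truth"))
  if (rho < 0 || rho > 1) stopf("'rho' must lie in [0, 1]")
  w <- make_windows(n_timepoints, tr_seconds, spec)
  W <- ncol(truth$assignments)
  if (nrow(w) != W)
    stopf("geometry implies %d windows but truth has %d columns", nrow(w), W)
  with_seed(seed, {
    n <- nrow(truth$assignments)
    K <- length(attr(truth$assignments, "communities"))
    # segment boundaries: midpoint between consecutive window centres
    centers <- (w[, "start"] + w[, "end"] - 1) / 2
    bounds <- c(0, floor((centers[-W] + centers[-1]) / 2) + 1, n_timepoints)
    seg_of_sample <- findInterval(seq_len(n_timepoints) - 1, bounds,
                                  rightmost.closed = TRUE)
    latents <- constrained_latents(K, n_timepoints, tr_seconds, band,
                                   w, rmax = max_latent_cor)           # T x K
    noise <- band_limited_noise(n, n_timepoints, tr_seconds, band)     # T x n
    labels_t <- truth$assignments[, seg_of_sample, drop = FALSE]       # n x T
    lat_sig <- matrix(latents[cbind(rep(seq_len(n_timepoints), each = n),
                                    as.vector(labels_t))], n, n_timepoints)
    signals <- sqrt(rho) * lat_sig + sqrt(1 - rho) * t(noise)
    parcellated_series(signals, tr_seconds = tr_seconds,
                       subject_id = subject_id,
                       region_ids = rownames(truth$assignments))
  })
}

#' Exact reconfiguration metrics of a planted truth
#'
#' Applies the package's metric definitions directly to the ground-truth
#' assignment matrix, providing the recovery target for end-to-end tests.
#'
#' @param truth A [plant_truth()] object.
#' @return List with `node_metrics`, `global` and `network` (as in
#'   [reconfig()]).
#' @export
planted_metric_oracle <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  node_metrics <- reconfig_metrics(truth$assignments)
  agg <- aggregate_metrics(node_metrics, truth$atlas)
  list(node_metrics = node_metrics, global = agg$global, network = agg$network)
}

#' Cohort specification for the synthetic generator
#'
#' Sample sizes, metric-fatigue effect map and covariate distributions of
#' a simulated patient / control cohort.  The defaults emulate a cohort
#' of 155 patients and 48 controls with a standardized disjointedness -
#' total fatigue association of 0.24 (0.28 for motor fatigue) in the
#' patient group only; covariate distributions follow the published
#' demographic and clinical ranges for such cohorts.
#'
#' @param n_pwms,n_hc Group sizes.
#' @param effects Named list: metric name -> named numeric vector of
#'   standardized effects per fatigue scale (applied in the patient group
#'   only).  Absolute effects must be < 1.
#' @param seed Default seed used by [generate_cohort()] when none is
#'   passed there.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pwms = 155, n_hc = 48,
                        effects = list(disjointedness = c(fatigue_total = 0.24,
                                                          fatigue_motor = 0.28,
                                                          fatigue_cognitive = 0.18)),
                        seed = 1L) {
  if (n_pwms < 2 || n_hc < 2) stopf("each group needs at least 2 subjects")
  bad <- unlist(effects)
  if (length(bad) && any(abs(bad) >= 1))
    stopf("standardized effects must have absolute value < 1")
  unknown <- setdiff(names(effects),
                     c("promiscuity", "flexibility", "cohesion", "disjointedness"))
  if (length(unknown))
    stopf("unknown metric%s in effect map: %s",
          if (length(unknown) > 1) "s" else "", paste(unknown, collapse = ", "))
  structure(list(n_pwms = n_pwms, n_hc = n_hc, effects = effects, seed = seed),
            class = "cohort_spec")
}

# FSMC-style scale parameters (mean, sd, min, max) per group and scale.
fsmc_params <- function(group, scale) {
  p <- list(
    pwMS = list(fatigue_total = c(50.3, 18.9, 20, 100),
                fatigue_motor = c(25.9, 10.5, 10, 50),
                fatigue_cognitive = c(24.4, 9.7, 10, 50)),
    HC = list(fatigue_total = c(35.8, 10.1, 20, 100),
              fatigue_motor = c(17.3, 5.2, 10, 50),
              fatigue_cognitive = c(18.5, 5.4, 10, 50))
  )
  p[[group]][[scale]]
}

#' Generate a synthetic cohort
#'
#' Draws per-subject planted truths with varying switching intensity,
#' derives each subject's planted global metrics, and generates phenotype
#' tables in which the declared fatigue scales correlate with the planted
#' metric at the declared standardized effect within the patient group
#' (controls get effect-free fatigue).  Optionally also generates the
#' BOLD-like series of every subject.
#'
#' @param spec A [cohort_spec()].
#' @param atlas Atlas used for every subject (default
#'   `example_atlas(200)`).
#' @param n_windows Windows per subject (default 25).
#' @param n_timepoints,tr_seconds,rho Passed to [generate_subject()] when
#'   `make_series = TRUE`.
#' @param make_series Generate the signal matrices (default `FALSE`:
#'   phenotypes, truths and planted metrics only, which is what the
#'   statistics layer consumes).
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return List with `phenotypes` (data frame), `planted` (data frame of
#'   per-subject planted global metrics), `truths` (list of
#'   `planted_truth`), and `series` (list of [parcellated_series()] or
#'   `NULL`).
#' @export
generate_cohort <- function(spec, atlas = example_atlas(200), n_windows = 25,
                            n_timepoints = 300, tr_seconds = 1, rho = 0.8,
                            make_series = FALSE, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n_pwms + spec$n_hc
    group <- c(rep("pwMS", spec$n_pwms), rep("HC", spec$n_hc))
    ids <- sprintf("sub%03d", seq_len(n))
    # switching intensity varies across subjects -> planted metric
    # variance; ranges scale with atlas size so placement stays feasible
    R <- length(atlas)
    n_dis <- sample(max(2, round(0.04 * R)):max(3, round(0.20 * R)), n,
                    replace = TRUE)
    n_coh <- sample(max(2, round(0.02 * R)):max(3, round(0.09 * R)), n,
                    replace = TRUE)
    sojourn <- c(min(4, n_windows - 5), min(8, n_windows - 5))
    if (sojourn[1] < 1) stopf("too few windows (%d) to plant sojourns", n_windows)
    sub_seeds <- sample.int(2^30, n)
    truths <- vector("list", n); names(truths) <- ids
    planted <- matrix(NA_real_, n, 4,
                      dimnames = list(ids, c("promiscuity", "flexibility",
                                             "cohesion", "disjointedness")))
    for (i in seq_len(n)) {
      truths[[i]] <- plant_truth(atlas, n_windows = n_windows,
                                 n_cohesive = n_coh[i], n_disjoint = n_dis[i],
                                 sojourn_range = sojourn,
                                 seed = sub_seeds[i])
      planted[i, ] <- planted_metric_oracle(truths[[i]])$global
    }
    phen <- data.frame(
      subject_id = ids, group = group,
      age = round(ifelse(group == "pwMS", stats::rnorm(n, 39, 10),
                         stats::rnorm(n, 33, 10))),
      sex = stats::rbinom(n, 1, ifelse(group == "pwMS", 0.62, 0.71)),
      education = pmax(8, round(ifelse(group == "pwMS", stats::rnorm(n, 14, 3),
                                       stats::rnorm(n, 17, 3)))),
      stringsAsFactors = FALSE
    )
    phen$age <- pmin(pmax(phen$age, 18), 70)
    is_ms <- group == "pwMS"
    phen$edss <- ifelse(is_ms, pmin(round(abs(stats::rnorm(n, 1.2, 1.3)) * 2) / 2, 7), NA)
    phen$disease_duration <- ifelse(is_ms, pmax(round(stats::rnorm(n, 10, 8)), 0), NA)
    dmt_p <- c(0.239, 0.335, 0.058, 0.058, 0.097, 0.039, 0.084, 0.052, 0.038)
    phen$dmt <- ifelse(is_ms, sample(dmt_categories(), n, replace = TRUE,
                                     prob = dmt_p / sum(dmt_p)), NA)
    phen$nbv <- round(ifelse(is_ms, stats::rnorm(n, 1512.1, 79.2),
                             stats::rnorm(n, 1572.9, 58.7)), 1)
    phen$t2_ll <- ifelse(is_ms, round(stats::rlnorm(n, log(3.5), 0.8), 2), NA)
    # fatigue: planted-metric association in the patient group only
    for (scale in c("fatigue_total", "fatigue_motor", "fatigue_cognitive")) {
      z <- stats::rnorm(n)
      for (metric in names(spec$effects)) {
        e <- spec$effects[[metric]][scale]
        if (!is.na(e) && e != 0) {
          zm <- rep(0, n)
          zm[is_ms] <- as.numeric(base::scale(planted[is_ms, metric]))
          z[is_ms] <- e * zm[is_ms] + sqrt(1 - e^2) * z[is_ms]
        }
      }
      score <- numeric(n)
      for (g in c("pwMS", "HC")) {
        p <- fsmc_params(g, scale)
        idx <- group == g
        score[idx] <- pmin(pmax(round(p[1] + p[2] * z[idx], 1), p[3]), p[4])
      }
      phen[[scale]] <- score
    }
    phen <- phen[, phenotype_columns()]
    series <- NULL
    if (make_series) {
      series <- vector("list", n); names(series) <- ids
      for (i in seq_len(n))
        series[[i]] <- generate_subject(truths[[i]], n_timepoints = n_timepoints,
                                        tr_seconds = tr_seconds, rho = rho,
                                        subject_id = ids[i],
                                        seed = sub_seeds[i] + 1L)
    }
    list(phenotypes = phen, planted = as.data.frame(planted),
         truths = truths, series = series)
  })
}

#' Write a complete synthetic fixture directory
#'
#' Generates a small cohort *with* signal series and writes everything a
#' pipeline run needs: one series TSV per subject, atlas TSV, coverage
#' TSV (full coverage), phenotype TSV, ground-truth assignment TSVs, and
#' a JSON manifest recording the seed and all parameters.
#'
#' @param dir Output directory (created if missing).
#' @param spec A [cohort_spec()] (default: a small 6 + 4 cohort).
#' @param atlas,n_windows,n_timepoints,tr_seconds,rho As in
#'   [generate_cohort()].
#' @param seed Integer seed.
#' @return The manifest, invisibly.
#' @export
simulate_fixture <- function(dir, spec = cohort_spec(n_pwms = 6, n_hc = 4),
                             atlas = example_atlas(40), n_windows = 7,
                             n_timepoints = 120, tr_seconds = 1, rho = 0.8,
                             seed = spec$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "series"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  cohort <- generate_cohort(spec, atlas = atlas, n_windows = n_windows,
                            n_timepoints = n_timepoints,
                            tr_seconds = tr_seconds, rho = rho,
                            make_series = TRUE, seed = seed)
  for (id in names(cohort$series)) {
    write_series(cohort$series[[id]], file.path(dir, "series", paste0(id, ".tsv")))
    write_assignments(cohort$truths[[id]]$assignments,
                      file.path(dir, "truth", paste0(id, ".tsv")))
  }
  write_atlas(atlas, file.path(dir, "atlas.tsv"))
  cov <- matrix(1, length(cohort$series), length(atlas),
                dimnames = list(names(cohort$series), names(atlas)))
  write_coverage(cov, file.path(dir, "coverage.tsv"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  manifest <- list(seed = seed, n_pwms = spec$n_pwms, n_hc = spec$n_hc,
                   n_regions = length(atlas), n_windows = n_windows,
                   n_timepoints = n_timepoints, tr_seconds = tr_seconds,
                   rho = rho, subjects = names(cohort$series),
                   package_version = as.character(utils::packageVersion("netreconfig")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
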