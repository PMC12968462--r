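# Sliding-window segmentation and per-window connectivity.

#' Sliding-window specification
#'
#' Window and step lengths in seconds; the defaults (60 s window, 10 s
#' step) segment a 300-volume, TR = 1 s scan into 25 windows, a choice
#' reported to capture the full range of time-varying network
#' reconfiguration.
#'
#' @param window_seconds Window length in seconds (default 60).
#' @param step_seconds Step between consecutive window starts in seconds
#'   (default 10).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_seconds = 60, step_seconds = 10) {
  if (!is.numeric(window_seconds) || window_seconds <= 0)
    stopf("'window_seconds' must be positive")
  if (!is.numeric(step_seconds) || step_seconds <= 0)
    stopf("'step_seconds' must be positive")
  structure(list(window_seconds = window_seconds, step_seconds = step_seconds),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> window %g s, step %g s\n",
              x$window_seconds, x$step_seconds))
  invisible(x)
}

# Seconds -> samples, rounding to the nearest integer (exact at TR = 1 s).
spec_in_samples <- function(spec, tr_seconds) {
  L <- as.integer(round(spec$window_seconds / tr_seconds))
  S <- as.integer(round(spec$step_seconds / tr_seconds))
  if (L < 2) stopf("window of %g s is < 2 samples at TR = %g s",
                   spec$window_seconds, tr_seconds)
  if (S < 1) stopf("step of %g s is < 1 sample at TR = %g s",
                   spec$step_seconds, tr_seconds)
  list(L = L, S = S)
}

#' Enumerate sliding windows
#'
#' Windows start at samples 0, S, 2S, ... and span L samples each, where
#' L and S are the window and step lengths converted to samples by
#' rounding.  Trailing samples not covered by a full window are dropped,
#' so the window count is `floor((N - L) / S) + 1`.
#'
#' @param n_timepoints Number of samples N in the series.
#' @param tr_seconds Repetition time in seconds.
#' @param spec A [window_spec()].
#' @return Integer matrix with one row per window and columns `start`,
#'   `end`: half-open 0-based sample intervals `[start, end)`.
#' @export
#' @examples
#' nrow(make_windows(300, 1, window_spec(60, 10)))  # 25
make_windows <- function(n_timepoints, tr_seconds, spec = window_spec()) {
  ls <- spec_in_samples(spec, tr_seconds)
  L <- ls$L; S <- ls$S
  if (L > n_timepoints)
    stopf("window of %d samples exceeds series length %d", L, n_timepoints)
  n_windows <- (n_timepoints - L) %/% S + 1L
  start <- (seq_len(n_windows) - 1L) * S
  cbind(start = start, end = start + L)
}

#' Per-window absolute Fisher-z connectivity
#'
#' For each sliding window, computes all pairwise Pearson correlations
#' between region signals, clips them to `[-clip, clip]`, and takes the
#' absolute Fisher r-to-z transform `|atanh(r)|` as the nonnegative edge
#' weight.  The diagonal is set to zero (self-connectivity excluded).
#'
#' @param series A [parcellated_series()].
#' @param spec A [window_spec()].
#' @param clip Correlations are clipped to this magnitude before `atanh`
#'   so that perfectly correlated signals yield a finite, maximal weight
#'   (default `1 - 1e-7`).
#' @return An object of class `windowed_connectivity`: list with
#'   `weights` (array, regions x regions x windows), `windows` (the
#'   bounds matrix from [make_windows()]), `region_ids` and `spec`.
#' @export
windowed_correlation <- function(series, spec = window_spec(), clip = 1 - 1e-7) {
  stopifnot(inherits(series, "parcellated_series"))
  w <- make_windows(n_timepoints(series), series$tr_seconds, spec)
  R <- n_regions(series)
  ids <- region_ids(series)
  X <- series$signals
  weights <- array(0, dim = c(R, R, nrow(w)),
                   dimnames = list(ids, ids, NULL))
  for (k in seq_len(nrow(w))) {
    idx <- (w[k, "start"] + 1L):w[k, "end"]
    seg <- X[, idx, drop = FALSE]
    sds <- apply(seg, 1, stats::sd)
    if (any(sds == 0))
      stopf("zero-variance signal in window %d for region%s %s", k,
            if (sum(sds == 0) > 1) "s" else "",
            paste(ids[sds == 0], collapse = ", "))
    r <- stats::cor(t(seg))
    r <- pmin(pmax(r, -clip), clip)
    z <- abs(atanh(r))
    diag(z) <- 0
    weights[, , k] <- z
  }
  structure(list(weights = weights, windows = w, region_ids = ids,
                 spec = spec, clip = clip, subject_id = series$subject_id),
            class = "windowed_connectivity")
}

#' @export
print.windowed_connectivity <- function(x, ...) {
  cat(sprintf("<windowed_connectivity> %d regions, %d windows (window %g s, step %g s)\n",
              length(x$region_ids), dim(x$weights)[3],
              x$spec$window_seconds, x$spec$step_seconds))
  invisible(x)
}
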