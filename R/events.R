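# Event alignment, baseline z-scoring, and per-trial quantification:
# peak-filtered AUC and time-to-peak. Conventions fixed here: the z-score
# baseline SD is the population SD (divisor n); AUC regions are maximal runs
# of z > 0 within the response window; a region is discarded when its peak
# height is strictly below `discard_fraction` times the response window's
# (max - min) range; retained regions are integrated by the trapezoid rule
# including half-sample ramps to the neighbouring non-positive samples.

#' Event window specification
#'
#' Defaults per label: loom 2 s baseline / 2 s response; cs 1.5 s / 2 s;
#' us 0.5 s pre / 0.5 s post.
#'
#' @param label Event label (`loom`, `cs`, `us`, or custom).
#' @param baseline_s Seconds before onset used as the z-score baseline.
#' @param response_s Seconds after onset analyzed as the response.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(label, baseline_s = NULL, response_s = NULL) {
  defaults <- default_config()$windows
  if (is.null(baseline_s) || is.null(response_s)) {
    if (!label %in% names(defaults))
      stop_fmt("no default window for label '%s'; give baseline_s and response_s",
               label)
    baseline_s <- baseline_s %||% defaults[[label]]$baseline_s
    response_s <- response_s %||% defaults[[label]]$response_s
  }
  check_scalar_num(baseline_s, "baseline_s", positive = TRUE)
  check_scalar_num(response_s, "response_s", positive = TRUE)
  structure(list(label = label, baseline_s = baseline_s, response_s = response_s),
            class = "window_spec")
}

#' Align a processed trace to events
#'
#' Builds the trial x time matrix of raw dF/F around each event onset. For
#' loom trials (several expansion instants sharing one `trial_index`) the
#' alignment is to the first expansion of each trial, one row per trial.
#' Windows are half-open on relative time, spanning
#' `[-baseline_s, response_s)`. Trials whose window leaves the recording, and
#' trials whose window contains an isosbestic QC flag, are marked invalid and
#' excluded from group summaries.
#'
#' @param trace A [process_recording()] result.
#' @param events An [event_log()].
#' @param window A [window_spec()]; its `label` selects the events.
#' @return An object of class `aligned_trials`: raw matrix `mat`
#'   (trial x time), `rel_time_s`, `window`, `fs_hz`, `onsets_s`,
#'   `trial_qc` (logical retained flags), `trial_status` (reason strings),
#'   `zscored` flag.
#' @export
align_trials <- function(trace, events, window) {
  stopifnot(inherits(trace, "processed_trace"), inherits(events, "event_log"),
            inherits(window, "window_spec"))
  ev <- events[events$label == window$label, , drop = FALSE]
  if (nrow(ev) == 0L) stop_fmt("no '%s' events in the log", window$label)
  # one row per trial; for multi-instant trials (loom) align to the first onset
  onsets <- vapply(split(ev$onset_s, ev$trial_index), min, numeric(1))
  onsets <- onsets[order(as.integer(names(onsets)))]
  fs <- trace$fs_hz
  n_b <- round(window$baseline_s * fs)
  n_r <- round(window$response_s * fs)
  n_col <- n_b + n_r
  n_tr <- length(onsets)
  rel <- (seq_len(n_col) - n_b - 1L) / fs
  mat <- matrix(NA_real_, n_tr, n_col)
  status <- rep("ok", n_tr)
  qc_ok <- rep(TRUE, n_tr)
  N <- length(trace$time_s)
  for (i in seq_len(n_tr)) {
    i0 <- findInterval(onsets[i] - 1e-9, trace$time_s) + 1L  # first sample at/after onset
    idx <- seq.int(i0 - n_b, i0 + n_r - 1L)
    if (idx[1] < 1L || idx[n_col] > N) {
      status[i] <- "window_out_of_range"
      qc_ok[i] <- FALSE
      next
    }
    mat[i, ] <- trace$dff[idx]
    flags <- trace$qc$flagged_times_s
    if (length(flags) > 0L &&
        any(flags >= onsets[i] - window$baseline_s &
            flags < onsets[i] + window$response_s)) {
      status[i] <- "isosbestic_artifact"
      qc_ok[i] <- FALSE
    }
  }
  structure(list(mat = mat, rel_time_s = rel, window = window, fs_hz = fs,
                 onsets_s = unname(onsets), trial_qc = qc_ok,
                 trial_status = status, n_trials = n_tr, zscored = FALSE),
            class = "aligned_trials")
}

#' Baseline z-scoring of aligned trials
#'
#' Each trial is standardized with the mean and standard deviation of its own
#' pre-event baseline (`rel_time < 0`); the SD is the population SD
#' (divisor n). Trials with zero baseline SD are marked invalid
#' (`degenerate_baseline`) rather than propagating NaN.
#'
#' @param at An [align_trials()] result (raw).
#' @return The same structure with `mat` replaced by z-scores and
#'   `zscored = TRUE`.
#' @export
zscore_baseline <- function(at) {
  stopifnot(inherits(at, "aligned_trials"))
  if (at$zscored) stop_fmt("trials are already z-scored")
  bl <- at$rel_time_s < 0
  if (!any(bl)) stop_fmt("empty baseline segment")
  for (i in seq_len(at$n_trials)) {
    if (!at$trial_qc[i]) next
    x <- at$mat[i, ]
    mu <- mean(x[bl])
    sdp <- sqrt(mean((x[bl] - mu)^2))
    if (sdp == 0) {
      at$trial_qc[i] <- FALSE
      at$trial_status[i] <- "degenerate_baseline"
      at$mat[i, ] <- NA_real_
      next
    }
    at$mat[i, ] <- (x - mu) / sdp
  }
  at$zscored <- TRUE
  at
}

#' Peak-filtered area under the curve
#'
#' Over the response window (`rel_time >= 0`), maximal contiguous regions
#' with z > 0 are identified (the baseline level is 0 in z units, since
#' traces are baseline-standardized). A region's height is its maximum z;
#' regions with height strictly below
#' `discard_fraction * (max - min of the windowed trace)` are discarded.
#' The AUC is the summed trapezoidal area of the retained regions, including
#' the half-sample ramps down to the adjacent non-positive samples; negative
#' deflections never contribute. An empty retained set yields AUC 0.
#'
#' @param z Single-trial z-scored trace.
#' @param rel_time_s Relative times matching `z`.
#' @param discard_fraction Peak filter fraction (default 0.10).
#' @return List with `auc` (z units x seconds), `retained_peak_count`, and
#'   `regions` (data.frame of region start/stop indices, heights, kept flag).
#' @export
compute_auc <- function(z, rel_time_s, discard_fraction = 0.10) {
  if (length(z) != length(rel_time_s)) stop_fmt("z / rel_time length mismatch")
  ridx <- which(rel_time_s >= 0)
  if (length(ridx) == 0L) stop_fmt("z-trace does not cover the response window")
  resp <- z[ridx]
  if (anyNA(resp)) stop_fmt("NA in response window (invalid trial?)")
  dt <- if (length(rel_time_s) > 1L) stats::median(diff(rel_time_s)) else 1
  thr <- discard_fraction * (max(resp) - min(resp))
  pos <- resp > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_runs <- which(r$values)
  n_resp <- length(resp)
  regions <- data.frame(start = integer(), stop = integer(),
                        height = numeric(), kept = logical())
  auc <- 0; kept_n <- 0L
  for (k in keep_runs) {
    s <- starts[k]; e <- ends[k]
    h <- max(resp[s:e])
    kept <- h >= thr  # strict-< discard rule
    if (kept) {
      seg <- resp[s:e]
      # trapezoid incl. half-sample ramps to the neighbouring non-positive
      # samples; ramps collapse to dt * sum(seg) minus half-weights at ends
      # that touch the window boundary (where no ramp exists)
      a <- sum(seg)
      if (s == 1L) a <- a - seg[1] / 2
      if (e == n_resp) a <- a - seg[length(seg)] / 2
      auc <- auc + a * dt
      kept_n <- kept_n + 1L
    }
    regions <- rbind(regions, data.frame(start = s, stop = e, height = h,
                                         kept = kept))
  }
  list(auc = auc, retained_peak_count = kept_n, regions = regions)
}

#' Time to peak
#'
#' Latency from event onset to the maximal z-scored sample within the
#' response window; ties break to the earliest sample.
#'
#' @inheritParams compute_auc
#' @return Seconds from onset (`0 <= t < response length`).
#' @export
time_to_peak <- function(z, rel_time_s) {
  ridx <- which(rel_time_s >= 0)
  if (length(ridx) == 0L) stop_fmt("empty response window")
  resp <- z[ridx]
  if (anyNA(resp)) stop_fmt("NA in response window (invalid trial?)")
  rel_time_s[ridx[which.max(resp)]]
}

#' Per-trial metric table
#'
#' @param at A z-scored [aligned_trials()] set.
#' @param discard_fraction AUC peak filter fraction.
#' @return data.frame with one row per trial: `trial`, `label`, `auc`,
#'   `time_to_peak_s`, `peak_z`, `retained_peak_count`, `qc`, `status`.
#'   Metrics are NA for invalid trials.
#' @export
trial_metrics <- function(at, discard_fraction = 0.10) {
  stopifnot(inherits(at, "aligned_trials"))
  if (!at$zscored) stop_fmt("z-score the trials first (zscore_baseline)")
  out <- data.frame(trial = seq_len(at$n_trials), label = at$window$label,
                    auc = NA_real_, time_to_peak_s = NA_real_,
                    peak_z = NA_real_, retained_peak_count = NA_integer_,
                    qc = at$trial_qc, status = at$trial_status,
                    stringsAsFactors = FALSE)
  ridx <- which(at$rel_time_s >= 0)
  for (i in seq_len(at$n_trials)) {
    if (!at$trial_qc[i]) next
    z <- at$mat[i, ]
    a <- compute_auc(z, at$rel_time_s, discard_fraction)
    out$auc[i] <- a$auc
    out$retained_peak_count[i] <- a$retained_peak_count
    out$time_to_peak_s[i] <- time_to_peak(z, at$rel_time_s)
    out$peak_z[i] <- max(z[ridx])
  }
  out
}

#' Summarize aligned trials
#'
#' Mean trace and SEM band over retained trials, the per-trial metric table,
#' and the heatmap matrix (rows ordered by trial index).
#'
#' @param at A z-scored [aligned_trials()] set.
#' @param discard_fraction AUC peak filter fraction.
#' @return List with `status` (`"ok"` or `"empty"`), `rel_time_s`,
#'   `mean`, `sem`, `metrics`, `heatmap`, `n_retained`.
#' @export
summarize_trials <- function(at, discard_fraction = 0.10) {
  stopifnot(inherits(at, "aligned_trials"))
  keep <- which(at$trial_qc)
  if (length(keep) == 0L)
    return(list(status = "empty", rel_time_s = at$rel_time_s, mean = NULL,
                sem = NULL, metrics = trial_metrics(at, discard_fraction),
                heatmap = NULL, n_retained = 0L))
  m <- at$mat[keep, , drop = FALSE]
  mu <- colMeans(m)
  sem <- if (length(keep) > 1L) apply(m, 2, stats::sd) / sqrt(length(keep))
         else rep(0, ncol(m))
  list(status = "ok", rel_time_s = at$rel_time_s, mean = mu, sem = sem,
       metrics = trial_metrics(at, discard_fraction),
       heatmap = m, n_retained = length(keep))
}
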