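# Brute-force reference implementations, written independently of the package
# internals (plain scan loops), plus small fixture builders.

# bin means by explicit loop
oracle_bin_means <- function(x, w) {
  nb <- length(x) %/% w
  out <- numeric(nb)
  for (j in seq_len(nb)) out[j] <- mean(x[((j - 1) * w + 1):(j * w)])
  out
}

# peak-filtered AUC by per-sample scan: regions of z > 0, height max, discard
# strictly below frac * (max - min), trapezoid with half-sample edge ramps
oracle_auc <- function(z, rel, frac) {
  ridx <- which(rel >= 0)
  resp <- z[ridx]
  dt <- stats::median(diff(rel))
  thr <- frac * (max(resp) - min(resp))
  n <- length(resp)
  total <- 0; count <- 0L
  i <- 1L
  while (i <= n) {
    if (resp[i] > 0) {
      j <- i
      while (j < n && resp[j + 1L] > 0) j <- j + 1L
      h <- -Inf
      for (k in i:j) if (resp[k] > h) h <- resp[k]
      if (!(h < thr)) {
        # trapezoid of c(0, region, 0): equals sum(region), minus a half
        # sample weight at any end flush with the window boundary
        a <- sum(resp[i:j])
        if (i == 1L) a <- a - resp[i] / 2
        if (j == n) a <- a - resp[j] / 2
        total <- total + a * dt
        count <- count + 1L
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(auc = total, count = count)
}

# total overlap of bouts with window [w1, w2), by explicit loop
oracle_bout_overlap <- function(bouts, w1, w2) {
  tot <- 0
  for (i in seq_len(nrow(bouts))) {
    lo <- max(bouts$start_s[i], w1)
    hi <- min(bouts$stop_s[i], w2)
    if (hi > lo) tot <- tot + (hi - lo)
  }
  tot
}

# sub-threshold runs of at least min_s, per-sample scan over a motion vector
# sampled at dt; returns start/stop times like detect_freezing
oracle_immobile_runs <- function(t, v, thr, dt, min_s) {
  n <- length(v)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (v[i] < thr) {
      j <- i
      while (j < n && v[j + 1L] < thr) j <- j + 1L
      if ((j - i + 1L) * dt >= min_s - 1e-9)
        out[[length(out) + 1L]] <- c(t[i], t[j] + dt)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) return(data.frame(start_s = numeric(), stop_s = numeric()))
  m <- do.call(rbind, out)
  data.frame(start_s = m[, 1], stop_s = m[, 2])
}

# threshold-run count by scan
oracle_run_count <- function(above) {
  cnt <- 0L; prev <- FALSE
  for (a in above) {
    if (a && !prev) cnt <- cnt + 1L
    prev <- a
  }
  cnt
}

# line-cross count by scan
oracle_crossings <- function(p, L) {
  cnt <- 0L
  for (i in seq_len(length(p) - 1L)) {
    if ((p[i] > L) != (p[i + 1L] > L)) cnt <- cnt + 1L
  }
  cnt
}

# Minimal aligned_trials object for direct z-score/AUC tests.
make_aligned <- function(mat, fs_hz, baseline_s, response_s, label = "loom") {
  n_b <- round(baseline_s * fs_hz)
  n_col <- ncol(mat)
  structure(list(
    mat = mat,
    rel_time_s = (seq_len(n_col) - n_b - 1L) / fs_hz,
    window = window_spec(label, baseline_s, response_s),
    fs_hz = fs_hz,
    onsets_s = rep(NA_real_, nrow(mat)),
    trial_qc = rep(TRUE, nrow(mat)),
    trial_status = rep("ok", nrow(mat)),
    n_trials = nrow(mat),
    zscored = FALSE), class = "aligned_trials")
}

# One-transient session through the full pipeline; fs 960 Hz gives an exact
# 120 Hz analysis grid.
sim_single_trial <- function(amplitude, seed, noise_sd = 0, onset = 5,
                             fs_hz = 960, rise = 0.1, decay = 1.0,
                             duration = 12) {
  sp <- session_spec(duration, fs_hz = fs_hz, noise_sd = noise_sd, seed = seed)
  tr <- if (amplitude > 0) list(transient_spec(onset, amplitude, rise, decay))
        else list()
  g <- generate_photometry_session(sp, tr)
  pt <- process_recording(g$recording)
  ev <- event_log("loom", onset, NA_real_, 1L)
  zscore_baseline(align_trials(pt, ev, window_spec("loom")))
}
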