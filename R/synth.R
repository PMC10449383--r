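# Seedable synthetic photometry sessions and behavior tracks with known ground
# truth. The generator reproduces the study's trial structure (looming: 5
# expansions of 250 ms expand + 250 ms hold + 2 s pause; conditioning: 20 s CS
# co-terminating with a 2 s US, ITI uniform on 35-120 s) so the downstream
# pipeline can be validated end to end without animal data.

#' Photometry session specification
#'
#' @param duration_s Session length, seconds.
#' @param fs_hz Acquisition rate, Hz. Default 1000 (desk scale); 11000 is the
#'   hardware-faithful rate and is supported.
#' @param bleach_amplitude Fractional amplitude of the photobleaching
#'   exponential added multiplicatively to the baseline (0 disables bleaching).
#' @param bleach_tau_s Photobleaching time constant, seconds. The default is
#'   long relative to a session so the trend is locally near-linear, matching
#'   the first-order detrend; shorter values are a stress-test knob.
#' @param noise_sd Gaussian noise SD, fluorescence units.
#' @param baseline_f0 Baseline fluorescence, arbitrary units (> 0).
#' @param seed RNG seed; identical specs with identical seeds produce
#'   bit-identical sessions.
#' @return A validated list of class `session_spec`.
#' @export
session_spec <- function(duration_s, fs_hz = 1000, bleach_amplitude = 0.1,
                         bleach_tau_s = 1200, noise_sd = 0.005,
                         baseline_f0 = 1, seed = 1L) {
  check_scalar_num(duration_s, "duration_s", positive = TRUE)
  check_scalar_num(fs_hz, "fs_hz", positive = TRUE)
  check_scalar_num(bleach_amplitude, "bleach_amplitude", nonneg = TRUE)
  check_scalar_num(bleach_tau_s, "bleach_tau_s", positive = TRUE)
  check_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar_num(baseline_f0, "baseline_f0", positive = TRUE)
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 bleach_amplitude = bleach_amplitude, bleach_tau_s = bleach_tau_s,
                 noise_sd = noise_sd, baseline_f0 = baseline_f0,
                 seed = as.integer(seed)),
            class = "session_spec")
}

#' Calcium transient specification
#'
#' A transient is a difference-of-exponentials kernel
#' `(1 - exp(-t/rise)) * exp(-t/decay)`, peak-normalized to `amplitude`
#' (dF/F units). Defaults emulate slow-indicator kinetics with an
#' onset-to-peak latency of a few hundred milliseconds.
#'
#' @param onset_s Transient onset, seconds from session start.
#' @param amplitude Peak dF/F (>= 0).
#' @param rise_tau_s,decay_tau_s Rise and decay time constants, seconds;
#'   `rise_tau_s < decay_tau_s`.
#' @return A list of class `transient_spec`.
#' @export
transient_spec <- function(onset_s, amplitude = 0.05, rise_tau_s = 0.1,
                           decay_tau_s = 1.0) {
  check_scalar_num(onset_s, "onset_s", nonneg = TRUE)
  check_scalar_num(amplitude, "amplitude", nonneg = TRUE)
  check_scalar_num(rise_tau_s, "rise_tau_s", positive = TRUE)
  check_scalar_num(decay_tau_s, "decay_tau_s", positive = TRUE)
  if (rise_tau_s >= decay_tau_s)
    stop_fmt("rise_tau_s (%g) must be < decay_tau_s (%g)", rise_tau_s, decay_tau_s)
  structure(list(onset_s = onset_s, amplitude = amplitude,
                 rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s),
            class = "transient_spec")
}

#' Difference-of-exponentials transient kernel
#'
#' Evaluates the peak-normalized kernel at times `t` (seconds after onset).
#' The unnormalized kernel `(1 - exp(-t/r)) * exp(-t/d)` attains its maximum
#' at `t* = r * log((r + d) / r)`; the returned values are scaled so the peak
#' equals 1.
#'
#' @param t Times after onset, seconds (values < 0 give 0).
#' @param rise_tau_s,decay_tau_s Kernel time constants.
#' @return Kernel values in [0, 1].
#' @export
transient_kernel <- function(t, rise_tau_s, decay_tau_s) {
  r <- rise_tau_s; d <- decay_tau_s
  peak <- (1 - exp(-transient_peak_time(r, d) / r)) *
    exp(-transient_peak_time(r, d) / d)
  k <- ifelse(t < 0, 0, (1 - exp(-t / r)) * exp(-t / d) / peak)
  k
}

#' @rdname transient_kernel
#' @return `transient_peak_time()` returns the onset-to-peak latency
#'   `r * log((r + d)/r)` in seconds.
#' @export
transient_peak_time <- function(rise_tau_s, decay_tau_s) {
  rise_tau_s * log((rise_tau_s + decay_tau_s) / rise_tau_s)
}

#' Stimulation protocol specification
#'
#' @param kind `"loom"` (repeated overhead expanding-disk presentations) or
#'   `"conditioning"` (tone CS co-terminating with a footshock US).
#' @param n_trials Number of trials (> 0).
#' @param loom_expand_s,loom_hold_s,loom_pause_s Loom timing: the disk expands
#'   for 250 ms, holds for 250 ms, then pauses 2 s before the next expansion.
#' @param loom_reps_per_trial Expansions per loom trial (default 5).
#' @param cs_duration_s,us_duration_s CS/US lengths (defaults 20 s and 2 s;
#'   the US co-terminates with its CS).
#' @param iti_range_s Inter-trial interval bounds, drawn uniformly (default
#'   35-120 s).
#' @param lead_in_s Quiet period before the first trial, seconds.
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(kind = c("loom", "conditioning"), n_trials = 5L,
                          loom_expand_s = 0.25, loom_hold_s = 0.25,
                          loom_pause_s = 2, loom_reps_per_trial = 5L,
                          cs_duration_s = 20, us_duration_s = 2,
                          iti_range_s = c(35, 120), lead_in_s = 30) {
  kind <- match.arg(kind)
  if (!is.numeric(n_trials) || n_trials < 1 || n_trials != round(n_trials))
    stop_fmt("n_trials must be a positive integer (got %s)", format(n_trials))
  for (nm in c("loom_expand_s", "loom_hold_s", "loom_pause_s", "cs_duration_s",
               "us_duration_s", "lead_in_s"))
    check_scalar_num(get(nm), nm, positive = TRUE)
  if (loom_reps_per_trial < 1) stop_fmt("loom_reps_per_trial must be >= 1")
  if (length(iti_range_s) != 2L || iti_range_s[1] > iti_range_s[2] ||
      any(iti_range_s <= 0))
    stop_fmt("iti_range_s must be positive c(min, max) with min <= max")
  if (us_duration_s >= cs_duration_s)
    stop_fmt("us_duration_s must be shorter than cs_duration_s")
  structure(list(kind = kind, n_trials = as.integer(n_trials),
                 loom_expand_s = loom_expand_s, loom_hold_s = loom_hold_s,
                 loom_pause_s = loom_pause_s,
                 loom_reps_per_trial = as.integer(loom_reps_per_trial),
                 cs_duration_s = cs_duration_s, us_duration_s = us_duration_s,
                 iti_range_s = as.numeric(iti_range_s), lead_in_s = lead_in_s),
            class = "protocol_spec")
}

#' Generate an event schedule from a protocol
#'
#' Conditioning trials are CS intervals whose US co-terminates with the CS
#' (US offset equals CS offset). Loom trials are `loom_reps_per_trial`
#' expansion-onset instants spaced `expand + hold + pause` seconds apart.
#' Inter-trial intervals are drawn uniformly from `iti_range_s`; the ITI is
#' measured from the end of one trial to the onset of the next.
#'
#' @param protocol A [protocol_spec()].
#' @param seed RNG seed (determines the ITIs).
#' @return An [event_log()].
#' @export
generate_event_schedule <- function(protocol, seed = 1L) {
  stopifnot(inherits(protocol, "protocol_spec"))
  p <- protocol
  with_seed(seed, {
    itis <- stats::runif(p$n_trials - 1L, p$iti_range_s[1], p$iti_range_s[2])
    if (p$kind == "conditioning") {
      onset <- numeric(p$n_trials)
      t0 <- p$lead_in_s
      for (i in seq_len(p$n_trials)) {
        onset[i] <- t0
        t0 <- t0 + p$cs_duration_s + if (i < p$n_trials) itis[i] else 0
      }
      cs_off <- onset + p$cs_duration_s
      ev <- event_log(
        label = rep(c("cs", "us"), each = p$n_trials),
        onset_s = c(onset, cs_off - p$us_duration_s),
        offset_s = c(cs_off, cs_off),
        trial_index = rep(seq_len(p$n_trials), 2L))
    } else {
      period <- p$loom_expand_s + p$loom_hold_s + p$loom_pause_s
      trial_len <- p$loom_reps_per_trial * period
      onsets <- numeric(0); trial <- integer(0)
      t0 <- p$lead_in_s
      for (i in seq_len(p$n_trials)) {
        onsets <- c(onsets, t0 + (seq_len(p$loom_reps_per_trial) - 1L) * period)
        trial <- c(trial, rep(i, p$loom_reps_per_trial))
        t0 <- t0 + trial_len + if (i < p$n_trials) itis[i] else 0
      }
      ev <- event_log(label = rep("loom", length(onsets)), onset_s = onsets,
                      offset_s = NA_real_, trial_index = trial)
    }
    ev
  })
}

#' Generate a synthetic dual-channel photometry session
#'
#' The GCaMP channel is
#' `F0 * (1 + A_b * exp(-t/tau_b)) * (1 + sum of transient kernels) + noise`;
#' the isosbestic channel carries an independent bleaching trend, noise, and
#' optional downward step artifacts (emulating sudden patch-cord/LED changes)
#' at the requested times. Both channels share one time base.
#'
#' @param spec A [session_spec()].
#' @param transients List of [transient_spec()] objects (all within the
#'   session).
#' @param artifact_times_s Times at which an isosbestic step artifact is
#'   injected.
#' @param artifact_step_frac Step amplitude as a fraction of the isosbestic
#'   baseline (default 0.05).
#' @return A list with elements `recording` ([raw_recording()]) and
#'   `ground_truth` (transients, schedule placeholders, artifact times).
#' @export
generate_photometry_session <- function(spec, transients = list(),
                                        artifact_times_s = numeric(),
                                        artifact_step_frac = 0.05) {
  stopifnot(inherits(spec, "session_spec"))
  if (inherits(transients, "transient_spec")) transients <- list(transients)
  for (tr in transients) {
    stopifnot(inherits(tr, "transient_spec"))
    if (tr$onset_s >= spec$duration_s)
      stop_fmt("transient onset %g s outside session (%g s)", tr$onset_s,
               spec$duration_s)
  }
  if (any(artifact_times_s < 0 | artifact_times_s >= spec$duration_s))
    stop_fmt("artifact times must lie within the session")
  n <- round(spec$duration_s * spec$fs_hz)
  t <- (seq_len(n) - 1L) / spec$fs_hz
  trend <- 1 + spec$bleach_amplitude * exp(-t / spec$bleach_tau_s)
  tsum <- numeric(n)
  for (tr in transients)
    tsum <- tsum + tr$amplitude *
      transient_kernel(t - tr$onset_s, tr$rise_tau_s, tr$decay_tau_s)
  iso_f0 <- 0.8 * spec$baseline_f0
  with_seed(spec$seed, {
    gcamp <- spec$baseline_f0 * trend * (1 + tsum) +
      stats::rnorm(n, 0, spec$noise_sd)
    iso_trend <- 1 + spec$bleach_amplitude * exp(-t / (1.2 * spec$bleach_tau_s))
    iso <- iso_f0 * iso_trend + stats::rnorm(n, 0, spec$noise_sd)
    for (at in artifact_times_s)
      iso[t >= at] <- iso[t >= at] - artifact_step_frac * iso_f0
    rec <- raw_recording(t, gcamp, iso, fs_hz = spec$fs_hz)
    gt <- list(
      transients = lapply(transients, unclass),
      artifact_times_s = as.numeric(artifact_times_s),
      spec = unclass(spec))
    list(recording = rec, ground_truth = gt)
  })
}

#' Behavior track specification
#'
#' @param duration_s Session length, seconds.
#' @param arena_cm Arena width/height, cm (default 37 x 40 open-top arena).
#' @param frame_rate_hz Camera frame rate (default 30).
#' @param freeze_bouts List of `c(start_s, stop_s)` immobility bouts; snapped
#'   to the frame grid so scored freezing percentages are exactly recoverable.
#' @param rearing_times_s Rearing annotation times.
#' @param escape_windows List of `c(start_s, stop_s, speed_multiplier)` sprint
#'   windows; the multiplier (> 1) scales the baseline speed.
#' @param baseline_speed_cm_s Exploratory locomotion speed outside special
#'   windows (default 8 cm/s).
#' @param seed RNG seed.
#' @return A list of class `behavior_spec`.
#' @export
behavior_spec <- function(duration_s, arena_cm = c(37, 40), frame_rate_hz = 30,
                          freeze_bouts = list(), rearing_times_s = numeric(),
                          escape_windows = list(), baseline_speed_cm_s = 8,
                          seed = 1L) {
  check_scalar_num(duration_s, "duration_s", positive = TRUE)
  check_scalar_num(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  check_scalar_num(baseline_speed_cm_s, "baseline_speed_cm_s", positive = TRUE)
  norm_win <- function(w, len, what) {
    w <- as.numeric(w)
    if (length(w) != len) stop_fmt("%s entries need %d values", what, len)
    if (w[1] < 0 || w[2] > duration_s || w[2] <= w[1])
      stop_fmt("%s window [%g, %g) invalid for a %g s session", what, w[1], w[2],
               duration_s)
    w
  }
  freeze_bouts <- lapply(freeze_bouts, norm_win, len = 2L, what = "freeze_bouts")
  escape_windows <- lapply(escape_windows, function(w) {
    w <- norm_win(w, 3L, "escape_windows")
    if (w[3] <= 1) stop_fmt("escape speed_multiplier must be > 1 (got %g)", w[3])
    w
  })
  for (f in freeze_bouts) for (e in escape_windows)
    if (interval_overlap(f[1], f[2], e[1], e[2]) > 0)
      stop_fmt("freeze bout [%g, %g) overlaps escape window [%g, %g)",
               f[1], f[2], e[1], e[2])
  if (any(rearing_times_s < 0 | rearing_times_s > duration_s))
    stop_fmt("rearing times must lie within the session")
  structure(list(duration_s = duration_s, arena_cm = as.numeric(arena_cm),
                 frame_rate_hz = frame_rate_hz, freeze_bouts = freeze_bouts,
                 rearing_times_s = sort(as.numeric(rearing_times_s)),
                 escape_windows = escape_windows,
                 baseline_speed_cm_s = baseline_speed_cm_s,
                 seed = as.integer(seed)),
            class = "behavior_spec")
}

#' Generate a synthetic behavior track
#'
#' Emits a random-heading walk whose per-frame speed equals the baseline speed
#' outside special windows, zero inside freeze bouts, and
#' `multiplier * baseline` inside escape windows. Near the arena walls the
#' heading is steered back toward the center so step lengths (and hence
#' measured speeds) are preserved. Freeze bouts are snapped to the frame grid.
#'
#' @param spec A [behavior_spec()].
#' @return A list with `track` ([behavior_track()]) and `ground_truth`
#'   (snapped freeze bouts, rearing times, escape windows).
#' @export
generate_behavior_track <- function(spec) {
  stopifnot(inherits(spec, "behavior_spec"))
  fps <- spec$frame_rate_hz
  n <- round(spec$duration_s * fps)
  t <- (seq_len(n) - 1L) / fps
  snap <- function(w) c(round(w[1] * fps) / fps, round(w[2] * fps) / fps)
  fb <- lapply(spec$freeze_bouts, snap)
  # per-interval target speed (interval i covers [t_i, t_{i+1}))
  speed <- rep(spec$baseline_speed_cm_s, n - 1L)
  for (w in fb) speed[t[-n] >= w[1] & t[-n] < w[2] - 1e-9] <- 0
  for (w in spec$escape_windows)
    speed[t[-n] >= w[1] & t[-n] < w[2]] <- w[3] * spec$baseline_speed_cm_s
  wdt <- spec$arena_cm[1]; hgt <- spec$arena_cm[2]
  with_seed(spec$seed, {
    x <- numeric(n); y <- numeric(n)
    x[1] <- wdt / 2; y[1] <- hgt / 2
    theta <- stats::runif(1, 0, 2 * pi)
    dth <- stats::rnorm(n - 1L, 0, 0.4)
    margin <- max(2, 2 * max(speed) / fps)
    for (i in seq_len(n - 1L)) {
      near_wall <- x[i] < margin || x[i] > wdt - margin ||
        y[i] < margin || y[i] > hgt - margin
      if (near_wall) {
        theta <- atan2(hgt / 2 - y[i], wdt / 2 - x[i]) + 0.3 * dth[i]
      } else {
        theta <- theta + dth[i]
      }
      step <- speed[i] / fps
      x[i + 1L] <- min(max(x[i] + step * cos(theta), 0), wdt)
      y[i + 1L] <- min(max(y[i] + step * sin(theta), 0), hgt)
    }
    trk <- behavior_track(t, x_cm = x, y_cm = y,
                          rearing_times_s = spec$rearing_times_s,
                          frame_rate_hz = fps, arena_cm = spec$arena_cm)
    gt <- list(freeze_bouts = fb, rearing_times_s = spec$rearing_times_s,
               escape_windows = spec$escape_windows,
               baseline_speed_cm_s = spec$baseline_speed_cm_s,
               frame_rate_hz = fps, duration_s = spec$duration_s)
    list(track = trk, ground_truth = gt)
  })
}
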