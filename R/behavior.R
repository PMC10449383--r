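# Defensive-behavior scoring from trajectories / motion indices:
# freezing (complete immobility >= 1 s), freezing percentages, pre-CS
# freezing, the differential rearing score, escape detection (speed > 3x the
# pre-stimulus mean), and locomotion/anxiety metrics (line crosses,
# center-time percentage).

# Per-frame motion measure: interval i covers [t_i, t_i + dt). With positions,
# the measure is centroid speed (cm/s) over the interval to the next frame
# (n - 1 values); with a motion index only, the index itself is used.
track_motion <- function(track) {
  stopifnot(inherits(track, "behavior_track"))
  t <- track$frame_time_s
  if (!is.null(track$x_cm)) {
    n <- length(t)
    d <- sqrt(diff(track$x_cm)^2 + diff(track$y_cm)^2)
    v <- d / diff(t)
    list(t = t[-n], v = v, dt = stats::median(diff(t)), kind = "speed")
  } else {
    list(t = t, v = track$motion_index, dt = stats::median(diff(t)),
         kind = "motion_index")
  }
}

#' Detect freezing bouts
#'
#' Freezing is complete immobility (motion below threshold) lasting at least
#' `min_bout_s`; shorter sub-threshold runs are not bouts. Bouts are maximal
#' runs of immobile frames, reported as half-open intervals.
#'
#' @param track A [behavior_track()].
#' @param motion_threshold Speed (cm/s) or motion-index value below which a
#'   frame is immobile.
#' @param min_bout_s Minimum bout duration, seconds (default 1).
#' @return data.frame with columns `start_s`, `stop_s` (possibly 0 rows).
#' @export
detect_freezing <- function(track, motion_threshold = 0.5, min_bout_s = 1.0) {
  m <- track_motion(track)
  if (length(m$v) == 0L) stop_fmt("empty track")
  check_scalar_num(min_bout_s, "min_bout_s", positive = TRUE)
  still <- m$v < motion_threshold
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths * m$dt >= min_bout_s - 1e-9)
  data.frame(start_s = m$t[starts[keep]],
             stop_s = m$t[ends[keep]] + m$dt)
}

#' Freezing percentage within a window
#'
#' 100 x (total freezing time inside the window) / (window length); bouts are
#' clipped to the window.
#'
#' @param bouts A [detect_freezing()] result (or any `start_s`/`stop_s`
#'   data.frame).
#' @param window `c(start_s, stop_s)` of the scoring window (e.g. a CS
#'   presentation, or the 30 s after loom onset).
#' @return Percentage in [0, 100].
#' @export
freezing_percentage <- function(bouts, window) {
  if (length(window) != 2L || window[2] <= window[1])
    stop_fmt("window must be c(start, stop) with stop > start")
  if (nrow(bouts) == 0L) return(0)
  tot <- sum(interval_overlap(bouts$start_s, bouts$stop_s, window[1], window[2]))
  100 * tot / (window[2] - window[1])
}

#' Pre-CS freezing percentage
#'
#' Mean over CS presentations of the freezing percentage in the
#' `precs_window_s` seconds before each CS onset. A CS whose pre-window
#' starts before the track does is skipped (with a warning).
#'
#' @param bouts A [detect_freezing()] result.
#' @param events An [event_log()] containing `cs` intervals.
#' @param precs_window_s Pre-CS window length, seconds (default 25).
#' @param track_start_s Time of the first scoreable instant (default 0).
#' @return Mean percentage across scoreable CS trials.
#' @export
pre_cs_freezing <- function(bouts, events, precs_window_s = 25,
                            track_start_s = 0) {
  onsets <- events$onset_s[events$label == "cs"]
  if (length(onsets) == 0L) stop_fmt("no 'cs' events in the log")
  ok <- onsets - precs_window_s >= track_start_s - 1e-9
  if (any(!ok)) {
    warning(sprintf("%d CS trial(s) skipped: pre-CS window precedes the track",
                    sum(!ok)), call. = FALSE)
    onsets <- onsets[ok]
  }
  if (length(onsets) == 0L) return(NA_real_)
  mean(vapply(onsets, function(o)
    freezing_percentage(bouts, c(o - precs_window_s, o)), numeric(1)))
}

#' Differential rearing score
#'
#' Rearing events are counted in the 30 s before (baseline) and after the
#' stimulus onset; the differential is post minus pre, so negative values
#' indicate suppression of exploratory rearing. Windows are half-open, so an
#' event exactly at onset counts in the post window.
#'
#' @param rearing_times_s Annotated rearing event times.
#' @param onset_s Stimulus (loom) onset.
#' @param window_s Window length on each side, seconds (default 30).
#' @return List with `pre`, `post`, `differential`.
#' @export
rearing_differential <- function(rearing_times_s, onset_s, window_s = 30) {
  pre <- sum(rearing_times_s >= onset_s - window_s & rearing_times_s < onset_s)
  post <- sum(rearing_times_s >= onset_s & rearing_times_s < onset_s + window_s)
  list(pre = pre, post = post, differential = post - pre)
}

#' Detect escape events
#'
#' An escape is a sharp locomotor acceleration: a maximal run, within the
#' scoring window after stimulus onset, where the smoothed speed exceeds
#' `multiplier` times the mean speed over the pre-stimulus window. Speed is
#' smoothed with a centered moving average (edges padded by replication) to
#' suppress single-frame tracking jitter.
#'
#' @param track A [behavior_track()] with positions.
#' @param onset_s Stimulus onset, seconds.
#' @param multiplier Threshold multiple of the pre-stimulus mean speed
#'   (default 3).
#' @param window_s Scoring window length before and after onset (default 30).
#' @param smooth_s Moving-average width, seconds (default 0.25).
#' @return List with `count` (number of escape runs; NA when not evaluable),
#'   `status` (`"ok"` or `"not_evaluable"`), `reference_speed`.
#' @export
detect_escapes <- function(track, onset_s, multiplier = 3, window_s = 30,
                           smooth_s = 0.25) {
  m <- track_motion(track)
  if (m$kind != "speed")
    stop_fmt("escape detection needs positions (speed), not a motion index")
  pre <- m$v[m$t >= onset_s - window_s & m$t < onset_s]
  if (length(pre) == 0L) stop_fmt("empty pre-stimulus segment")
  ref <- mean(pre)
  if (ref == 0)
    return(list(count = NA_integer_, status = "not_evaluable",
                reference_speed = 0))
  k <- max(1L, as.integer(round(smooth_s / m$dt)))
  v_s <- smooth_replicate(m$v, k)
  inwin <- which(m$t >= onset_s & m$t < onset_s + window_s)
  fast <- v_s[inwin] > multiplier * ref
  r <- rle(fast)
  list(count = sum(r$values), status = "ok", reference_speed = ref)
}

# centered moving average with edge replication
smooth_replicate <- function(v, k) {
  if (k <= 1L) return(v)
  half_l <- (k - 1L) %/% 2L
  half_r <- k - 1L - half_l
  vp <- c(rep(v[1], half_l), v, rep(v[length(v)], half_r))
  as.numeric(stats::filter(vp, rep(1 / k, k), sides = 2))[
    (half_l + 1L):(half_l + length(v))]
}

#' Locomotion and anxiety metrics
#'
#' Line crosses count transitions of the centroid across virtual grid lines;
#' center time is the percentage of frames spent inside a central rectangle.
#' Both require positions; motion-index-only tracks report the metrics as
#' unavailable.
#'
#' @param track A [behavior_track()].
#' @param window `c(start_s, stop_s)` analysis window.
#' @param lines_x,lines_y Grid line positions (cm); defaults split the arena
#'   into thirds along each axis.
#' @param center_rect `c(xmin, ymin, xmax, ymax)` of the center zone;
#'   defaults to the central rectangle of half the arena dimensions.
#' @return List with `status`, `line_crosses`, `center_time_pct`.
#' @export
locomotion_metrics <- function(track, window, lines_x = NULL, lines_y = NULL,
                               center_rect = NULL) {
  stopifnot(inherits(track, "behavior_track"))
  if (is.null(track$x_cm))
    return(list(status = "unavailable", line_crosses = NA_integer_,
                center_time_pct = NA_real_))
  w <- track$arena_cm[1]; h <- track$arena_cm[2]
  lines_x <- lines_x %||% (w * c(1, 2) / 3)
  lines_y <- lines_y %||% (h * c(1, 2) / 3)
  center_rect <- center_rect %||% c(w / 4, h / 4, 3 * w / 4, 3 * h / 4)
  sel <- track$frame_time_s >= window[1] & track$frame_time_s < window[2]
  if (!any(sel)) stop_fmt("no frames inside the analysis window")
  x <- track$x_cm[sel]; y <- track$y_cm[sel]
  crosses <- 0L
  for (L in lines_x) crosses <- crosses + sum(diff(x > L) != 0)
  for (L in lines_y) crosses <- crosses + sum(diff(y > L) != 0)
  inside <- x >= center_rect[1] & x <= center_rect[3] &
    y >= center_rect[2] & y <= center_rect[4]
  list(status = "ok", line_crosses = crosses,
       center_time_pct = 100 * mean(inside))
}

#' Score defensive behavior for a session
#'
#' Applies the full behavioral scoring battery per trial: freezing percentage
#' in the scoring window after each trial onset (loom) or during each CS,
#' pre-CS freezing, the rearing differential and escape count (loom), and
#' tail-rattling counts passed through from manual annotation.
#'
#' @param track A [behavior_track()].
#' @param events An [event_log()].
#' @param cfg A [run_config()].
#' @param tail_rattling Optional integer vector of manually annotated
#'   tail-rattling counts per trial (passthrough; never computed).
#' @return data.frame with one row per trial and label.
#' @export
score_defensive_behavior <- function(track, events, cfg = default_config(),
                                     tail_rattling = NULL) {
  bouts <- detect_freezing(track, cfg$motion_threshold, cfg$freezing_min_bout_s)
  rows <- list()
  labs <- intersect(c("loom", "cs"), unique(events$label))
  for (lab in labs) {
    ev <- events[events$label == lab, , drop = FALSE]
    onsets <- vapply(split(ev$onset_s, ev$trial_index), min, numeric(1))
    tri <- as.integer(names(onsets))
    for (j in seq_along(onsets)) {
      o <- onsets[j]
      if (lab == "loom") {
        win <- c(o, o + cfg$scoring_window_s)
        rd <- rearing_differential(track$rearing_times_s, o, cfg$scoring_window_s)
        esc <- detect_escapes(track, o, cfg$escape_multiplier,
                              cfg$scoring_window_s, cfg$escape_smooth_s)
        rows[[length(rows) + 1L]] <- data.frame(
          trial = tri[j], label = lab,
          freezing_pct = freezing_percentage(bouts, win),
          pre_cs_freezing_pct = NA_real_,
          rearing_pre = rd$pre, rearing_post = rd$post,
          rearing_differential = rd$differential,
          escape_events = esc$count, escape_status = esc$status,
          tail_rattling = if (!is.null(tail_rattling)) tail_rattling[j] else NA_integer_,
          stringsAsFactors = FALSE)
      } else {
        off <- ev$offset_s[ev$trial_index == tri[j]][1]
        if (is.na(off)) stop_fmt("cs events need offsets")
        pc <- if (o - cfg$precs_window_s >= track$frame_time_s[1] - 1e-9)
          freezing_percentage(bouts, c(o - cfg$precs_window_s, o)) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          trial = tri[j], label = lab,
          freezing_pct = freezing_percentage(bouts, c(o, off)),
          pre_cs_freezing_pct = pc,
          rearing_pre = NA_integer_, rearing_post = NA_integer_,
          rearing_differential = NA_integer_,
          escape_events = NA_integer_, escape_status = NA_character_,
          tail_rattling = if (!is.null(tail_rattling)) tail_rattling[j] else NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) stop_fmt("no loom or cs events to score")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
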