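# On-disk representations: recording.csv, events.csv, behavior.csv,
# ground_truth.json. Times are seconds (float) from recording start; intervals
# are half-open [onset, offset).

#' Construct a dual-channel photometry recording
#'
#' @param time_s Strictly increasing sample clock, seconds.
#' @param gcamp Calcium-dependent fluorescence channel.
#' @param isosbestic Calcium-independent (isosbestic excitation) channel, used
#'   only for artifact quality control.
#' @param fs_hz Sampling rate; inferred from the median time step when NULL.
#'   Must agree with the median step within 1% when given.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(time_s, gcamp, isosbestic, fs_hz = NULL) {
  n <- length(time_s)
  if (length(gcamp) != n || length(isosbestic) != n)
    stop_fmt("channel lengths differ: time %d, gcamp %d, isosbestic %d",
             n, length(gcamp), length(isosbestic))
  if (n < 2L) stop_fmt("a recording needs at least 2 samples")
  dt <- diff(time_s)
  bad <- which(dt <= 0)
  if (length(bad) > 0L)
    stop_fmt("time_s must be strictly increasing; violation at row %d", bad[1] + 1L)
  fs_med <- 1 / stats::median(dt)
  if (is.null(fs_hz)) {
    fs_hz <- fs_med
  } else if (abs(fs_hz - fs_med) > 0.01 * fs_hz) {
    stop_fmt("fs_hz = %g inconsistent with median time step (implies %g Hz)",
             fs_hz, fs_med)
  }
  structure(list(time_s = as.numeric(time_s), gcamp = as.numeric(gcamp),
                 isosbestic = as.numeric(isosbestic), fs_hz = fs_hz),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples @ %.6g Hz (%.3g s)\n",
              length(x$time_s), x$fs_hz, diff(range(x$time_s))))
  invisible(x)
}

#' Read / write a recording CSV (`time_s,gcamp,isosbestic`)
#'
#' @param path CSV file path.
#' @return `read_recording()` returns a [raw_recording()].
#' @export
read_recording <- function(path) {
  d <- read_checked_csv(path, c("time_s", "gcamp", "isosbestic"))
  raw_recording(d$time_s, d$gcamp, d$isosbestic)
}

#' @rdname read_recording
#' @param rec A `raw_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  write_num_csv(data.frame(time_s = rec$time_s, gcamp = rec$gcamp,
                           isosbestic = rec$isosbestic), path)
  invisible(path)
}

#' Construct an event log
#'
#' Labeled intervals (CS, US) or instants (loom expansions) on the recording
#' clock. Intervals are half-open; instants have `offset_s = NA`.
#'
#' @param label Character labels (`loom`, `cs`, `us`, or custom).
#' @param onset_s,offset_s Onset and offset, seconds; `offset_s` NA for
#'   instantaneous events.
#' @param trial_index Integer trial membership (loom trials group several
#'   expansion instants under one index).
#' @return A `data.frame` of class `event_log`, sorted by onset.
#' @export
event_log <- function(label, onset_s, offset_s = NA_real_, trial_index = seq_along(onset_s)) {
  d <- data.frame(label = as.character(label), onset_s = as.numeric(onset_s),
                  offset_s = as.numeric(offset_s),
                  trial_index = as.integer(trial_index),
                  stringsAsFactors = FALSE)
  if (any(!nzchar(d$label) | is.na(d$label))) stop_fmt("event labels must be nonempty")
  has_off <- !is.na(d$offset_s)
  if (any(has_off & d$offset_s <= d$onset_s)) {
    k <- which(has_off & d$offset_s <= d$onset_s)[1]
    stop_fmt("event %d ('%s'): offset (%g) must exceed onset (%g)",
             k, d$label[k], d$offset_s[k], d$onset_s[k])
  }
  d <- d[order(d$onset_s), , drop = FALSE]
  rownames(d) <- NULL
  # overlapping same-label intervals are a logging error
  for (lab in unique(d$label)) {
    di <- d[d$label == lab & !is.na(d$offset_s), , drop = FALSE]
    if (nrow(di) > 1L && any(di$onset_s[-1] < di$offset_s[-nrow(di)]))
      stop_fmt("overlapping '%s' intervals in event log", lab)
  }
  class(d) <- c("event_log", "data.frame")
  d
}

#' Read / write an event CSV (`label,onset_s,offset_s,trial_index`)
#'
#' An empty `offset_s` field denotes an instantaneous event.
#'
#' @param path CSV file path.
#' @return `read_events()` returns an [event_log()].
#' @export
read_events <- function(path) {
  d <- read_checked_csv(path, c("label", "onset_s", "offset_s", "trial_index"),
                        monotone_col = NULL)
  event_log(d$label, d$onset_s, d$offset_s, d$trial_index)
}

#' @rdname read_events
#' @param events An `event_log`.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_log"))
  write_num_csv(as.data.frame(events), path)
  invisible(path)
}

#' Construct a behavior track
#'
#' Timestamped position (and/or motion index) frames with annotated rearing
#' events. At least one of position or motion index must be present.
#'
#' @param frame_time_s Monotone frame timestamps, seconds.
#' @param x_cm,y_cm Optional centroid position, cm.
#' @param motion_index Optional nonnegative per-frame motion measure.
#' @param rearing_times_s Annotated rearing event times (manual scoring input).
#' @param frame_rate_hz Frame rate; inferred from timestamps when NULL.
#' @param arena_cm Arena width/height `c(w, h)` in cm (positions validated
#'   against it when present).
#' @return An object of class `behavior_track`.
#' @export
behavior_track <- function(frame_time_s, x_cm = NULL, y_cm = NULL,
                           motion_index = NULL, rearing_times_s = numeric(),
                           frame_rate_hz = NULL, arena_cm = c(37, 40)) {
  n <- length(frame_time_s)
  if (n < 2L) stop_fmt("a behavior track needs at least 2 frames")
  if (any(diff(frame_time_s) <= 0))
    stop_fmt("frame_time_s must be strictly increasing; violation at row %d",
             which(diff(frame_time_s) <= 0)[1] + 1L)
  has_pos <- !is.null(x_cm) && !is.null(y_cm)
  if (!has_pos && is.null(motion_index))
    stop_fmt("a behavior track needs positions (x_cm, y_cm) or a motion_index")
  if (has_pos) {
    if (length(x_cm) != n || length(y_cm) != n)
      stop_fmt("position columns must match frame count")
    if (any(x_cm < -1e-9 | x_cm > arena_cm[1] + 1e-9) ||
        any(y_cm < -1e-9 | y_cm > arena_cm[2] + 1e-9))
      stop_fmt("positions fall outside the %g x %g cm arena", arena_cm[1], arena_cm[2])
  }
  if (!is.null(motion_index)) {
    if (length(motion_index) != n) stop_fmt("motion_index must match frame count")
    if (any(motion_index < 0)) stop_fmt("motion_index must be >= 0")
  }
  if (is.null(frame_rate_hz)) frame_rate_hz <- 1 / stats::median(diff(frame_time_s))
  structure(list(frame_time_s = as.numeric(frame_time_s),
                 x_cm = if (has_pos) as.numeric(x_cm),
                 y_cm = if (has_pos) as.numeric(y_cm),
                 motion_index = if (!is.null(motion_index)) as.numeric(motion_index),
                 rearing_times_s = sort(as.numeric(rearing_times_s)),
                 frame_rate_hz = frame_rate_hz,
                 arena_cm = as.numeric(arena_cm)),
            class = "behavior_track")
}

#' @export
print.behavior_track <- function(x, ...) {
  cat(sprintf("<behavior_track> %d frames @ %.4g Hz; %s; %d rearing events\n",
              length(x$frame_time_s), x$frame_rate_hz,
              if (is.null(x$x_cm)) "motion index only" else "positions",
              length(x$rearing_times_s)))
  invisible(x)
}

#' Read / write a behavior CSV (`frame_time_s,x_cm,y_cm[,motion_index]`)
#'
#' Rearing annotations travel in a companion single-column CSV
#' (`rearing_time_s`) because they are sparse manual annotations, not frames.
#'
#' @param path CSV file path.
#' @param rearing_path Optional path to the rearing annotation CSV.
#' @param arena_cm Arena dimensions, cm.
#' @return `read_behavior()` returns a [behavior_track()].
#' @export
read_behavior <- function(path, rearing_path = NULL, arena_cm = c(37, 40)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"frame_time_s" %in% names(d))
    stop_fmt("%s: missing required column 'frame_time_s'", path)
  has_pos <- all(c("x_cm", "y_cm") %in% names(d))
  rear <- numeric()
  if (!is.null(rearing_path)) {
    r <- utils::read.csv(rearing_path, stringsAsFactors = FALSE)
    if (!"rearing_time_s" %in% names(r))
      stop_fmt("%s: missing required column 'rearing_time_s'", rearing_path)
    rear <- r$rearing_time_s
  }
  behavior_track(d$frame_time_s,
                 x_cm = if (has_pos) d$x_cm,
                 y_cm = if (has_pos) d$y_cm,
                 motion_index = d[["motion_index"]],
                 rearing_times_s = rear, arena_cm = arena_cm)
}

#' @rdname read_behavior
#' @param track A `behavior_track`.
#' @export
write_behavior <- function(track, path, rearing_path = NULL) {
  stopifnot(inherits(track, "behavior_track"))
  d <- data.frame(frame_time_s = track$frame_time_s)
  if (!is.null(track$x_cm)) { d$x_cm <- track$x_cm; d$y_cm <- track$y_cm }
  if (!is.null(track$motion_index)) d$motion_index <- track$motion_index
  write_num_csv(d, path)
  if (!is.null(rearing_path))
    write_num_csv(data.frame(rearing_time_s = track$rearing_times_s), rearing_path)
  invisible(path)
}

#' Write / read session ground truth as JSON
#'
#' @param gt Ground-truth list emitted by the synthetic generators.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# -- internal CSV plumbing ---------------------------------------------------

read_checked_csv <- function(path, required, monotone_col = "time_s") {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss) > 0L)
    stop_fmt("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  if (!is.null(monotone_col)) {
    tv <- d[[monotone_col]]
    bad <- which(diff(tv) <= 0)
    if (length(bad) > 0L)
      stop_fmt("%s: %s not strictly increasing at row %d", path, monotone_col,
               bad[1] + 1L)
  }
  d
}

# 15 significant digits keeps round-trips within 1e-9 relative.
write_num_csv <- function(d, path) {
  for (k in names(d)) if (is.double(d[[k]])) {
    v <- formatC(d[[k]], digits = 15, format = "g")
    v[is.na(d[[k]])] <- NA_character_
    d[[k]] <- v
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
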