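# Defensive-behavior scoring against brute-force interval/threshold oracles.

# A hand-built track: motion index encodes immobility runs directly.
motion_track <- function(m, fps = 10) {
  behavior_track(frame_time_s = (seq_along(m) - 1) / fps, motion_index = m,
                 frame_rate_hz = fps)
}

test_that("freezing bouts are maximal sub-threshold runs of at least 1 s", {
  fps <- 10
  # runs of immobility: 0.8 s, 1.2 s, 3.0 s separated by movement
  m <- c(rep(5, 10), rep(0, 8), rep(5, 10), rep(0, 12), rep(5, 10),
         rep(0, 30), rep(5, 10))
  bouts <- detect_freezing(motion_track(m, fps), motion_threshold = 0.5,
                           min_bout_s = 1)
  expect_equal(nrow(bouts), 2L)
  expect_equal(bouts$stop_s - bouts$start_s, c(1.2, 3.0))
  want <- oracle_immobile_runs((seq_along(m) - 1) / fps, m, 0.5, 1 / fps, 1)
  expect_equal(bouts, want)
  # a 0.5 s run alone is no bout; full-window immobility is one bout
  expect_equal(nrow(detect_freezing(motion_track(c(rep(5, 10), rep(0, 5), rep(5, 10))),
                                    0.5, 1)), 0L)
  full <- detect_freezing(motion_track(rep(0, 300)), 0.5, 1)
  expect_equal(nrow(full), 1L)
  expect_equal(full$stop_s - full$start_s, 30)
})

test_that("freezing percentage clips bouts to the window", {
  bouts <- data.frame(start_s = c(5, 18), stop_s = c(11, 22))
  expect_equal(freezing_percentage(bouts, c(2, 22)), 100 * 10 / 20)  # 10 s in 20 s
  expect_equal(freezing_percentage(data.frame(start_s = numeric(),
                                              stop_s = numeric()), c(0, 30)), 0)
  # bout straddling the edge: 3 s inside a 30 s window -> 10%
  straddle <- data.frame(start_s = 28, stop_s = 40)
  expect_equal(freezing_percentage(straddle, c(1, 31)), 10)
  expect_equal(freezing_percentage(straddle, c(1, 31)),
               100 * oracle_bout_overlap(straddle, 1, 31) / 30)
  expect_error(freezing_percentage(bouts, c(5, 5)), "window")
})

test_that("pre-CS freezing averages the 25 s pre-onset windows over trials", {
  ev <- event_log(c("cs", "cs"), c(30, 90), c(50, 110), 1:2)
  bouts <- data.frame(start_s = c(10, 80), stop_s = c(20, 85))
  # windows [5,30) and [65,90): overlaps 10 s and 5 s -> 40% and 20% -> mean 30%
  expect_equal(pre_cs_freezing(bouts, ev), 30)
  expect_equal(pre_cs_freezing(data.frame(start_s = numeric(),
                                          stop_s = numeric()), ev), 0)
  # identical bouts per trial -> same as a single window
  b2 <- data.frame(start_s = c(10, 70), stop_s = c(20, 80))
  expect_equal(pre_cs_freezing(b2, ev),
               freezing_percentage(b2, c(5, 30)))
  # first CS too early: skipped with a warning
  ev2 <- event_log(c("cs", "cs"), c(10, 90), c(30, 110), 1:2)
  expect_warning(v <- pre_cs_freezing(bouts, ev2), "skipped")
  expect_equal(v, freezing_percentage(bouts, c(65, 90)))
})

test_that("the rearing differential is post minus pre with half-open windows", {
  rd <- rearing_differential(c(5, 10, 15, 20, 25, 28, 35, 40, 55, 58), 30)
  expect_equal(rd$pre, 6L); expect_equal(rd$post, 4L)
  expect_equal(rd$differential, -2L)
  expect_equal(rearing_differential(numeric(), 30),
               list(pre = 0L, post = 0L, differential = 0L))
  # an event exactly at onset counts in the post window
  expect_equal(rearing_differential(30, 30)$post, 1L)
  expect_equal(rearing_differential(30, 30)$pre, 0L)
})

test_that("escape detection thresholds smoothed speed at 3x the pre-loom mean", {
  # constant-speed track: no escapes
  b0 <- behavior_spec(70, baseline_speed_cm_s = 6, seed = 41)
  tr0 <- generate_behavior_track(b0)$track
  expect_equal(detect_escapes(tr0, 35)$count, 0L)
  # one sprint at 3.5x baseline -> exactly one escape run
  b1 <- behavior_spec(70, escape_windows = list(c(40, 42, 3.5)),
                      baseline_speed_cm_s = 6, seed = 42)
  tr1 <- generate_behavior_track(b1)$track
  e1 <- detect_escapes(tr1, 35)
  expect_equal(e1$count, 1L)
  expect_equal(e1$status, "ok")
  # sprint at only 2x baseline stays below the 3x rule
  b2 <- behavior_spec(70, escape_windows = list(c(40, 42, 2)),
                      baseline_speed_cm_s = 6, seed = 43)
  tr2 <- generate_behavior_track(b2)$track
  expect_equal(detect_escapes(tr2, 35)$count, 0L)
  # zero reference speed -> not evaluable, not a division by zero
  b3 <- behavior_spec(70, freeze_bouts = list(c(0, 40)), seed = 44)
  tr3 <- generate_behavior_track(b3)$track
  e3 <- detect_escapes(tr3, 35)
  expect_equal(e3$status, "not_evaluable")
  expect_true(is.na(e3$count))
})

test_that("line crosses match a sign-change oracle and center time counts frames", {
  fps <- 10
  # back and forth across x = 10 five times, constant y
  x <- rep(c(8, 12), length.out = 11)
  t <- (0:10) / fps
  trk <- behavior_track(t, x_cm = x, y_cm = rep(20, 11), frame_rate_hz = fps)
  lm1 <- locomotion_metrics(trk, c(0, 2), lines_x = 10, lines_y = numeric())
  expect_equal(lm1$line_crosses, 10L)
  expect_equal(lm1$line_crosses, oracle_crossings(x, 10))
  # stationary track: zero crosses; center% is 0 or 100 by location
  trk2 <- behavior_track(t, x_cm = rep(18, 11), y_cm = rep(20, 11),
                         frame_rate_hz = fps)
  lm2 <- locomotion_metrics(trk2, c(0, 2))
  expect_equal(lm2$line_crosses, 0L)
  expect_equal(lm2$center_time_pct, 100)
  trk3 <- behavior_track(t, x_cm = rep(1, 11), y_cm = rep(1, 11),
                         frame_rate_hz = fps)
  expect_equal(locomotion_metrics(trk3, c(0, 2))$center_time_pct, 0)
  # half the frames inside the center -> 50%
  x4 <- c(rep(18, 5), rep(1, 5)); y4 <- c(rep(20, 5), rep(1, 5))
  trk4 <- behavior_track((0:9) / fps, x_cm = x4, y_cm = y4, frame_rate_hz = fps)
  expect_equal(locomotion_metrics(trk4, c(0, 1))$center_time_pct, 50)
  # motion-index-only tracks cannot provide locomotion metrics
  lm5 <- locomotion_metrics(motion_track(rep(1, 20)), c(0, 1))
  expect_equal(lm5$status, "unavailable")
})

test_that("scores are invariant to a common time shift", {
  dt <- 12.5
  b <- behavior_spec(80, freeze_bouts = list(c(40, 45)),
                     rearing_times_s = c(20, 50), seed = 77)
  tr <- generate_behavior_track(b)$track
  tr_shift <- behavior_track(tr$frame_time_s + dt, tr$x_cm, tr$y_cm,
                             rearing_times_s = tr$rearing_times_s + dt,
                             frame_rate_hz = tr$frame_rate_hz,
                             arena_cm = tr$arena_cm)
  bouts <- detect_freezing(tr)
  bouts_s <- detect_freezing(tr_shift)
  expect_equal(bouts_s$start_s, bouts$start_s + dt)
  expect_equal(freezing_percentage(bouts, c(35, 65)),
               freezing_percentage(bouts_s, c(35, 65) + dt))
  expect_equal(rearing_differential(tr$rearing_times_s, 35)$differential,
               rearing_differential(tr_shift$rearing_times_s, 35 + dt)$differential)
  expect_equal(detect_escapes(tr, 35)$count, detect_escapes(tr_shift, 35 + dt)$count)
})

test_that("generated ground truth is recovered from synthetic tracks", {
  b <- behavior_spec(100, freeze_bouts = list(c(35, 38.5), c(50, 52)),
                     rearing_times_s = c(10, 20, 28, 40, 70),
                     escape_windows = list(c(60, 61.5, 4)), seed = 101)
  g <- generate_behavior_track(b)
  bouts <- detect_freezing(g$track)
  gt <- g$ground_truth
  expect_equal(nrow(bouts), 2L)
  expect_equal(bouts$start_s, vapply(gt$freeze_bouts, `[`, numeric(1), 1))
  expect_equal(bouts$stop_s, vapply(gt$freeze_bouts, `[`, numeric(1), 2))
  # freezing % in [30, 60) window: bouts contribute 3.5 + 2 = 5.5 s
  expect_equal(freezing_percentage(bouts, c(30, 60)), 100 * 5.5 / 30)
  rd <- rearing_differential(g$track$rearing_times_s, 30)
  expect_equal(rd$pre, 3L); expect_equal(rd$post, 1L)  # events at 10,20,28 | 40
  expect_equal(detect_escapes(g$track, 55, window_s = 25)$count, 1L)
})

test_that("session-level score tables combine freezing, rearing and escapes", {
  sched <- generate_event_schedule(protocol_spec("loom", n_trials = 2L,
                                                 lead_in_s = 35), seed = 3)
  onsets <- vapply(split(sched$onset_s, sched$trial_index), min, numeric(1))
  dur <- max(sched$onset_s) + 40
  b <- behavior_spec(dur, freeze_bouts = lapply(unname(onsets),
                                                function(o) c(o + 1, o + 7)),
                     rearing_times_s = unname(onsets) - 3, seed = 11)
  trk <- generate_behavior_track(b)$track
  sc <- score_defensive_behavior(trk, sched)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$freezing_pct, rep(100 * 6 / 30, 2))
  expect_equal(sc$rearing_differential, rep(-1L, 2))
  expect_equal(sc$escape_events, rep(0L, 2))
})
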