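# Pipeline orchestration: simulate -> photometry -> events -> behavior ->
# report, as plain-file stages with a JSON manifest per stage. Stages are
# idempotent; rerunning with the same seed and inputs reproduces identical
# files. The exported cmd_* functions are the primary surface; the bundled
# Rscript (inst/cli/photothreat.R) is a thin wrapper over them.

pkg_version <- function() {
  as.character(utils::packageVersion("photothreat"))
}

write_manifest <- function(outdir, stage, inputs, outputs, seed = NULL) {
  digest <- function(paths) {
    paths <- as.character(unlist(paths))
    paths <- paths[file.exists(paths)]
    d <- as.list(tools::md5sum(paths))
    names(d) <- basename(paths)   # keep manifests independent of the run dir
    d
  }
  man <- list(stage = stage, tool_version = pkg_version(),
              seed = seed, inputs = digest(unlist(inputs)),
              outputs = digest(unlist(outputs)),
              status = "ok")
  jsonlite::write_json(man, file.path(outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(man)
}

require_inputs <- function(stage, paths) {
  miss <- paths[!file.exists(paths)]
  if (length(miss) > 0L)
    stop_fmt("stage '%s' is missing upstream output(s): %s (run the earlier stage first)",
             stage, paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Simulate a full synthetic session to disk
#'
#' Generates an event schedule, a photometry session with one transient locked
#' to each trial onset, and a behavior track with freezing starting shortly
#' after each trial onset; writes `recording.csv`, `events.csv`,
#' `behavior.csv`, `rearing.csv`, `ground_truth.json` and a stage manifest.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Master seed; sub-seeds for schedule, photometry and behavior
#'   are derived deterministically from it.
#' @param cfg A [run_config()].
#' @param protocol A [protocol_spec()].
#' @param transient_amplitude Peak dF/F of the per-trial transient.
#' @param noise_sd Photometry noise SD.
#' @param artifact_times_s Isosbestic step artifact times, if any.
#' @return Invisibly, a list of written paths.
#' @export
cmd_simulate <- function(outdir, seed = 1L, cfg = default_config(),
                         protocol = protocol_spec("loom", n_trials = 5L),
                         transient_amplitude = 0.05, noise_sd = 0.005,
                         artifact_times_s = numeric()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  sched <- generate_event_schedule(protocol, seed = seed)
  onsets <- vapply(split(sched$onset_s, sched$trial_index), min, numeric(1))
  dur <- max(sched$onset_s, sched$offset_s, na.rm = TRUE) + 60
  sspec <- session_spec(duration_s = dur, fs_hz = 1000, noise_sd = noise_sd,
                        seed = seed + 1L)
  trans <- lapply(unname(onsets), transient_spec,
                  amplitude = transient_amplitude)
  sess <- generate_photometry_session(sspec, trans, artifact_times_s)
  fb <- lapply(unname(onsets), function(o) c(o + 2, o + 10))
  bspec <- behavior_spec(duration_s = dur, freeze_bouts = fb,
                         rearing_times_s = pmax(0, unname(onsets) - 5),
                         seed = seed + 2L)
  beh <- generate_behavior_track(bspec)
  paths <- list(recording = file.path(outdir, "recording.csv"),
                events = file.path(outdir, "events.csv"),
                behavior = file.path(outdir, "behavior.csv"),
                rearing = file.path(outdir, "rearing.csv"),
                ground_truth = file.path(outdir, "ground_truth.json"))
  write_recording(sess$recording, paths$recording)
  write_events(sched, paths$events)
  write_behavior(beh$track, paths$behavior, paths$rearing)
  write_ground_truth(list(photometry = sess$ground_truth,
                          behavior = beh$ground_truth,
                          seed = seed), paths$ground_truth)
  write_manifest(outdir, "simulate", inputs = list(), outputs = paths,
                 seed = seed)
  invisible(paths)
}

#' Photometry stage: recording -> processed dF/F + QC
#'
#' Reads `recording.csv`, writes `processed.csv` (`time_s,dff`) and `qc.json`.
#'
#' @param outdir Run directory holding `recording.csv`.
#' @param cfg A [run_config()].
#' @return Invisibly, the [process_recording()] result.
#' @export
cmd_photometry <- function(outdir, cfg = default_config()) {
  rec_path <- file.path(outdir, "recording.csv")
  require_inputs("photometry", rec_path)
  rec <- read_recording(rec_path)
  pt <- process_recording(rec, cfg)
  proc_path <- file.path(outdir, "processed.csv")
  qc_path <- file.path(outdir, "qc.json")
  write_num_csv(data.frame(time_s = pt$time_s, dff = pt$dff), proc_path)
  jsonlite::write_json(
    list(passed = pt$qc$passed,
         max_isosbestic_jump_z = pt$qc$max_isosbestic_jump_z,
         flagged_times_s = pt$qc$flagged_times_s,
         fs_hz = pt$fs_hz, fit_coeffs = pt$fit_coeffs),
    qc_path, auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, "photometry", inputs = list(rec_path),
                 outputs = list(proc_path, qc_path))
  invisible(pt)
}

read_processed <- function(outdir) {
  proc_path <- file.path(outdir, "processed.csv")
  qc_path <- file.path(outdir, "qc.json")
  require_inputs("events", c(proc_path, qc_path))
  d <- read_checked_csv(proc_path, c("time_s", "dff"))
  q <- jsonlite::read_json(qc_path, simplifyVector = TRUE)
  qc <- structure(list(passed = isTRUE(q$passed),
                       max_isosbestic_jump_z = q$max_isosbestic_jump_z,
                       flagged_times_s = as.numeric(q$flagged_times_s)),
                  class = "qc_report")
  structure(list(time_s = d$time_s, dff = d$dff, fs_hz = q$fs_hz,
                 fit_coeffs = as.numeric(q$fit_coeffs),
                 isosbestic = NULL, qc = qc),
            class = "processed_trace")
}

#' Events stage: aligned z-scored trials and per-trial metrics
#'
#' Reads `processed.csv`, `qc.json` and `events.csv`; writes
#' `aligned_trials.csv` (long: trial, rel_time_s, z) and `trial_metrics.csv`.
#'
#' @param outdir Run directory.
#' @param label Event label to align to (`loom`, `cs` or `us`).
#' @param cfg A [run_config()].
#' @return Invisibly, the z-scored [aligned_trials()] set.
#' @export
cmd_events <- function(outdir, label = "loom", cfg = default_config()) {
  ev_path <- file.path(outdir, "events.csv")
  require_inputs("events", ev_path)
  pt <- read_processed(outdir)
  events <- read_events(ev_path)
  w <- cfg$windows[[label]]
  win <- window_spec(label, w$baseline_s, w$response_s)
  at <- zscore_baseline(align_trials(pt, events, win))
  met <- trial_metrics(at, cfg$peak_discard_fraction)
  long <- data.frame(
    trial = rep(seq_len(at$n_trials), each = length(at$rel_time_s)),
    rel_time_s = rep(at$rel_time_s, at$n_trials),
    z = as.vector(t(at$mat)))
  al_path <- file.path(outdir, sprintf("aligned_trials_%s.csv", label))
  mt_path <- file.path(outdir, sprintf("trial_metrics_%s.csv", label))
  write_num_csv(long, al_path)
  write_num_csv(met, mt_path)
  write_manifest(outdir, paste0("events_", label),
                 inputs = list(ev_path, file.path(outdir, "processed.csv")),
                 outputs = list(al_path, mt_path))
  invisible(at)
}

#' Behavior stage: defensive-behavior score table
#'
#' Reads `behavior.csv`, `rearing.csv` and `events.csv`; writes `scores.csv`.
#'
#' @param outdir Run directory.
#' @param cfg A [run_config()].
#' @return Invisibly, the score data.frame.
#' @export
cmd_behavior <- function(outdir, cfg = default_config()) {
  beh_path <- file.path(outdir, "behavior.csv")
  ev_path <- file.path(outdir, "events.csv")
  require_inputs("behavior", c(beh_path, ev_path))
  rear_path <- file.path(outdir, "rearing.csv")
  track <- read_behavior(beh_path,
                         rearing_path = if (file.exists(rear_path)) rear_path)
  events <- read_events(ev_path)
  sc <- score_defensive_behavior(track, events, cfg)
  sc_path <- file.path(outdir, "scores.csv")
  write_num_csv(sc, sc_path)
  write_manifest(outdir, "behavior", inputs = list(beh_path, ev_path),
                 outputs = list(sc_path))
  invisible(sc)
}

#' Report stage: condition summaries
#'
#' Collects the aligned trials and metrics into per-condition mean +/- SEM
#' traces (`mean_trace_<label>.csv`), the heatmap matrix
#' (`heatmap_<label>.csv`), and a JSON summary of the metric and behavior
#' tables.
#'
#' @param outdir Run directory.
#' @param label Event label summarized.
#' @param cfg A [run_config()].
#' @return Invisibly, the summary list.
#' @export
cmd_report <- function(outdir, label = "loom", cfg = default_config()) {
  ev_path <- file.path(outdir, "events.csv")
  require_inputs("report", ev_path)
  pt <- read_processed(outdir)
  events <- read_events(ev_path)
  w <- cfg$windows[[label]]
  win <- window_spec(label, w$baseline_s, w$response_s)
  at <- zscore_baseline(align_trials(pt, events, win))
  sm <- summarize_trials(at, cfg$peak_discard_fraction)
  mt_path <- file.path(outdir, sprintf("mean_trace_%s.csv", label))
  hm_path <- file.path(outdir, sprintf("heatmap_%s.csv", label))
  outs <- list(mt_path)
  if (sm$status == "ok") {
    write_num_csv(data.frame(rel_time_s = sm$rel_time_s, mean_z = sm$mean,
                             sem_z = sm$sem), mt_path)
    hm <- as.data.frame(sm$heatmap)
    names(hm) <- formatC(sm$rel_time_s, digits = 6, format = "g")
    utils::write.csv(cbind(trial = which(at$trial_qc), hm), hm_path,
                     row.names = FALSE)
    outs <- c(outs, hm_path)
  } else {
    write_num_csv(data.frame(rel_time_s = numeric(), mean_z = numeric(),
                             sem_z = numeric()), mt_path)
  }
  summary <- list(label = label, n_trials = at$n_trials,
                  n_retained = sm$n_retained, status = sm$status,
                  mean_auc = mean(sm$metrics$auc, na.rm = TRUE),
                  mean_time_to_peak_s = mean(sm$metrics$time_to_peak_s,
                                             na.rm = TRUE))
  sum_path <- file.path(outdir, sprintf("summary_%s.json", label))
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, paste0("report_", label), inputs = list(ev_path),
                 outputs = c(outs, sum_path))
  invisible(summary)
}

#' Run the full pipeline on a simulated session
#'
#' Convenience wrapper: simulate, process, align (loom), score behavior and
#' report, all inside `outdir`.
#'
#' @inheritParams cmd_simulate
#' @param label Event label for the events/report stages.
#' @return Invisibly, the report summary.
#' @export
run_pipeline <- function(outdir, seed = 1L, cfg = default_config(),
                         protocol = protocol_spec("loom", n_trials = 5L),
                         label = protocol$kind) {
  if (label == "conditioning") label <- "cs"
  cmd_simulate(outdir, seed = seed, cfg = cfg, protocol = protocol)
  cmd_photometry(outdir, cfg = cfg)
  cmd_events(outdir, label = label, cfg = cfg)
  cmd_behavior(outdir, cfg = cfg)
  invisible(cmd_report(outdir, label = label, cfg = cfg))
}
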