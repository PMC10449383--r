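# Run configuration: every tunable the analysis exposes, with defaults matching
# the acquisition/scoring conventions the pipeline implements (120 Hz analysis
# rate, first-order detrend, 10% peak filter, 1 s freezing bouts, 3x escape
# rule, 30 s scoring window, 25 s pre-CS window).

#' Default run configuration
#'
#' Returns the full configuration list used by every pipeline stage. Values can
#' be overridden via [run_config()] or a YAML/JSON file via [load_config()].
#'
#' @return A named list of class `run_config`:
#' \describe{
#'   \item{analysis_fs_hz}{Analysis sampling rate after local-average
#'     downsampling (Hz, default 120).}
#'   \item{detrend_order}{Order of the least-squares polynomial fitted to the
#'     GCaMP channel for dF/F normalization (default 1).}
#'   \item{qc_z_threshold}{Robust z threshold on isosbestic first differences
#'     above which a sample is flagged as a sudden change (default 5).}
#'   \item{peak_discard_fraction}{Peaks whose height is below this fraction of
#'     the response window's min-to-max range are discarded from the AUC
#'     (default 0.10).}
#'   \item{windows}{Per-label event windows, seconds before/after onset:
#'     loom 2/2, cs 1.5/2, us 0.5/0.5.}
#'   \item{freezing_min_bout_s}{Minimum immobility duration to count as a
#'     freezing bout (s, default 1).}
#'   \item{motion_threshold}{Speed (cm/s) or motion-index value below which a
#'     frame counts as immobile (default 0.5 cm/s).}
#'   \item{escape_multiplier}{Escape = smoothed speed exceeding this multiple
#'     of the mean pre-stimulus speed (default 3).}
#'   \item{escape_smooth_s}{Moving-average width applied to speed before
#'     escape thresholding (s, default 0.25).}
#'   \item{scoring_window_s}{Behavioral scoring window after stimulus onset
#'     (s, default 30).}
#'   \item{precs_window_s}{Pre-CS freezing window before each CS onset
#'     (s, default 25).}
#'   \item{us_integrate_pre}{Whether the 0.5 s preceding the US is integrated
#'     into the US AUC together with the 0.5 s following it (default TRUE).}
#' }
#' @export
default_config <- function() {
  structure(list(
    analysis_fs_hz = 120,
    detrend_order = 1L,
    qc_z_threshold = 5,
    peak_discard_fraction = 0.10,
    windows = list(
      loom = list(baseline_s = 2,   response_s = 2),
      cs   = list(baseline_s = 1.5, response_s = 2),
      us   = list(baseline_s = 0.5, response_s = 0.5)
    ),
    freezing_min_bout_s = 1.0,
    motion_threshold = 0.5,
    escape_multiplier = 3,
    escape_smooth_s = 0.25,
    scoring_window_s = 30,
    precs_window_s = 25,
    us_integrate_pre = TRUE
  ), class = "run_config")
}

#' Build a run configuration with overrides
#'
#' @param ... Named overrides of fields in [default_config()]. Unknown names
#'   are an error.
#' @return A validated `run_config` list.
#' @examples
#' cfg <- run_config(analysis_fs_hz = 60)
#' cfg$detrend_order  # still the default
#' @export
run_config <- function(...) {
  merge_config(default_config(), list(...))
}

merge_config <- function(cfg, overrides) {
  if (length(overrides) == 0L) return(validate_config(cfg))
  nm <- names(overrides)
  if (is.null(nm) || any(nm == ""))
    stop_fmt("configuration overrides must be named")
  unknown <- setdiff(nm, names(cfg))
  if (length(unknown) > 0L)
    stop_fmt("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  for (k in nm) {
    if (k == "windows") {
      wo <- overrides[[k]]
      bad <- setdiff(names(wo), names(cfg$windows))
      if (length(bad) > 0L)
        stop_fmt("unknown window label(s) in config: %s", paste(bad, collapse = ", "))
      for (lab in names(wo)) {
        fld <- setdiff(names(wo[[lab]]), c("baseline_s", "response_s"))
        if (length(fld) > 0L)
          stop_fmt("unknown window field(s) for '%s': %s", lab, paste(fld, collapse = ", "))
        cfg$windows[[lab]][names(wo[[lab]])] <- wo[[lab]]
      }
    } else {
      cfg[[k]] <- overrides[[k]]
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  check_scalar_num(cfg$analysis_fs_hz, "analysis_fs_hz", positive = TRUE)
  if (cfg$detrend_order < 0 || cfg$detrend_order != round(cfg$detrend_order))
    stop_fmt("`detrend_order` must be a non-negative integer")
  check_scalar_num(cfg$qc_z_threshold, "qc_z_threshold", positive = TRUE)
  check_scalar_num(cfg$peak_discard_fraction, "peak_discard_fraction", nonneg = TRUE)
  if (cfg$peak_discard_fraction >= 1)
    stop_fmt("`peak_discard_fraction` must lie in [0, 1)")
  for (lab in names(cfg$windows)) {
    w <- cfg$windows[[lab]]
    check_scalar_num(w$baseline_s, paste0("windows$", lab, "$baseline_s"), positive = TRUE)
    check_scalar_num(w$response_s, paste0("windows$", lab, "$response_s"), positive = TRUE)
  }
  check_scalar_num(cfg$freezing_min_bout_s, "freezing_min_bout_s", positive = TRUE)
  check_scalar_num(cfg$motion_threshold, "motion_threshold", positive = TRUE)
  check_scalar_num(cfg$escape_multiplier, "escape_multiplier", positive = TRUE)
  check_scalar_num(cfg$escape_smooth_s, "escape_smooth_s", positive = TRUE)
  check_scalar_num(cfg$scoring_window_s, "scoring_window_s", positive = TRUE)
  check_scalar_num(cfg$precs_window_s, "precs_window_s", positive = TRUE)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Keys absent from the file keep their documented defaults; unknown keys are
#' rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop_fmt("unsupported config format '%s' (use yaml or json)", ext)
  )
  if (is.null(raw)) raw <- list()
  merge_config(default_config(), raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  flat <- x[setdiff(names(x), "windows")]
  for (k in names(flat)) cat(sprintf("  %-22s %s\n", k, format(flat[[k]])))
  for (lab in names(x$windows)) {
    w <- x$windows[[lab]]
    cat(sprintf("  window %-15s baseline %g s, response %g s\n",
                lab, w$baseline_s, w$response_s))
  }
  invisible(x)
}
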