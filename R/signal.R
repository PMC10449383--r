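# Raw recording -> quality-controlled dF/F at the analysis rate.
# Order of operations is fixed: local-average downsampling of both channels,
# least-squares polynomial fit to the downsampled GCaMP channel,
# dF/F = (signal - fit)/fit, then isosbestic jump QC.

#' Downsample by local averaging
#'
#' Output sample j is the mean of the input samples in bin j of width
#' `round(fs_in / fs_out)`; a trailing partial bin is dropped. Constant
#' signals are preserved exactly. Note 11 kHz -> 120 Hz is non-integer
#' (91.67): the bin width is rounded and the effective output rate
#' (`fs_in / width`) is returned as an attribute.
#'
#' @param x Numeric sample vector.
#' @param fs_in,fs_out Input and requested output rates, Hz
#'   (`fs_in >= fs_out`).
#' @return Binned means with attribute `fs_hz` (effective output rate).
#' @export
downsample_local_average <- function(x, fs_in, fs_out) {
  check_scalar_num(fs_in, "fs_in", positive = TRUE)
  check_scalar_num(fs_out, "fs_out", positive = TRUE)
  if (fs_out > fs_in)
    stop_fmt("fs_out (%g) must not exceed fs_in (%g)", fs_out, fs_in)
  w <- max(1L, as.integer(round(fs_in / fs_out)))
  nb <- length(x) %/% w
  if (nb == 0L) stop_fmt("signal shorter than one bin (%d samples)", w)
  y <- colMeans(matrix(x[seq_len(nb * w)], nrow = w))
  attr(y, "fs_hz") <- fs_in / w
  y
}

#' Least-squares polynomial baseline fit
#'
#' Fits a polynomial of the given order to `y` over `t` by ordinary least
#' squares and evaluates it at the sample times.
#'
#' @param t Sample times, seconds.
#' @param y Signal values.
#' @param order Polynomial order (default 1, a straight line).
#' @return List with `coeffs` (ascending powers, intercept first) and
#'   `fitted` (the evaluated polynomial).
#' @export
fit_baseline_polynomial <- function(t, y, order = 1L) {
  if (length(t) != length(y)) stop_fmt("t and y must have equal length")
  if (length(y) <= order + 1L)
    stop_fmt("need more than order + 1 = %d samples (got %d)", order + 1L, length(y))
  if (max(t) - min(t) <= 0) stop_fmt("degenerate time axis (all times equal)")
  X <- outer(t, 0:order, `^`)
  fit <- stats::lm.fit(X, y)
  coeffs <- unname(fit$coefficients)
  list(coeffs = coeffs, fitted = as.numeric(X %*% coeffs))
}

#' Fractional fluorescence change
#'
#' `dF/F = (signal - fitted) / fitted`, the ratio normalization that makes the
#' readout invariant to detector gain.
#'
#' @param gcamp Raw (downsampled) GCaMP samples.
#' @param fitted Fitted baseline at the same samples; must be strictly
#'   positive everywhere.
#' @return The dF/F vector.
#' @export
compute_dff <- function(gcamp, fitted) {
  if (length(gcamp) != length(fitted)) stop_fmt("signal/fit length mismatch")
  if (any(fitted <= 0))
    stop_fmt("fitted baseline non-positive at sample %d; trace unusable for ratio normalization",
             which(fitted <= 0)[1])
  (gcamp - fitted) / fitted
}

#' Isosbestic sudden-change quality control
#'
#' The calcium-independent isosbestic channel should vary only slowly; a
#' sudden jump indicates an optical artifact and disqualifies the affected
#' trace. First differences are z-scored against their own median and
#' MAD-derived scale (robust, so the artifact cannot mask itself) and samples
#' with `|z|` above the threshold are flagged.
#'
#' @param isosbestic Isosbestic samples at the analysis rate.
#' @param threshold_z Flagging threshold on the robust z (default 5).
#' @param time_s Optional sample times used to report flagged times; defaults
#'   to sample index based times at 1 Hz.
#' @return A list of class `qc_report`: `passed`, `max_isosbestic_jump_z`,
#'   `flagged_times_s`.
#' @export
qc_isosbestic <- function(isosbestic, threshold_z = 5, time_s = NULL) {
  n <- length(isosbestic)
  if (n < 3L) stop_fmt("isosbestic QC needs at least 3 samples")
  if (is.null(time_s)) time_s <- seq_len(n) - 1
  d <- diff(isosbestic)
  med <- stats::median(d)
  sc <- stats::mad(d)               # 1.4826 * median |d - med|
  if (sc == 0) sc <- stats::sd(d)   # heavy-tie fallback
  if (sc == 0 || !is.finite(sc)) {  # constant differences: nothing to flag
    rep_ <- list(passed = TRUE, max_isosbestic_jump_z = 0,
                 flagged_times_s = numeric())
    class(rep_) <- "qc_report"
    return(rep_)
  }
  z <- (d - med) / sc
  hit <- which(abs(z) > threshold_z)
  rep_ <- list(passed = length(hit) == 0L,
               max_isosbestic_jump_z = max(abs(z)),
               # a jump between samples i and i+1 is reported at sample i+1
               flagged_times_s = as.numeric(time_s[hit + 1L]))
  class(rep_) <- "qc_report"
  rep_
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s; max |jump z| = %.3g; %d flagged sample(s)\n",
              if (x$passed) "passed" else "FAILED",
              x$max_isosbestic_jump_z, length(x$flagged_times_s)))
  invisible(x)
}

#' Process a raw recording into a dF/F trace
#'
#' Downsamples both channels to the analysis rate by local averaging, fits a
#' polynomial baseline to the downsampled GCaMP channel, computes
#' dF/F = (signal - fit)/fit, and runs the isosbestic sudden-change QC.
#' The polynomial is fitted to the GCaMP channel itself over the whole
#' recording; the isosbestic channel is used only for QC.
#'
#' @param rec A [raw_recording()].
#' @param cfg A [run_config()] (defaults used when omitted).
#' @return An object of class `processed_trace`: `time_s`, `dff`, `fs_hz`
#'   (effective analysis rate), `fit_coeffs`, `isosbestic` (downsampled),
#'   `qc` ([qc_isosbestic()] report).
#' @export
process_recording <- function(rec, cfg = default_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  g <- downsample_local_average(rec$gcamp, rec$fs_hz, cfg$analysis_fs_hz)
  iso <- downsample_local_average(rec$isosbestic, rec$fs_hz, cfg$analysis_fs_hz)
  tt <- downsample_local_average(rec$time_s, rec$fs_hz, cfg$analysis_fs_hz)
  fs_eff <- attr(g, "fs_hz")
  fit <- fit_baseline_polynomial(as.numeric(tt), as.numeric(g),
                                 order = cfg$detrend_order)
  dff <- compute_dff(as.numeric(g), fit$fitted)
  qc <- qc_isosbestic(as.numeric(iso), threshold_z = cfg$qc_z_threshold,
                      time_s = as.numeric(tt))
  structure(list(time_s = as.numeric(tt), dff = dff, fs_hz = fs_eff,
                 fit_coeffs = fit$coeffs, isosbestic = as.numeric(iso),
                 qc = qc),
            class = "processed_trace")
}

#' @export
print.processed_trace <- function(x, ...) {
  cat(sprintf("<processed_trace> %d samples @ %.6g Hz; fit order %d; QC %s\n",
              length(x$dff), x$fs_hz, length(x$fit_coeffs) - 1L,
              if (x$qc$passed) "passed" else "FAILED"))
  invisible(x)
}
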