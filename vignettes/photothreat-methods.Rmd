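---
title: "Quantifying photometry signals and defensive behavior with photothreat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying photometry signals and defensive behavior with photothreat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photothreat)
```

## Overview

`photothreat` implements a complete analysis chain for fiber-photometry
recordings made during innate (looming-stimulus) and learned (tone/footshock
conditioning) threat paradigms, together with the behavioral scoring that
accompanies them. The chain is:

1. **Signal conditioning** — local-average downsampling of the raw dual-channel
   recording to an analysis rate of 120 Hz, a least-squares polynomial baseline
   fit to the GCaMP channel, and the ratio normalization
   $\Delta F/F = (F - \hat F)/\hat F$, where $\hat F$ is the fitted baseline.
2. **Quality control** — rejection of traces showing a sudden change in the
   calcium-independent isosbestic channel.
3. **Event alignment** — extraction of peri-event windows, per-trial z-scoring
   against the pre-event baseline, and per-trial metrics: a peak-filtered area
   under the curve (AUC) and the time to peak.
4. **Behavior scoring** — freezing percentage, pre-CS freezing, the
   differential rearing score, escape events, line crosses and center time.

Because raw animal recordings are not shipped with the package, every stage is
validated against a seedable synthetic-session generator whose ground truth is
known exactly. The generator is first-class, tested code, not a fixture.

## The signal model

The synthetic GCaMP channel is

$$F(t) = F_0\,\bigl(1 + A_b e^{-t/\tau_b}\bigr)\,\Bigl(1 + \sum_i a_i\,k(t - t_i)\Bigr) + \varepsilon(t),$$

with $F_0$ the baseline fluorescence, $A_b$ and $\tau_b$ the photobleaching
amplitude and time constant, $\varepsilon \sim \mathcal N(0, \sigma^2)$ white
noise, and $k$ a peak-normalized difference-of-exponentials transient kernel

$$k(t) = \frac{(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}}{k_{\max}}, \qquad t \ge 0 .$$

The kernel's argmax has the closed form $t^* = \tau_r \log\!\bigl(
(\tau_r + \tau_d)/\tau_r\bigr)$, which the tests use as an analytic oracle. The
isosbestic channel carries an independent bleaching trend, the same noise
level, and optional downward step artifacts that emulate sudden patch-cord or
LED changes.

Default kinetics are $\tau_r = 0.1$ s, $\tau_d = 1.0$ s (onset-to-peak
$\approx$ 240 ms), in the range typical of slow genetically encoded calcium
indicators; no published kinetics are reproduced, and both constants are
plain arguments of `transient_spec()`. The default artifact step is 5% of the
isosbestic baseline — large enough to be unambiguous, small enough not to
saturate the robust z statistic.

### Bleaching versus the linear detrend

The pipeline detrends with a *first-order* polynomial, while bleaching is
exponential. The generator's default $\tau_b$ (1200 s) is long relative to a
session, so the trend is locally near-linear and the mismatch bias on a 0.05
$\Delta F/F$ transient stays below 10%. Short $\tau_b$ values are deliberately
allowed as a stress-test knob: they quantify how the linear detrend degrades
when bleaching is fast, which is a property of the method, not a bug in the
generator.

## Numerical choices

* **Downsampling.** "Local averaging" is implemented as non-overlapping bin
  means with bin width `round(fs_in / fs_out)`; a trailing partial bin is
  dropped. 11 kHz to 120 Hz is a non-integer ratio (91.67), so the bin width
  is 92 and the *effective* analysis rate (11000/92 Hz) is recorded in the
  output rather than pretending to be exactly 120 Hz. At the desk-scale rates
  used in the tests (960 or 1000 Hz) the ratio is integral.
* **Baseline fit.** Ordinary least squares on the downsampled GCaMP channel
  over the whole recording. The fit is to the GCaMP channel itself — the
  isosbestic channel enters only the discard rule, never the normalization.
  Fitting per session (not per trial) keeps the normalization independent of
  the trial structure.
* **QC statistic.** "Sudden change" is operationalized as the robust z of the
  isosbestic first differences: $z_i = (d_i - \mathrm{med}(d))/\mathrm{MAD}(d)$,
  flagged when $|z| > 5$. The median/MAD scale prevents a large artifact from
  masking itself, which a mean/SD z would allow. A constant channel (zero
  scale) passes with $z_{\max} = 0$. QC is computed session-wide, and each
  aligned trial is re-checked: only trials whose window contains a flagged
  sample are excluded, so a single artifact does not discard a whole session.
  The unit of exclusion is the trial.
* **Z-scoring.** Each trial is standardized with the mean and *population* SD
  (divisor $n$) of its own pre-event baseline. The convention is fixed so
  hand-computed examples are exactly reproducible. A zero-SD baseline marks
  the trial invalid (`degenerate_baseline`); NaNs never propagate.
* **Peak-filtered AUC.** Within the response window, maximal runs of $z > 0$
  are response regions (0 is the implicit baseline of a standardized trace).
  A region is discarded when its peak height is *strictly below* 10% of the
  response window's min-to-max range — the filter used by common
  curve-analysis software; a height exactly at threshold is retained.
  Retained regions are integrated by the trapezoid rule including the
  half-sample ramps down to the neighbouring non-positive samples, which makes
  a grid-aligned triangular peak integrate to its exact area. Negative
  deflections never contribute. These three choices (positive-only regions,
  zero baseline, strict-< discard) are interpretations of a one-line
  description in the source methods; all are config-exposed.
* **Time to peak.** The relative time of the maximal z sample in the response
  window, ties to the earliest sample. Note this is a *per-sample argmax*:
  with realistic indicator kinetics the kernel is nearly flat around its peak
  (for the defaults it drops only $3.7\times10^{-4}$ of the amplitude over one
  120 Hz sample), so under measurement noise the single-trial argmax jitters
  over many samples even at high SNR. Time-to-peak is therefore a reliable
  *population* statistic (means across trials are stable) but not a
  sample-accurate single-trial estimator; the test suite asserts one-sample
  recovery only for noise-free sessions.
* **Event windows.** Loom: 2 s baseline, 2 s response, aligned to the *first*
  expansion of each 5-expansion trial. CS: 1.5 s baseline, 2 s response. US:
  0.5 s before and after onset; by default the preceding 0.5 s is integrated
  into the US AUC as well (config switch `us_integrate_pre`), and the z
  baseline for US windows is the window's own pre segment, since a CS-linked
  baseline is unavailable in loom-only sessions.

## Behavior scoring

Freezing is a maximal run of sub-threshold motion lasting at least 1 s;
shorter immobility does not count. With positions, motion is the per-frame
centroid speed (cm/s, assigned to the interval to the next frame); with a
motion index, the index itself. The immobility threshold (default 0.5 cm/s)
is config-exposed because the original detector's internal parameters are not
public. Freezing percentage is bout time clipped to the scoring window over
window length, times 100; pre-CS freezing averages the 25 s pre-onset windows
across CS trials.

Escapes are maximal runs, inside the 30 s post-onset window, where the speed —
smoothed with a 0.25 s centered moving average to suppress single-frame
tracking jitter — exceeds 3× the mean speed over the 30 s before onset. The
averaging span for the reference is a package choice (the source methods do
not state one); a zero reference (fully immobile baseline) makes escapes
not-evaluable rather than infinite. The rearing differential is the count in
the 30 s after onset minus the count in the 30 s before, with half-open
windows so an event exactly at onset is "post". Tail rattling is a manual
annotation passed through, never computed. Line crosses are sign changes of
the position against virtual grid lines; center time is the fraction of
frames inside a central rectangle.

## What the synthetic generator does and does not emulate

The generator reproduces the *structure* of the study conditions: the looming
protocol (5 expansions of 250 ms expand + 250 ms hold + 2 s pause, i.e.
consecutive onsets 2.5 s apart), the conditioning protocol (20 s CS
co-terminating with a 2 s US, inter-trial intervals uniform on 35–120 s), the
37 × 40 cm arena, exponential photobleaching, GCaMP-like transient kinetics,
Gaussian noise, isosbestic step artifacts, and locomotion with freezing
bouts, rearing annotations and escape sprints.

It does **not** emulate: biological trial-to-trial variability in transient
amplitude or kinetics, habituation dynamics across trials, correlated
(pink/motion) noise, hemodynamic contamination, video-level tracking noise,
or any neural model of learning. Freeze bouts are snapped to the camera frame
grid so the generated track realizes the requested bouts exactly — this makes
ground-truth freezing percentages exactly recoverable, a property of the
generator used to validate the detector, not a claim about real tracking
data. Consequently, green tests demonstrate that the *computations* are
correct and stable under the stated noise, not that the defaults are optimal
for any particular preparation.

## Problem sizes and determinism

The test suite and the acceptance script run desk-scale problems: sessions of
12–360 s at 960–1000 Hz (960 Hz gives an exactly integral 120 Hz analysis
grid), 50-trial parameter-recovery sweeps, 100-trial null controls, 20-session
QC batteries, and 100 randomized behavior tracks — sizes chosen so the whole
battery completes in well under a minute while leaving every statistical
check non-trivial. The hardware-faithful 11 kHz rate is supported and tested
for rate bookkeeping, but is unnecessary for verifying the math. All
randomness flows through explicit integer seeds; generator calls restore the
caller's RNG state, and two pipeline runs with the same seed are
byte-identical on disk.

## Known limitations

* The linear detrend is faithful to the implemented method but biased when
  bleaching is fast relative to the session; the generator exposes this
  regime rather than hiding it.
* Single-trial time-to-peak is noise-limited by design (argmax of samples);
  see above.
* Percentage-based freezing scores inherit the frame rate's quantization
  (one frame at 30 Hz is 0.11% of a 30 s window).
* The escape rule compares against the *mean* pre-stimulus speed; a baseline
  containing long immobility lowers the reference and makes the rule more
  sensitive, which mirrors how the definition is stated.
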