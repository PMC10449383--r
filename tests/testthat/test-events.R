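# Event alignment, baseline z-scoring, peak-filtered AUC and time-to-peak.

make_trace_120 <- function(dff, qc_flags = numeric()) {
  n <- length(dff)
  structure(list(time_s = (0:(n - 1)) / 120, dff = dff, fs_hz = 120,
                 fit_coeffs = c(0, 0), isosbestic = NULL,
                 qc = structure(list(passed = length(qc_flags) == 0L,
                                     max_isosbestic_jump_z = 0,
                                     flagged_times_s = qc_flags),
                                class = "qc_report")),
            class = "processed_trace")
}

test_that("alignment yields a trial x time matrix spanning [-baseline, response)", {
  set.seed(1)
  tr <- make_trace_120(rnorm(120 * 60))
  ev <- event_log(rep("loom", 3), c(10, 25, 40), NA_real_, 1:3)
  at <- align_trials(tr, ev, window_spec("loom"))  # (2, 2) s at 120 Hz
  expect_equal(dim(at$mat), c(3L, 480L))
  expect_equal(range(at$rel_time_s), c(-2, 2 - 1 / 120))
  expect_true(all(at$trial_qc))
  # early event: window underflow marks the trial invalid with a reason
  ev2 <- event_log(rep("loom", 2), c(1, 30), NA_real_, 1:2)
  at2 <- align_trials(tr, ev2, window_spec("loom"))
  expect_false(at2$trial_qc[1])
  expect_equal(at2$trial_status[1], "window_out_of_range")
  expect_true(at2$trial_qc[2])
})

test_that("loom trials with five expansions align to the first expansion, one row per trial", {
  set.seed(2)
  tr <- make_trace_120(rnorm(120 * 120))
  sched <- generate_event_schedule(protocol_spec("loom", n_trials = 4L), seed = 5)
  at <- align_trials(tr, sched, window_spec("loom"))
  expect_equal(at$n_trials, 4L)
  first_onsets <- vapply(split(sched$onset_s, sched$trial_index), min, numeric(1))
  expect_equal(at$onsets_s, unname(first_onsets))
})

test_that("per-trial isosbestic QC excludes only trials whose window holds a flag", {
  set.seed(3)
  tr <- make_trace_120(rnorm(120 * 60), qc_flags = 25.5)
  ev <- event_log(rep("loom", 3), c(10, 25, 40), NA_real_, 1:3)
  at <- align_trials(tr, ev, window_spec("loom"))
  expect_equal(at$trial_qc, c(TRUE, FALSE, TRUE))
  expect_equal(at$trial_status[2], "isosbestic_artifact")
})

test_that("baseline z-scoring leaves every retained baseline at mean 0, SD 1", {
  set.seed(4)
  tr <- make_trace_120(rnorm(120 * 60, 0.02, 0.01))
  ev <- event_log(rep("loom", 5), c(10, 20, 30, 40, 50), NA_real_, 1:5)
  at <- zscore_baseline(align_trials(tr, ev, window_spec("loom")))
  bl <- at$rel_time_s < 0
  for (i in 1:5) {
    x <- at$mat[i, bl]
    expect_lt(abs(mean(x)), 1e-6)
    expect_lt(abs(sqrt(mean((x - mean(x))^2)) - 1), 1e-6)
  }
})

test_that("hand-computed z-scores use the population SD convention", {
  # baseline {1, 3}: mean 2, population SD 1; response {4} -> z = 2
  at <- make_aligned(matrix(c(1, 3, 4), 1, 3), fs_hz = 1,
                     baseline_s = 2, response_s = 1)
  z <- zscore_baseline(at)
  expect_equal(z$mat[1, ], c(-1, 1, 2))
})

test_that("a constant trial is marked invalid, never NaN", {
  at <- make_aligned(rbind(rep(1, 10), c(rnorm(5), rnorm(5) + 1)), fs_hz = 2.5,
                     baseline_s = 2, response_s = 2)
  z <- zscore_baseline(at)
  expect_false(z$trial_qc[1])
  expect_equal(z$trial_status[1], "degenerate_baseline")
  expect_true(z$trial_qc[2])
  expect_false(anyNA(z$mat[2, ]))
  m <- trial_metrics(z)
  expect_true(is.na(m$auc[1]))
  expect_false(anyNA(m$auc[2]))
})

test_that("AUC integrates a grid-aligned triangle exactly and zero traces to zero", {
  fs <- 120
  k <- (-240):239
  rel <- k / fs
  z <- numeric(length(rel))
  expect_equal(compute_auc(z, rel)$auc, 0)
  # triangle: feet at 0.5 and 1.5 s, apex 4 at 1.0 s -> area 2.0
  up <- k >= 60 & k <= 120
  dn <- k > 120 & k <= 180
  z[up] <- (k[up] - 60) * 4 / 60
  z[dn] <- (180 - k[dn]) * 4 / 60
  out <- compute_auc(z, rel, 0.10)
  expect_equal(out$auc, 2.0, tolerance = 1e-9)
  expect_equal(out$retained_peak_count, 1L)
})

test_that("the 10% filter discards only peaks strictly below threshold", {
  fs <- 100
  k <- (-100):199
  rel <- k / fs
  z <- numeric(length(rel))
  # peak A: height 4 at 0.5 s; peak B: height 0.2 at 1.5 s; dip to -0.5
  ia <- k >= 40 & k <= 60
  ib <- k >= 140 & k <= 160
  z[ia] <- 4 * (1 - abs(k[ia] - 50) / 10)
  z[ib] <- 0.2 * (1 - abs(k[ib] - 150) / 10)
  z[k >= 90 & k <= 100] <- -0.5
  out <- compute_auc(z, rel, 0.10)
  # range = 4 - (-0.5) = 4.5; threshold 0.45; only the height-4 peak survives
  expect_equal(out$retained_peak_count, 1L)
  expect_equal(out$auc, oracle_auc(z, rel, 0.10)$auc)
  # a peak exactly at threshold is retained (strict-< discard)
  z2 <- numeric(length(rel))
  z2[k %in% c(10, 11, 12)] <- c(0.5, 1, 0.5)    # range max = 1, min = 0
  z2[k %in% c(110, 111, 112)] <- c(0.05, 0.1, 0.05)
  out2 <- compute_auc(z2, rel, 0.10)  # threshold 0.1 * 1 equals the small height
  expect_equal(out2$retained_peak_count, 2L)
})

test_that("region AUC equals the exhaustive per-sample reference on random traces", {
  set.seed(77)
  for (rep_i in 1:60) {
    n <- sample(20:500, 1)
    fs <- sample(c(20, 50, 120), 1)
    rel <- (seq_len(n) - sample(1:(n - 5), 1) - 1) / fs
    if (!any(rel >= 0)) rel <- rel - min(rel)
    z <- rnorm(n, 0, 1) + sample(c(-0.5, 0, 0.5), 1)
    frac <- sample(c(0, 0.1, 0.3), 1)
    got <- compute_auc(z, rel, frac)
    want <- oracle_auc(z, rel, frac)
    expect_identical(got$auc, want$auc)
    expect_identical(got$retained_peak_count, want$count)
  }
})

test_that("time to peak takes the earliest maximal sample in the response window", {
  k <- (-100):199
  rel <- k / 100
  z <- numeric(length(rel))
  z[k == 80] <- 3
  expect_equal(time_to_peak(z, rel), 0.8)
  # monotone decreasing response -> first sample
  z2 <- -seq_along(rel) / 100
  expect_equal(time_to_peak(z2, rel), 0)
  # ties break earliest
  z3 <- numeric(length(rel)); z3[k %in% c(50, 150)] <- 2
  expect_equal(time_to_peak(z3, rel), 0.5)
  # synthetic kernel argmax within one analysis sample
  at <- sim_single_trial(0.06, seed = 12, noise_sd = 0)
  expect_lte(abs(time_to_peak(at$mat[1, ], at$rel_time_s) -
                   transient_peak_time(0.1, 1.0)), 1 / 120 + 1e-9)
})

test_that("z, AUC and time-to-peak are invariant to affine raw-signal maps", {
  set.seed(9)
  base <- matrix(rnorm(3 * 40), 3, 40)
  at1 <- zscore_baseline(make_aligned(base, 10, 2, 2))
  at2 <- zscore_baseline(make_aligned(2.7 * base + 5, 10, 2, 2))
  expect_equal(at1$mat, at2$mat, tolerance = 1e-12)
  m1 <- trial_metrics(at1); m2 <- trial_metrics(at2)
  expect_equal(m1$auc, m2$auc, tolerance = 1e-12)
  expect_equal(m1$time_to_peak_s, m2$time_to_peak_s)
})

test_that("AUC increases with injected amplitude (rank correlation > 0.9)", {
  set.seed(31)
  amps <- runif(50, 0.01, 0.1)
  aucs <- vapply(seq_along(amps), function(i) {
    at <- sim_single_trial(amps[i], seed = 400 + i, noise_sd = 0.01)
    trial_metrics(at)$auc[1]
  }, numeric(1))
  expect_gt(cor(amps, aucs, method = "spearman"), 0.9)
})

test_that("summaries report mean, SEM and heatmap over retained trials", {
  set.seed(13)
  one <- make_aligned(matrix(rnorm(40), 1, 40), 10, 2, 2)
  s1 <- summarize_trials(zscore_baseline(one))
  expect_equal(s1$mean, zscore_baseline(one)$mat[1, ])
  expect_equal(s1$sem, rep(0, 40))
  # identical trials -> SEM 0
  row <- rnorm(40)
  same <- zscore_baseline(make_aligned(rbind(row, row, row), 10, 2, 2))
  expect_equal(summarize_trials(same)$sem, rep(0, 40), tolerance = 1e-12)
  expect_equal(dim(summarize_trials(same)$heatmap), c(3L, 40L))
  # zero retained trials -> explicit empty status
  flat <- make_aligned(matrix(1, 2, 40), 10, 2, 2)
  expect_equal(summarize_trials(zscore_baseline(flat))$status, "empty")
})

test_that("null trials average to zero response within the CLT bound", {
  set.seed(55)
  nz <- 100
  mz <- vapply(seq_len(nz), function(i) {
    at <- sim_single_trial(0, seed = 8000 + i, noise_sd = 0.01)
    mean(at$mat[1, at$rel_time_s >= 0])
  }, numeric(1))
  expect_lt(abs(mean(mz)), 3 * sd(mz) / sqrt(nz))
})
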