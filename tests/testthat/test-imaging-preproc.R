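make_raw <- function(samples, fs = 10, sweep_start = 0, stim_onset = 3,
                     stim_offset = 6) {
  raw_trace(samples, fs = fs, sweep_start = sweep_start,
            stim_onset = stim_onset, stim_offset = stim_offset)
}

test_that("dF/F0 uses the documented baseline window", {
  fs <- 10
  n <- 80
  f <- rep(100, n)
  f[31:60] <- 150 # stimulus epoch
  raw <- make_raw(f, fs = fs)
  # baseline = samples with 1 <= t < 3, i.e. indices 11..30 (value 100)
  d <- compute_dff(raw)
  expect_equal(d$f0, 100)
  expect_equal(d$samples[1:30], rep(0, 30))
  expect_equal(d$samples[31], 0.5)
  # constant trace gives all-zero dF/F
  expect_equal(compute_dff(make_raw(rep(7, n)))$samples, rep(0, n))
})

test_that("dF/F0 errors on invalid baselines", {
  expect_error(compute_dff(make_raw(rep(100, 80), stim_onset = 0.5)),
               "baseline")
  expect_error(compute_dff(make_raw(rep(-5, 80))), "F0")
  # trace too short for the stimulus epoch
  expect_error(raw_trace(rep(1, 10), fs = 10, stim_onset = 3,
                         stim_offset = 6), "beyond")
})

test_that("low-pass smoothing preserves DC and removes fast noise", {
  set.seed(1)
  fs <- 7.2
  t <- seq(0, 20, by = 1 / fs)
  slow <- sin(2 * pi * 0.1 * t)
  noisy <- slow + rnorm(length(t), sd = 0.3)
  tr <- dff_trace(noisy, fs = fs)
  sm <- lowpass_smooth(tr, cutoff = 1)
  expect_lt(mean((sm$samples - slow)^2), mean((noisy - slow)^2) / 4)
  # constant input is unchanged
  const <- lowpass_smooth(dff_trace(rep(2.5, 100), fs = fs), cutoff = 1)
  expect_equal(const$samples, rep(2.5, 100), tolerance = 1e-6)
  expect_error(lowpass_smooth(tr, cutoff = 10), "cutoff")
})

test_that("per-ROI normalization is idempotent and scales the max to 1", {
  df <- data.frame(roi = rep(c("a", "b"), each = 4),
                   dff = c(1, 2, 4, 3, 5, 10, 2, 1))
  n1 <- normalize_by_roi_max(df)
  expect_equal(max(n1$dff[n1$roi == "a"]), 1)
  expect_equal(max(n1$dff[n1$roi == "b"]), 1)
  expect_equal(n1$dff[1:4], c(1, 2, 4, 3) / 4)
  expect_equal(normalize_by_roi_max(n1), n1)
  expect_error(normalize_by_roi_max(data.frame(roi = "a", dff = -1)))
})

test_that("peak and mean responses respect the window", {
  tr <- dff_trace(c(0, 0, 1, 3, 2, 0), fs = 1, stim_onset = 2,
                  stim_offset = 4)
  expect_equal(peak_response(tr), 3)
  expect_equal(mean_response(tr), 2)
  expect_equal(peak_response(tr, c(0, 1)), 0)
  expect_error(peak_response(tr, c(10, 11)), "window")
})

test_that("half-rise time interpolates between samples", {
  fs <- 10
  # ramp from 0 to 1 over 1 s starting at onset (t = 1)
  t <- seq(0, 3, by = 1 / fs)
  y <- pmin(pmax(t - 1, 0), 1)
  tr <- dff_trace(y, fs = fs, stim_onset = 1, stim_offset = 3)
  expect_equal(half_rise_time(tr), 0.5, tolerance = 1e-9)
  # already above half at onset
  tr2 <- dff_trace(c(0.9, 1, 1, 1), fs = 1, stim_onset = 1, stim_offset = 3)
  expect_equal(half_rise_time(tr2), 0)
  # a trace already at its peak at onset has zero rise time
  expect_equal(half_rise_time(dff_trace(c(1, 0.5, 0.2, 0.1), fs = 1,
                                        stim_onset = 0, stim_offset = 3)),
               0)
  # a trace with no positive excursion cannot have a half-rise time
  expect_error(half_rise_time(dff_trace(c(-1, -0.4, -0.2, -0.3), fs = 1,
                                        stim_onset = 0, stim_offset = 3)),
               "rise")
})

test_that("adaptation index compares offset response to the peak", {
  tr <- dff_trace(c(0, 1, 0.8, 0.5), fs = 1, stim_onset = 1, stim_offset = 3)
  expect_equal(adaptation_index(tr), 0.5)
  plateau <- dff_trace(c(0, 1, 1, 1), fs = 1, stim_onset = 1,
                       stim_offset = 3)
  expect_equal(adaptation_index(plateau), 1)
})

test_that("pose cleaning interpolates low-confidence frames", {
  fs <- 30
  n <- 90
  pose <- data.frame(x = seq(0, 89), y = rep(2, n),
                     confidence = rep(1, n))
  pose$x[40] <- 1e4 # glitch frame
  pose$confidence[40] <- 0.1
  out <- clean_pose_trace(pose, fs = fs, target_fs = 7.2, cutoff = NULL)
  # the glitch is replaced by its linear neighbourhood, so x stays linear
  expect_lt(max(abs(out$x - out$time * fs)), 1e-6)
  expect_equal(out$time[2] - out$time[1], 1 / 7.2)
  expect_error(clean_pose_trace(data.frame(x = 1, y = 1, confidence = 0.1),
                                fs = 30), "confidence")
})
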