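# Calcium trace containers and preprocessing.

#' Raw fluorescence trace
#'
#' @param samples fluorescence values (a.u.).
#' @param fs sampling rate, Hz.
#' @param sweep_start start time of the imaging sweep, seconds.
#' @param stim_onset,stim_offset stimulus epoch, seconds.
#' @param roi ROI identifier.
#' @param side `"left"`, `"right"` or `"none"`.
#' @return an object of class `raw_trace`.
#' @export
raw_trace <- function(samples, fs, sweep_start = 0, stim_onset, stim_offset,
                      roi = "roi1", side = "none") {
  stopifnot(fs > 0, sweep_start < stim_onset, stim_onset < stim_offset)
  n <- length(samples)
  if (stim_offset > sweep_start + n / fs + 1e-9) {
    stop("stim_offset beyond trace end")
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 sweep_start = sweep_start, stim_onset = stim_onset,
                 stim_offset = stim_offset, roi = roi, side = side),
            class = "raw_trace")
}

#' dF/F0 trace
#'
#' @param samples dF/F0 values.
#' @param fs sampling rate, Hz.
#' @param stim_onset,stim_offset stimulus epoch, seconds.
#' @param f0 baseline fluorescence used for normalization (a.u.), if known.
#' @param sweep_start trace start time, seconds.
#' @param roi ROI identifier.
#' @param side antenna/hemisphere label.
#' @return an object of class `dff_trace`.
#' @export
dff_trace <- function(samples, fs, stim_onset = NA_real_,
                      stim_offset = NA_real_, f0 = NA_real_,
                      sweep_start = 0, roi = "roi1", side = "none") {
  stopifnot(fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs,
                 sweep_start = sweep_start, stim_onset = stim_onset,
                 stim_offset = stim_offset, f0 = f0, roi = roi, side = side),
            class = "dff_trace")
}

#' Sample times of a trace
#' @param trace a `dff_trace` or `raw_trace`.
#' @return numeric vector of times in seconds.
#' @export
trace_times <- function(trace) {
  trace$sweep_start + (seq_along(trace$samples) - 1) / trace$fs
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("dF/F0 trace: %d samples at %.3g Hz (%.2f s), roi %s, side %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$roi,
              x$side))
  if (is.finite(x$stim_onset)) {
    cat(sprintf("  stimulus %.2f-%.2f s, range [%.3g, %.3g]\n",
                x$stim_onset, x$stim_offset, min(x$samples), max(x$samples)))
  }
  invisible(x)
}

#' Compute dF/F0 from a raw trace
#'
#' The baseline F0 is the mean fluorescence over the half-open window from
#' 1 s after sweep start up to (excluding) stimulus onset.
#'
#' @param raw a [raw_trace()].
#' @return a [dff_trace()].
#' @export
compute_dff <- function(raw) {
  stopifnot(inherits(raw, "raw_trace"))
  t <- raw$sweep_start + (seq_along(raw$samples) - 1) / raw$fs
  base_idx <- which(t >= raw$sweep_start + 1 & t < raw$stim_onset)
  if (length(base_idx) == 0) stop("empty baseline window")
  f0 <- mean(raw$samples[base_idx])
  if (f0 <= 0) stop("non-positive baseline F0")
  dff_trace((raw$samples - f0) / f0, fs = raw$fs,
            stim_onset = raw$stim_onset, stim_offset = raw$stim_offset,
            f0 = f0, sweep_start = raw$sweep_start, roi = raw$roi,
            side = raw$side)
}

#' Zero-phase Butterworth low-pass smoothing
#'
#' Forward-backward filtering (no phase lag), preserving the DC level.
#'
#' @param trace a [dff_trace()].
#' @param cutoff cutoff frequency, Hz; must be below Nyquist.
#' @param order filter order (default 2).
#' @return the smoothed trace.
#' @export
lowpass_smooth <- function(trace, cutoff = 1, order = 2) {
  stopifnot(inherits(trace, "dff_trace"))
  if (cutoff <= 0 || cutoff >= trace$fs / 2) {
    stop("cutoff must lie in (0, fs/2)")
  }
  bf <- signal::butter(order, cutoff / (trace$fs / 2), type = "low")
  out <- trace
  # filter around the mean: filtfilt assumes zero initial conditions, so
  # removing the DC level first avoids large edge transients
  m <- mean(trace$samples)
  out$samples <- m + as.numeric(signal::filtfilt(bf, trace$samples - m))
  out
}

window_index <- function(trace, window) {
  t <- trace_times(trace)
  idx <- which(t >= window[1] & t <= window[2] + 1e-9)
  if (length(idx) == 0) stop("empty response window")
  idx
}

#' Peak response in a window
#' @param trace a [dff_trace()].
#' @param window `c(start, end)` in seconds; defaults to the stimulus epoch.
#' @return maximum sample value in the window.
#' @export
peak_response <- function(trace, window = c(trace$stim_onset,
                                            trace$stim_offset)) {
  max(trace$samples[window_index(trace, window)])
}

#' Mean response in a window
#' @inheritParams peak_response
#' @return mean sample value in the window.
#' @export
mean_response <- function(trace, window = c(trace$stim_onset,
                                            trace$stim_offset)) {
  mean(trace$samples[window_index(trace, window)])
}

#' Half-rise time of a response
#'
#' First time after stimulus onset at which the trace crosses 50% of its
#' post-onset peak, minus the onset time; linearly interpolated between
#' samples.
#'
#' @param trace a [dff_trace()] with stimulus annotations.
#' @return half-rise time in seconds.
#' @export
half_rise_time <- function(trace) {
  t <- trace_times(trace)
  idx <- which(t >= trace$stim_onset)
  if (length(idx) < 2) stop("too few samples after stimulus onset")
  y <- trace$samples[idx]
  tt <- t[idx]
  peak <- max(y)
  if (peak <= 0) stop("no rise above zero after onset")
  half <- peak / 2
  if (y[1] >= half) return(0)
  cross <- which(y >= half)[1]
  if (is.na(cross)) stop("trace never crosses half peak")
  # linear interpolation between samples cross-1 and cross
  t0 <- tt[cross - 1]; t1 <- tt[cross]
  y0 <- y[cross - 1]; y1 <- y[cross]
  t_half <- t0 + (half - y0) / (y1 - y0) * (t1 - t0)
  t_half - trace$stim_onset
}

#' Adaptation index of a sustained response
#'
#' Ratio of the response at stimulus offset to the peak response during the
#' stimulus; lower values indicate stronger adaptation, a non-adapting
#' plateau gives 1.
#'
#' @param trace a [dff_trace()] with stimulus annotations.
#' @return the index, in (-Inf, 1].
#' @export
adaptation_index <- function(trace) {
  idx <- window_index(trace, c(trace$stim_onset, trace$stim_offset))
  y <- trace$samples[idx]
  peak <- max(y)
  if (peak <= 0) stop("non-positive peak")
  y[length(y)] / peak
}

#' Normalize values by the per-ROI maximum
#'
#' Each ROI's values are divided by the largest value of that ROI over the
#' whole experiment, so the per-ROI maximum becomes 1. Idempotent.
#'
#' @param data data.frame of per-sample or per-trial values.
#' @param value column name holding the values.
#' @param roi column name identifying the ROI.
#' @return the data.frame with the value column rescaled.
#' @export
normalize_by_roi_max <- function(data, value = "dff", roi = "roi") {
  stopifnot(is.data.frame(data), value %in% names(data), roi %in% names(data))
  mx <- tapply(data[[value]], data[[roi]], max)
  if (any(mx <= 0)) stop("ROI with no positive value")
  data[[value]] <- data[[value]] / as.numeric(mx[as.character(data[[roi]])])
  data
}

#' Clean and resample a pose trace
#'
#' Replaces low-confidence keypoint positions by linear interpolation of
#' their neighbours, resamples to a target rate, and applies the same
#' zero-phase low-pass filter used for calcium traces.
#'
#' @param pose data.frame with columns `x`, `y`, `confidence` (frames at
#'   rate `fs`).
#' @param fs input frame rate, Hz.
#' @param min_conf confidence threshold below which positions are replaced
#'   (default 0.7).
#' @param target_fs output sampling rate, Hz (default 7.2).
#' @param cutoff low-pass cutoff in Hz; `NULL` skips smoothing.
#' @return data.frame with columns `time`, `x`, `y` at `target_fs`.
#' @export
clean_pose_trace <- function(pose, fs, min_conf = 0.7, target_fs = 7.2,
                             cutoff = 1) {
  stopifnot(all(c("x", "y", "confidence") %in% names(pose)), fs > 0,
            target_fs > 0)
  ok <- pose$confidence >= min_conf
  if (sum(ok) < 2) stop("fewer than two frames above the confidence threshold")
  n <- nrow(pose)
  t_in <- (seq_len(n) - 1) / fs
  interp1 <- function(v) approx(t_in[ok], v[ok], xout = t_in, rule = 2)$y
  x <- ifelse(ok, pose$x, interp1(pose$x))
  y <- ifelse(ok, pose$y, interp1(pose$y))
  t_out <- seq(0, t_in[n], by = 1 / target_fs)
  xo <- approx(t_in, x, xout = t_out, rule = 2)$y
  yo <- approx(t_in, y, xout = t_out, rule = 2)$y
  if (!is.null(cutoff) && length(t_out) > 12 && cutoff < target_fs / 2) {
    xo <- lowpass_smooth(dff_trace(xo, fs = target_fs), cutoff)$samples
    yo <- lowpass_smooth(dff_trace(yo, fs = target_fs), cutoff)$samples
  }
  data.frame(time = t_out, x = xo, y = yo)
}
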