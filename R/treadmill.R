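# Spherical-treadmill trials: classification, lateral displacement,
# permutation test.

#' Spherical-treadmill trial
#'
#' @param forward,lateral forward and lateral velocities, mm/s (lateral
#'   positive to the fly's left).
#' @param rotational rotational velocity, degrees/s (positive
#'   counter-clockwise).
#' @param fs frame rate, Hz (default 50).
#' @param stim_side stimulus presentation side, `"left"` or `"right"`.
#' @param stim_window `c(start, end)` of the stimulus, seconds.
#' @param ball_radius treadmill ball radius, mm (default 4.5), used to
#'   convert rotation to a linear speed.
#' @return object of class `treadmill_trial`.
#' @export
treadmill_trial <- function(forward, lateral, rotational, fs = 50,
                            stim_side = c("left", "right"),
                            stim_window, ball_radius = 4.5) {
  stim_side <- match.arg(stim_side)
  n <- length(forward)
  stopifnot(length(lateral) == n, length(rotational) == n, fs > 0,
            length(stim_window) == 2, stim_window[1] < stim_window[2])
  if (stim_window[2] > n / fs + 1e-9) stop("trial does not cover the stimulus window")
  structure(list(forward = forward, lateral = lateral,
                 rotational = rotational, fs = fs, stim_side = stim_side,
                 stim_window = stim_window, ball_radius = ball_radius),
            class = "treadmill_trial")
}

rot_mm <- function(trial) deg2rad(trial$rotational) * trial$ball_radius

trial_speed <- function(trial) {
  sqrt(trial$forward^2 + trial$lateral^2 + rot_mm(trial)^2)
}

#' Classify a treadmill trial
#'
#' A trial is `no_movement` when the 95th percentile of the fly's speed on
#' all three axes stays below `still_thresh` throughout the trial;
#' `constant_movement` when its speed never drops below `rest_thresh` in a
#' window before or during the stimulus; otherwise `valid`. Rotational
#' speed is converted to mm/s via the ball radius.
#'
#' @param trial a [treadmill_trial()].
#' @param still_thresh mm/s (default 0.75).
#' @param rest_thresh mm/s (default 0.25).
#' @param pre_window seconds before stimulus onset included in the
#'   constant-movement check (default 2).
#' @return `"no_movement"`, `"constant_movement"` or `"valid"`.
#' @export
classify_treadmill_trial <- function(trial, still_thresh = 0.75,
                                     rest_thresh = 0.25, pre_window = 2) {
  stopifnot(inherits(trial, "treadmill_trial"))
  axes <- list(abs(trial$forward), abs(trial$lateral), abs(rot_mm(trial)))
  if (all(vapply(axes, function(a) quantile(a, 0.95) < still_thresh, TRUE))) {
    return("no_movement")
  }
  t <- (seq_along(trial$forward) - 1) / trial$fs
  win <- t >= trial$stim_window[1] - pre_window & t <= trial$stim_window[2]
  if (!any(win)) stop("missing peristimulus window")
  if (min(trial_speed(trial)[win]) >= rest_thresh) {
    return("constant_movement")
  }
  "valid"
}

#' Signed lateral displacement after movement onset
#'
#' Dead-reckons the fly's path in the world frame from the three velocity
#' axes and integrates displacement over the first second after movement
#' onset; the result is signed positive toward the stimulus side. Movement
#' onset is the first frame in the peristimulus window whose 3-axis speed
#' exceeds `rest_thresh` after a quiescent frame.
#'
#' @param trial a valid [treadmill_trial()].
#' @param duration integration time after onset, s (default 1).
#' @param rest_thresh movement-onset threshold, mm/s (default 0.25).
#' @param pre_window seconds before stimulus onset searched for onset.
#' @param signed return displacement signed toward the stimulus side
#'   (default TRUE); otherwise world-frame leftward displacement.
#' @return displacement in mm.
#' @export
lateral_displacement <- function(trial, duration = 1, rest_thresh = 0.25,
                                 pre_window = 2, signed = TRUE) {
  stopifnot(inherits(trial, "treadmill_trial"))
  fs <- trial$fs
  n <- length(trial$forward)
  t <- (seq_len(n) - 1) / fs
  speed <- trial_speed(trial)
  win <- which(t >= trial$stim_window[1] - pre_window &
                 t <= trial$stim_window[2])
  quiescent <- speed < rest_thresh
  onset <- NA_integer_
  for (i in win) {
    if (i > 1 && quiescent[i - 1] && !quiescent[i]) {
      onset <- i
      break
    }
  }
  if (is.na(onset)) stop("no movement onset found")
  idx <- onset:min(n, onset + round(duration * fs) - 1)
  # heading accumulated from rotation; initial heading along +x
  h <- deg2rad(cumsum(c(0, trial$rotational[idx[-length(idx)]])) / fs)
  vx <- trial$forward[idx] * cos(h) - trial$lateral[idx] * sin(h)
  vy <- trial$forward[idx] * sin(h) + trial$lateral[idx] * cos(h)
  y_disp <- sum(vy) / fs # world leftward displacement
  if (!signed) return(y_disp)
  if (trial$stim_side == "left") y_disp else -y_disp
}

#' Permutation test for side-dependent lateral displacement
#'
#' Two-sided permutation test of the difference in mean lateral
#' displacement between left- and right-presentation trials. All label
#' assignments are enumerated exactly when feasible; otherwise a Monte
#' Carlo sample of permutations is used.
#'
#' @param left_trials,right_trials numeric vectors of lateral displacements
#'   (world-frame sign convention shared across trials).
#' @param n_perm number of Monte Carlo permutations (default 10000).
#' @param seed integer seed for the Monte Carlo draw.
#' @param method `"auto"` (exact when the number of distinct assignments is
#'   at most `n_perm`), `"exact"` or `"montecarlo"`.
#' @return list of class `stat_report`: observed difference, p-value,
#'   method and permutation count.
#' @export
displacement_permutation_test <- function(left_trials, right_trials,
                                          n_perm = 10000, seed = NULL,
                                          method = c("auto", "exact",
                                                     "montecarlo")) {
  method <- match.arg(method)
  stopifnot(length(left_trials) >= 3, length(right_trials) >= 3)
  x <- c(left_trials, right_trials)
  n1 <- length(left_trials)
  n <- length(x)
  obs <- mean(left_trials) - mean(right_trials)
  n_comb <- choose(n, n1)
  if (method == "auto") {
    method <- if (n_comb <= n_perm) "exact" else "montecarlo"
  }
  if (method == "exact") {
    idx <- combn(n, n1)
    stats_all <- apply(idx, 2, function(i) mean(x[i]) - mean(x[-i]))
    p <- mean(abs(stats_all) >= abs(obs) - 1e-12)
    n_used <- ncol(idx)
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats_all <- replicate(n_perm, {
      i <- sample.int(n, n1)
      mean(x[i]) - mean(x[-i])
    })
    p <- (1 + sum(abs(stats_all) >= abs(obs) - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(test = "permutation test (difference in means)",
                 statistic = obs, p_value = p, method = method,
                 n_perm = n_used, design = "permutation"),
            class = "stat_report")
}
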