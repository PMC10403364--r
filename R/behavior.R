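# Arena behavior: tracked pairs, opposite-sex preference, turn detection,
# relative orientation.

#' Tracked receiver-stimulus pair
#'
#' Synchronized trajectories of a freely moving receiver fly and a stimulus
#' fly in world coordinates (mm; orientations in degrees counter-clockwise
#' from +x).
#'
#' @param frames data.frame with columns `frame`, `rx`, `ry`, `rori`,
#'   `sx`, `sy`, `sori`.
#' @param fs frame rate, Hz.
#' @param arena_center length-2 arena center (mm).
#' @param arena_radius arena radius (mm).
#' @return object of class `tracked_pair`.
#' @export
tracked_pair <- function(frames, fs, arena_center = c(0, 0),
                         arena_radius = 8) {
  need <- c("frame", "rx", "ry", "rori", "sx", "sy", "sori")
  stopifnot(all(need %in% names(frames)), fs > 0, arena_radius > 0)
  if (is.null(frames$valid)) frames$valid <- TRUE
  structure(list(frames = frames, fs = fs, arena_center = arena_center,
                 arena_radius = arena_radius),
            class = "tracked_pair")
}

#' @export
print.tracked_pair <- function(x, ...) {
  cat(sprintf(
    "tracked pair: %d frames at %g Hz (%.1f s), arena radius %g mm\n",
    nrow(x$frames), x$fs, nrow(x$frames) / x$fs, x$arena_radius))
  invisible(x)
}

# unwrap an orientation sequence in degrees
unwrap_deg <- function(theta) rad2deg(unwrap_rad(deg2rad(theta)))

unwrap_rad <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(theta[1], d))
}

#' Remove tracking artifacts from a pair of trajectories
#'
#' Frames in which either fly's centroid speed exceeds `max_speed` or its
#' orientation changes faster than `max_turn` are marked invalid and
#' excluded from downstream statistics (no interpolation).
#'
#' @param pair a [tracked_pair()].
#' @param max_speed mm/s (default 25).
#' @param max_turn degrees/s (default 400).
#' @return the pair with an updated logical `valid` column.
#' @export
clean_tracks <- function(pair, max_speed = 25, max_turn = 400) {
  stopifnot(inherits(pair, "tracked_pair"))
  f <- pair$frames
  if (nrow(f) < 2) stop("need at least 2 frames")
  fs <- pair$fs
  bad_fly <- function(x, y, ori) {
    v <- c(0, sqrt(diff(x)^2 + diff(y)^2) * fs)
    w <- c(0, abs(diff(unwrap_deg(ori))) * fs)
    v > max_speed | w > max_turn
  }
  bad <- bad_fly(f$rx, f$ry, f$rori) | bad_fly(f$sx, f$sy, f$sori)
  if (all(bad)) stop("all frames invalid")
  pair$frames$valid <- f$valid & !bad
  pair
}

# antennae / abdomen keypoints synthesized from centroid + orientation
keypoints <- function(x, y, ori, offset = 1.2) {
  list(antennae = cbind(x + offset * cos(deg2rad(ori)),
                        y + offset * sin(deg2rad(ori))),
       abdomen = cbind(x - offset * cos(deg2rad(ori)),
                       y - offset * sin(deg2rad(ori))))
}

#' Opposite-sex preference (OSP) score
#'
#' Percentage-scaled difference between the time a receiver spends within
#' `radius` mm of an opposite-sex stimulus and the time a same-sex control
#' receiver spends within the same radius:
#' `OSP = (t_opposite - t_same) / T * 100`, `T` being the recorded duration
#' of one assay. Frames within `rim_margin` of the arena wall are excluded.
#' Distance is measured between stimulus and receiver centroids.
#'
#' @param pair_opposite,pair_same [tracked_pair()] recordings with an
#'   opposite-sex and a same-sex stimulus fly.
#' @param radius scoring radius around the stimulus, mm (default 5).
#' @param rim_margin rim exclusion margin, mm (default 2).
#' @param max_radius largest radius of the distance profiles, mm.
#' @return object of class `osp_result`: `osp` (percent), and cumulative
#'   and discrete 1-mm-bin profiles.
#' @export
osp_score <- function(pair_opposite, pair_same, radius = 5, rim_margin = 2,
                      max_radius = 12) {
  stopifnot(inherits(pair_opposite, "tracked_pair"),
            inherits(pair_same, "tracked_pair"))
  n1 <- nrow(pair_opposite$frames)
  n2 <- nrow(pair_same$frames)
  if (abs(n1 / pair_opposite$fs - n2 / pair_same$fs) > 1) {
    stop("assay durations differ by more than 1 s")
  }
  time_within <- function(pair, r) {
    f <- pair$frames
    d <- sqrt((f$rx - f$sx)^2 + (f$ry - f$sy)^2)
    rim <- pair$arena_radius -
      sqrt((f$rx - pair$arena_center[1])^2 + (f$ry - pair$arena_center[2])^2)
    ok <- f$valid & rim >= rim_margin
    sum(ok & d <= r) / pair$fs
  }
  T_total <- n1 / pair_opposite$fs
  radii <- seq_len(max_radius)
  cum_opp <- vapply(radii, function(r) time_within(pair_opposite, r), 1)
  cum_same <- vapply(radii, function(r) time_within(pair_same, r), 1)
  cumulative <- data.frame(radius = radii,
                           osp = (cum_opp - cum_same) / T_total * 100)
  discrete <- data.frame(radius = radii,
                         osp = (diff(c(0, cum_opp)) - diff(c(0, cum_same))) /
                           T_total * 100)
  osp <- (time_within(pair_opposite, radius) -
            time_within(pair_same, radius)) / T_total * 100
  structure(list(osp = osp, radius = radius, cumulative = cumulative,
                 discrete = discrete),
            class = "osp_result")
}

#' @export
print.osp_result <- function(x, ...) {
  cat(sprintf("opposite-sex preference: %.2f%% within %g mm\n",
              x$osp, x$radius))
  invisible(x)
}

#' Egocentric relative orientation of the stimulus
#'
#' Angle of the stimulus direction in the receiver's heading frame: 0
#' degrees directly ahead, positive to the receiver's right, wrapped to
#' (-180, 180].
#'
#' @param pair a [tracked_pair()].
#' @param frame frame index (vectorized).
#' @return relative orientation(s) in degrees.
#' @export
relative_orientation <- function(pair, frame) {
  f <- pair$frames[frame, , drop = FALSE]
  dx <- f$sx - f$rx
  dy <- f$sy - f$ry
  if (any(dx == 0 & dy == 0)) stop("coincident receiver/stimulus positions")
  bearing <- rad2deg(atan2(dy, dx)) # world angle, CCW positive
  # CCW bearing relative to heading is positive to the left; flip the sign
  # so that positive is the receiver's right.
  wrap_angle(-(bearing - f$rori))
}

#' Detect turn initiations within pheromone-detection range
#'
#' A turn starts when the receiver's angular velocity exceeds `vel_thresh`;
#' onsets closer than `min_gap` are merged into the first. Turns are kept
#' only when the antennae-to-abdomen distance is below `range_outer`, the
#' centroid distance exceeds `range_inner`, and the pair is not within (or
#' in the `contact_cooloff` window after) a close-contact episode (centroid
#' distance below `range_inner`). Events whose facing-angle change is a
#' regression outlier relative to their onset angular velocity (residual
#' beyond `outlier_sd` standard deviations) are discarded.
#'
#' @param pair a cleaned [tracked_pair()].
#' @param vel_thresh angular velocity threshold, degrees/s (default 60).
#' @param min_gap minimal gap between turns, s (default 1).
#' @param range_outer maximal antennae-abdomen distance, mm (default 5).
#' @param range_inner minimal centroid distance, mm (default 2).
#' @param contact_cooloff exclusion window after close contact, s
#'   (default 30).
#' @param outlier_sd residual threshold of the outlier rule (default 3;
#'   applied when at least 5 events are available).
#' @param keypoint_offset antennae/abdomen offset from the centroid along
#'   the heading, mm (default 1.2).
#' @return data.frame of turn events: `frame`, `time`, `rel_orientation`,
#'   `angular_velocity`, `facing_change`.
#' @export
detect_turns <- function(pair, vel_thresh = 60, min_gap = 1,
                         range_outer = 5, range_inner = 2,
                         contact_cooloff = 30, outlier_sd = 3,
                         keypoint_offset = 1.2) {
  stopifnot(inherits(pair, "tracked_pair"))
  f <- pair$frames
  fs <- pair$fs
  n <- nrow(f)
  ori <- unwrap_deg(f$rori)
  # central-difference angular velocity
  av <- c(NA, (ori[3:n] - ori[1:(n - 2)]) * fs / 2, NA)
  av[1] <- av[2]; av[n] <- av[n - 1]
  kp_r <- keypoints(f$rx, f$ry, f$rori, keypoint_offset)
  kp_s <- keypoints(f$sx, f$sy, f$sori, keypoint_offset)
  d_ant_abd <- sqrt(rowSums((kp_r$antennae - kp_s$abdomen)^2))
  d_cent <- sqrt((f$rx - f$sx)^2 + (f$ry - f$sy)^2)
  # contact episodes and cool-off
  contact <- d_cent < range_inner
  excluded <- contact
  if (any(contact)) {
    cool_frames <- round(contact_cooloff * fs)
    ends <- which(diff(c(contact, FALSE)) == -1)
    for (e in ends) {
      excluded[seq(e + 1, min(n, e + cool_frames))] <- TRUE
    }
  }
  above <- !is.na(av) & abs(av) > vel_thresh & f$valid
  onsets <- which(above & !c(FALSE, above[-n]))
  if (length(onsets) == 0) {
    return(empty_turns())
  }
  # merge onsets closer than min_gap into the first
  gap_frames <- round(min_gap * fs)
  keep <- logical(length(onsets))
  last <- -Inf
  for (i in seq_along(onsets)) {
    if (onsets[i] - last >= gap_frames) {
      keep[i] <- TRUE
      last <- onsets[i]
    }
  }
  onsets <- onsets[keep]
  in_gate <- d_ant_abd[onsets] < range_outer & d_cent[onsets] > range_inner &
    !excluded[onsets]
  onsets <- onsets[in_gate]
  if (length(onsets) == 0) return(empty_turns())
  # facing-angle change over the suprathreshold excursion
  facing_change <- vapply(onsets, function(o) {
    end <- o
    while (end < n && !is.na(av[end + 1]) && abs(av[end + 1]) > vel_thresh) {
      end <- end + 1
    }
    ori[min(n, end + 1)] - ori[o]
  }, 1)
  events <- data.frame(frame = onsets, time = (onsets - 1) / fs,
                       rel_orientation = relative_orientation(pair, onsets),
                       angular_velocity = av[onsets],
                       facing_change = facing_change)
  if (nrow(events) >= 5) {
    fit <- lm(facing_change ~ angular_velocity, data = events)
    res <- residuals(fit)
    s <- sd(res)
    if (s > 0) events <- events[abs(res) <= outlier_sd * s, , drop = FALSE]
  }
  rownames(events) <- NULL
  events
}

empty_turns <- function() {
  data.frame(frame = integer(), time = numeric(),
             rel_orientation = numeric(), angular_velocity = numeric(),
             facing_change = numeric())
}
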