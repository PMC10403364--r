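# Synthetic behavioral recordings with known ground truth.

#' Generate a biased-random-walk receiver trajectory around a stimulus
#'
#' Emulates a preference assay: a decapitated stimulus fly is fixed 4 mm
#' from one side of a circular chamber and a receiver fly walks freely. The
#' receiver's step direction mixes a uniformly random component with a
#' stimulus-directed component weighted by `attraction_bias`.
#'
#' @param arena_radius arena radius, mm (default 8, a 16 mm chamber).
#' @param duration recording duration, s.
#' @param fs frame rate, Hz (default 30).
#' @param attraction_bias in [0, 1]; 0 is an unbiased walk, 1 walks
#'   straight to the stimulus.
#' @param speed walking speed, mm/s.
#' @param stim_offset distance of the stimulus from the wall, mm
#'   (default 4).
#' @param seed integer seed.
#' @return a [tracked_pair()].
#' @export
generate_osp_trajectories <- function(arena_radius = 8, duration = 120,
                                      fs = 30, attraction_bias = 0,
                                      speed = 10, stim_offset = 4,
                                      seed = NULL) {
  stopifnot(arena_radius > 0, attraction_bias >= 0, attraction_bias <= 1,
            duration > 0, fs > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  sx <- arena_radius - stim_offset
  sy <- 0
  x <- numeric(n); y <- numeric(n); ori <- numeric(n)
  x[1] <- -arena_radius / 2; y[1] <- 0
  step <- speed / fs
  heading <- runif(1, -pi, pi)
  for (i in 2:n) {
    to_stim <- atan2(sy - y[i - 1], sx - x[i - 1])
    rand_dir <- heading + rnorm(1, sd = 1.2)
    # mix of unit vectors: persistent random direction vs stimulus direction
    vx <- (1 - attraction_bias) * cos(rand_dir) +
      attraction_bias * cos(to_stim)
    vy <- (1 - attraction_bias) * sin(rand_dir) +
      attraction_bias * sin(to_stim)
    heading <- atan2(vy, vx)
    # near the stimulus a fully attracted fly hovers instead of overshooting
    len <- min(step, if (attraction_bias > 0.99)
      max(sqrt((sx - x[i - 1])^2 + (sy - y[i - 1])^2) - 0.5, 0) else step)
    xn <- x[i - 1] + len * cos(heading)
    yn <- y[i - 1] + len * sin(heading)
    # reflect at the wall
    r <- sqrt(xn^2 + yn^2)
    if (r > arena_radius - 0.5) {
      heading <- atan2(-yn, -xn) + runif(1, -0.5, 0.5)
      xn <- x[i - 1] + len * cos(heading)
      yn <- y[i - 1] + len * sin(heading)
    }
    x[i] <- xn; y[i] <- yn; ori[i - 1] <- rad2deg(heading)
  }
  ori[n] <- ori[n - 1]
  frames <- data.frame(frame = seq_len(n), rx = x, ry = y, rori = ori,
                       sx = sx, sy = sy, sori = 0)
  tracked_pair(frames, fs = fs, arena_center = c(0, 0),
               arena_radius = arena_radius)
}

#' Generate a scripted turn scenario
#'
#' Builds a tracked pair in which the receiver sits at the arena center and
#' executes scripted turns with known onset times, stimulus-relative
#' orientations and angular speeds, for round-trip testing of
#' [detect_turns()]. Between turns the receiver's orientation is constant;
#' the stimulus is placed so that at each turn onset it sits at the scripted
#' relative orientation and centroid distance.
#'
#' @param turns data.frame with columns `time` (s), `rel_orientation`
#'   (deg), `ang_speed` (deg/s), and optionally `duration` (s, default
#'   0.5) and `centroid_dist` (mm, default 3).
#' @param total_duration recording length, s.
#' @param fs frame rate, Hz (default 30).
#' @param arena_radius arena radius, mm.
#' @param seed unused; accepted for interface uniformity.
#' @return a [tracked_pair()] with attribute `"scripted"` holding the
#'   expanded turn table.
#' @export
generate_turn_scenario <- function(turns, total_duration = NULL, fs = 30,
                                   arena_radius = 8, seed = NULL) {
  stopifnot(all(c("time", "rel_orientation", "ang_speed") %in% names(turns)))
  turns <- turns[order(turns$time), , drop = FALSE]
  if (is.null(turns$duration)) turns$duration <- 0.5
  if (is.null(turns$centroid_dist)) turns$centroid_dist <- 3
  if (any(diff(turns$time) < turns$duration[-nrow(turns)])) {
    stop("overlapping scripted turns")
  }
  if (is.null(total_duration)) {
    total_duration <- max(turns$time + turns$duration) + 5
  }
  n <- round(total_duration * fs)
  t <- (seq_len(n) - 1) / fs
  # receiver at the center; orientation piecewise: constant, then ramps
  ori <- numeric(n)
  cur <- 0
  sx <- numeric(n); sy <- numeric(n)
  # default stimulus placement from the first scripted turn
  place_stim <- function(ori_now, rel, dist) {
    world <- deg2rad(ori_now - rel) # rel positive = right = CW from heading
    c(dist * cos(world), dist * sin(world))
  }
  seg_start <- 1
  for (k in seq_len(nrow(turns))) {
    tk <- turns$time[k]
    dur <- turns$duration[k]
    i0 <- which(t >= tk)[1]
    i1 <- min(n, which(t >= tk + dur)[1])
    ori[seg_start:(i0 - 1)] <- cur
    p <- place_stim(cur, turns$rel_orientation[k], turns$centroid_dist[k])
    span <- if (k < nrow(turns)) {
      seg_start:(which(t >= turns$time[k + 1])[1] - 1)
    } else {
      seg_start:n
    }
    sx[span] <- p[1]; sy[span] <- p[2]
    ramp <- i0:i1
    ori[ramp] <- cur + turns$ang_speed[k] * (t[ramp] - t[i0])
    cur <- ori[i1]
    if (i1 < n) ori[(i1 + 1):n] <- cur
    seg_start <- i1 + 1
  }
  frames <- data.frame(frame = seq_len(n), rx = 0, ry = 0,
                       rori = wrap_angle(ori), sx = sx, sy = sy, sori = 0)
  pair <- tracked_pair(frames, fs = fs, arena_center = c(0, 0),
                       arena_radius = arena_radius)
  attr(pair, "scripted") <- turns
  pair
}
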