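# Forward model of distance-dependent pheromone responses with
# contralateral inhibition.

#' Forward-model parameters
#'
#' Parameters of the generative model used throughout the synthetic-data
#' module: a logistic dependence of the instantaneous sensory drive on the
#' distance between the stimulus fly and an antenna, a first-order calcium
#' kernel, and a linear bilateral circuit in which each projection neuron
#' (PN) pools ipsi- and contralateral receptor-neuron (ORN) input and is
#' inhibited by a local interneuron driven from the contralateral antenna.
#'
#' The instantaneous drive at distance `d` (mm) is
#' `R(d) = base + (top - base) / (1 + exp((d - ed50) / slope))`,
#' so `ed50` is the half-maximal distance and responses decay with distance.
#'
#' @param top maximal normalized response (dimensionless).
#' @param base asymptotic far-field response; `top > base >= 0`.
#' @param ed50 half-maximal distance in mm, > 0.
#' @param slope logistic scale in mm, > 0.
#' @param w_ipsi,w_contra excitatory weights of the ipsi- and contralateral
#'   ORN onto a PN; `w_ipsi >= w_contra >= 0`. The default ratio 1 : 0.69
#'   follows the ipsi/contra ORN-to-lPN synapse counts (5,184 vs 3,580).
#' @param g_inhib gain of contralateral inhibition (>= 0). The default 0.9
#'   exceeds `w_contra`, making the net effect of a purely contralateral
#'   stimulus inhibitory, as observed in antennal-block experiments.
#' @param tau_rise calcium kernel time constant in seconds.
#' @param noise_sd standard deviation of i.i.d. Gaussian noise per sample
#'   (dF/F units).
#' @param antenna_sep inter-antennal distance in mm (default 0.3, on the
#'   order of a fly head width; not an empirically constrained value).
#' @return an object of class `forward_model_params`.
#' @export
forward_model_params <- function(top = 1, base = 0, ed50 = 2.4, slope = 0.5,
                                 w_ipsi = 1, w_contra = 0.69, g_inhib = 0.9,
                                 tau_rise = 0.3, noise_sd = 0.05,
                                 antenna_sep = 0.3) {
  stopifnot(top > base, base >= 0, ed50 > 0, slope > 0,
            w_ipsi >= w_contra, w_contra >= 0, g_inhib >= 0,
            tau_rise > 0, noise_sd >= 0, antenna_sep > 0)
  structure(list(top = top, base = base, ed50 = ed50, slope = slope,
                 w_ipsi = w_ipsi, w_contra = w_contra, g_inhib = g_inhib,
                 tau_rise = tau_rise, noise_sd = noise_sd,
                 antenna_sep = antenna_sep),
            class = "forward_model_params")
}

#' Preset forward-model parameters per cell type
#'
#' ED50 presets: 2.2 mm (ORN), 2.4 mm (lPN), 1.5 mm (lvPN). Time constants
#' are set so that lPNs track a moving stimulus faster than ORNs,
#' consistent with the shorter reported stimulus-response lag.
#'
#' @param cell_type one of "orn", "lpn", "lvpn".
#' @param ... overrides passed to [forward_model_params()].
#' @return a `forward_model_params` object.
#' @export
forward_model_preset <- function(cell_type = c("orn", "lpn", "lvpn"), ...) {
  cell_type <- match.arg(cell_type)
  defaults <- switch(cell_type,
    orn  = list(ed50 = 2.2, tau_rise = 0.6),
    lpn  = list(ed50 = 2.4, tau_rise = 0.3),
    lvpn = list(ed50 = 1.5, tau_rise = 0.8))
  args <- utils::modifyList(defaults, list(...))
  do.call(forward_model_params, args)
}

#' Logistic distance-response function
#'
#' @param d distance in mm (vectorized).
#' @param params a `forward_model_params` object.
#' @return instantaneous drive at each distance.
#' @export
logistic_response <- function(d, params) {
  params$base + (params$top - params$base) /
    (1 + exp((d - params$ed50) / params$slope))
}

#' Stimulus script: piecewise-linear stimulus trajectory
#'
#' Waypoints of the stimulus fly's position in the receiver frame
#' (x forward, y right, mm). Position is interpolated linearly between
#' waypoints (constant velocity), and held at the last waypoint after the
#' final time.
#'
#' @param time strictly increasing waypoint times in seconds.
#' @param x,y waypoint coordinates in mm.
#' @return an object of class `stimulus_script`.
#' @export
stimulus_script <- function(time, x, y) {
  stopifnot(length(time) == length(x), length(x) == length(y),
            all(is.finite(time)), all(is.finite(x)), all(is.finite(y)))
  if (any(diff(time) <= 0)) stop("waypoint times must be strictly increasing")
  structure(list(time = time, x = x, y = y), class = "stimulus_script")
}

#' Evaluate a stimulus script at given times
#' @param script a `stimulus_script`.
#' @param t times in seconds.
#' @return data.frame with columns `time`, `x`, `y`.
#' @export
script_position <- function(script, t) {
  x <- approx(script$time, script$x, xout = t, rule = 2)$y
  y <- approx(script$time, script$y, xout = t, rule = 2)$y
  data.frame(time = t, x = x, y = y)
}

#' Approach-hold-retreat presentation script
#'
#' The stimulus starts 10 mm in front of the receiver, approaches along the
#' midline to `distance` at `speed`, holds for `hold` seconds, and retreats.
#'
#' @param distance hold distance in mm.
#' @param speed approach speed in mm/s.
#' @param hold hold duration in seconds.
#' @param start_distance starting distance in mm.
#' @param lead time before the approach starts, seconds.
#' @return a `stimulus_script`.
#' @export
script_presentation <- function(distance, speed = 8.04, hold = 10,
                                start_distance = 10, lead = 2) {
  stopifnot(distance > 0, speed > 0, hold > 0, start_distance > distance)
  travel <- (start_distance - distance) / speed
  stimulus_script(
    time = c(0, lead, lead + travel, lead + travel + hold,
             lead + 2 * travel + hold),
    x = c(start_distance, start_distance, distance, distance, start_distance),
    y = c(0, 0, 0, 0, 0))
}

antenna_positions <- function(params) {
  list(left  = c(0, -params$antenna_sep / 2),
       right = c(0,  params$antenna_sep / 2))
}

# exact first-order low-pass of an instantaneous drive sampled at fs;
# initialized at the steady state of the first sample.
first_order_kernel <- function(drive, fs, tau) {
  a <- exp(-1 / (fs * tau))
  out <- numeric(length(drive))
  out[1] <- drive[1]
  for (i in seq_along(drive)[-1]) {
    out[i] <- a * out[i - 1] + (1 - a) * drive[i]
  }
  out
}

#' Simulate a single-antenna ORN calcium trace
#'
#' Computes the distance from the scripted stimulus position to one antenna,
#' applies the logistic distance-response function, convolves with a
#' first-order calcium kernel and adds Gaussian noise.
#'
#' @param params a `forward_model_params` object.
#' @param script a `stimulus_script`.
#' @param antenna `"left"` or `"right"`.
#' @param fs sampling rate in Hz.
#' @param seed optional integer seed for the noise.
#' @param duration trace duration in seconds (default: script end).
#' @param stim_onset,stim_offset stimulus epoch annotations in seconds
#'   (defaults: second and second-to-last waypoint times).
#' @return a [dff_trace()].
#' @export
simulate_orn_trace <- function(params, script, antenna = c("left", "right"),
                               fs = 7.2, seed = NULL, duration = NULL,
                               stim_onset = NULL, stim_offset = NULL) {
  antenna <- match.arg(antenna)
  stopifnot(inherits(params, "forward_model_params"),
            inherits(script, "stimulus_script"))
  if (fs <= 0) stop("fs must be positive")
  if (is.null(duration)) duration <- max(script$time)
  n <- max(2L, floor(duration * fs))
  t <- (seq_len(n) - 1) / fs
  pos <- script_position(script, t)
  if (any(!is.finite(pos$x)) || any(!is.finite(pos$y))) {
    stop("non-finite stimulus positions")
  }
  ant <- antenna_positions(params)[[antenna]]
  d <- sqrt((pos$x - ant[1])^2 + (pos$y - ant[2])^2)
  drive <- logistic_response(d, params)
  resp <- first_order_kernel(drive, fs, params$tau_rise)
  if (params$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    resp <- resp + rnorm(n, sd = params$noise_sd)
  }
  k <- length(script$time)
  if (is.null(stim_onset)) stim_onset <- script$time[min(2L, k)]
  if (is.null(stim_offset)) stim_offset <- script$time[max(1L, k - 1L)]
  dff_trace(resp, fs = fs, stim_onset = stim_onset,
            stim_offset = stim_offset, side = antenna)
}

#' Simulate bilateral PN calcium traces
#'
#' Left and right PN drives are
#' `PN_side = w_ipsi * ORN_same + (w_contra - g_inhib) * ORN_other`,
#' the contralateral inhibition being relayed by a local interneuron driven
#' from the contralateral antenna only. Drives are rectified at zero by
#' default; `rectify = FALSE` exposes the negative pre-clip drive
#' (sustained suppression).
#'
#' In this linear model the raw ipsi-contra response difference of the PNs
#' exceeds that of the ORNs exactly when `w_ipsi - w_contra + g_inhib > 1`;
#' the defaults satisfy this.
#'
#' @inheritParams simulate_orn_trace
#' @param rectify clip negative PN drives at zero (default TRUE).
#' @return list with elements `left` and `right`, each a [dff_trace()].
#' @export
simulate_bilateral_pn <- function(params, script, fs = 7.2, seed = NULL,
                                  duration = NULL, rectify = TRUE,
                                  stim_onset = NULL, stim_offset = NULL) {
  if (params$w_ipsi < 0 || params$w_contra < 0) stop("negative weights")
  noiseless <- params
  noiseless$noise_sd <- 0
  orn_l <- simulate_orn_trace(noiseless, script, "left", fs,
                              duration = duration,
                              stim_onset = stim_onset,
                              stim_offset = stim_offset)
  orn_r <- simulate_orn_trace(noiseless, script, "right", fs,
                              duration = duration,
                              stim_onset = stim_onset,
                              stim_offset = stim_offset)
  w_net <- params$w_contra - params$g_inhib
  pn_l <- params$w_ipsi * orn_l$samples + w_net * orn_r$samples
  pn_r <- params$w_ipsi * orn_r$samples + w_net * orn_l$samples
  if (rectify) {
    pn_l <- pmax(pn_l, 0)
    pn_r <- pmax(pn_r, 0)
  }
  if (params$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    pn_l <- pn_l + rnorm(length(pn_l), sd = params$noise_sd)
    pn_r <- pn_r + rnorm(length(pn_r), sd = params$noise_sd)
  }
  list(left = dff_trace(pn_l, fs = fs, stim_onset = orn_l$stim_onset,
                        stim_offset = orn_l$stim_offset, side = "left"),
       right = dff_trace(pn_r, fs = fs, stim_onset = orn_r$stim_onset,
                         stim_offset = orn_r$stim_offset, side = "right"))
}

#' Steady-state bilateral responses at stimulus positions
#'
#' Noise-free left/right responses of the forward model evaluated at one or
#' more stimulus positions, either at the sensory input (`"orn"`) or after
#' the bilateral circuit with contralateral inhibition (`"pn"`).
#'
#' @param params a `forward_model_params` object.
#' @param x,y stimulus coordinates, mm (fly at origin, facing +y).
#' @param cell_type `"pn"` (circuit output, default) or `"orn"`.
#' @param code `"logistic"` (forward model, default) or `"linear"` (an
#'   affine bilateral code, exactly within the decoder's model class).
#' @param rectify clip negative PN responses at zero (default TRUE).
#' @return data.frame with columns `left` and `right`.
#' @export
steady_state_bilateral <- function(params, x, y,
                                   cell_type = c("pn", "orn"),
                                   code = c("logistic", "linear"),
                                   rectify = TRUE) {
  cell_type <- match.arg(cell_type)
  code <- match.arg(code)
  if (code == "linear") {
    # affine bilateral code used for decoder identifiability checks:
    # responses are exactly linear in the stimulus coordinates.
    c0 <- 0.5; c1 <- 0.10; c2 <- 0.12
    return(data.frame(left = c0 + c1 * x - c2 * y,
                      right = c0 + c1 * x + c2 * y))
  }
  ant <- antenna_positions(params)
  d_l <- sqrt((x - ant$left[1])^2 + (y - ant$left[2])^2)
  d_r <- sqrt((x - ant$right[1])^2 + (y - ant$right[2])^2)
  o_l <- logistic_response(d_l, params)
  o_r <- logistic_response(d_r, params)
  if (cell_type == "orn") return(data.frame(left = o_l, right = o_r))
  w_net <- params$w_contra - params$g_inhib
  p_l <- params$w_ipsi * o_l + w_net * o_r
  p_r <- params$w_ipsi * o_r + w_net * o_l
  if (rectify) {
    p_l <- pmax(p_l, 0)
    p_r <- pmax(p_r, 0)
  }
  data.frame(left = p_l, right = p_r)
}

#' Generate a lattice stimulation session
#'
#' Simulates per-fly, per-trial bilateral peak responses to a stimulus
#' presented at every position of a hexagonal lattice, with ground truth
#' stored alongside. Responses are steady-state values of the forward model
#' plus i.i.d. Gaussian trial noise.
#'
#' @param params a `forward_model_params` object.
#' @param lattice a [build_hex_lattice()] object.
#' @param n_flies,n_trials numbers of flies and trials per position.
#' @param seed integer seed.
#' @param cell_type `"pn"` (bilateral circuit output, default) or `"orn"`.
#' @param code `"logistic"` (forward model, default) or `"linear"` (an
#'   affine bilateral code, exactly within the decoder's model class; used
#'   to validate decoder recovery).
#' @return data.frame with columns `fly`, `trial`, `pos`, `left`, `right`,
#'   `x`, `y`, `distance`, `angle`.
#' @export
generate_lattice_session <- function(params = forward_model_params(),
                                     lattice = build_hex_lattice(),
                                     n_flies = 8, n_trials = 3, seed = NULL,
                                     cell_type = c("pn", "orn"),
                                     code = c("logistic", "linear")) {
  cell_type <- match.arg(cell_type)
  code <- match.arg(code)
  if (n_flies < 1 || n_trials < 1) stop("n_flies and n_trials must be >= 1")
  pos <- lattice$positions
  ss <- steady_state_bilateral(params, pos$x, pos$y, cell_type, code)
  grid <- expand.grid(fly = seq_len(n_flies), trial = seq_len(n_trials),
                      pos = pos$pos)
  idx <- match(grid$pos, pos$pos)
  out <- data.frame(grid,
                    left = ss$left[idx], right = ss$right[idx],
                    x = pos$x[idx], y = pos$y[idx],
                    distance = pos$distance[idx], angle = pos$angle[idx])
  if (params$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    out$left <- out$left + rnorm(nrow(out), sd = params$noise_sd)
    out$right <- out$right + rnorm(nrow(out), sd = params$noise_sd)
  }
  out[order(out$pos, out$fly, out$trial), , drop = FALSE]
}
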