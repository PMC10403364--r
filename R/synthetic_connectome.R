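# Toy synapse tables with planted partner classes, and a distance-series
# response generator with known ground truth.

#' Generate a toy synapse table from a connection specification
#'
#' Expands a per-connection specification into individual synapse records
#' with deterministic neuron ids, so that planted selection decisions and
#' input-selectivity classes are recoverable by the connectome analyses.
#'
#' @param spec data.frame with columns `pre_type`, `post_type`, `weight`
#'   (total synapse count for the connection) and optionally `side`
#'   (default `"unknown"`), `roi` (default `"AL"`), `n_pre`, `n_post`
#'   (numbers of distinct cells per type in this connection, default 1;
#'   the weight is split as evenly as possible across cell pairs).
#' @return a [synapse_table()].
#' @export
generate_toy_connectome <- function(spec) {
  stopifnot(is.data.frame(spec),
            all(c("pre_type", "post_type", "weight") %in% names(spec)))
  if (nrow(spec) == 0) stop("empty specification")
  if (any(spec$weight < 1 | spec$weight != round(spec$weight))) {
    stop("weights must be positive integers")
  }
  if (is.null(spec$side)) spec$side <- "unknown"
  if (is.null(spec$roi)) spec$roi <- "AL"
  if (is.null(spec$n_pre)) spec$n_pre <- 1L
  if (is.null(spec$n_post)) spec$n_post <- 1L
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    r <- spec[i, ]
    pairs <- expand.grid(pre = seq_len(r$n_pre), post = seq_len(r$n_post))
    np <- nrow(pairs)
    w <- rep(r$weight %/% np, np)
    # leftover synapses go to the first pairs
    extra <- r$weight %% np
    if (extra > 0) w[seq_len(extra)] <- w[seq_len(extra)] + 1
    keep <- w > 0
    data.frame(pre_id = sprintf("%s.%d", r$pre_type, pairs$pre[keep]),
               pre_type = r$pre_type,
               post_id = sprintf("%s.%d", r$post_type, pairs$post[keep]),
               post_type = r$post_type, roi = r$roi, side = r$side,
               weight = w[keep])
  })
  synapse_table(do.call(rbind, rows))
}

#' Generate a distance-series response session
#'
#' Steady-state logistic responses at a set of probe distances for several
#' flies and trials, with i.i.d. Gaussian trial noise — the synthetic
#' counterpart of a distance-tuning imaging experiment.
#'
#' @param params a [forward_model_params()].
#' @param distances probe distances in mm (default the ten standard
#'   presentation distances).
#' @param n_flies,n_trials numbers of flies and trials per fly (defaults
#'   8 and 3).
#' @param seed integer seed.
#' @return data.frame with columns `fly`, `trial`, `distance`, `response`.
#' @export
generate_distance_session <- function(params,
                                      distances = c(5, 3.5, 3, 2.5, 2, 1.5,
                                                    1, 0.75, 0.5, 0.25),
                                      n_flies = 8, n_trials = 3,
                                      seed = NULL) {
  stopifnot(inherits(params, "forward_model_params"),
            n_flies >= 1, n_trials >= 1, all(distances > 0))
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(distance = distances, trial = seq_len(n_trials),
                      fly = seq_len(n_flies))
  mu <- logistic_response(grid$distance, params)
  response <- mu + if (params$noise_sd > 0) {
    rnorm(nrow(grid), sd = params$noise_sd)
  } else {
    0
  }
  data.frame(fly = grid$fly, trial = grid$trial, distance = grid$distance,
             response = response)
}
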