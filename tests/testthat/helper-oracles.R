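# Independent brute-force oracles used to validate the package's optimized
# or library-backed implementations.

# Textbook cross-correlation estimator: r(k) = c_xy(k) / sqrt(c_xx(0) c_yy(0))
# with c_xy(k) = (1/n) * sum_t (x[t+k] - mean(x)) (y[t] - mean(y)).
# Positive k means x follows y. Returns the argmax lag (in samples) and r.
oracle_ccf_lag <- function(x, y, lag_max) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  cx <- sum((x - mx)^2) / n
  cy <- sum((y - my)^2) / n
  ks <- -lag_max:lag_max
  r <- vapply(ks, function(k) {
    if (k >= 0) {
      t <- seq_len(n - k)
      sum((x[t + k] - mx) * (y[t] - my)) / n
    } else {
      t <- seq_len(n + k)
      sum((x[t] - mx) * (y[t - k] - my)) / n
    }
  }, 1) / sqrt(cx * cy)
  best <- which.max(r)
  list(lag = ks[best], correlation = r[best])
}

# Grid-search objective for the circular median: mean unsigned circular
# distance (degrees) from m to the sample.
oracle_circ_objective <- function(angles, m) {
  d <- (angles - m) %% 360
  d <- pmin(d, 360 - d)
  mean(d)
}

# Best objective over a fine grid of candidate directions.
oracle_circ_median_objective <- function(angles, step = 0.05) {
  grid <- seq(-180, 180, by = step)
  min(vapply(grid, function(m) oracle_circ_objective(angles, m), 1))
}

# Exact two-sided permutation p-value for the difference in means, by
# bitmask enumeration of all subsets of size n1 (independent of combn).
oracle_perm_p <- function(g1, g2) {
  x <- c(g1, g2)
  n <- length(x)
  n1 <- length(g1)
  obs <- mean(g1) - mean(g2)
  stats <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (sum(bits) != n1) next
    stats <- c(stats, mean(x[bits]) - mean(x[!bits]))
  }
  mean(abs(stats) >= abs(obs) - 1e-12)
}

# Decoder coefficients by explicit normal equations.
oracle_decoder_coefs <- function(responses) {
  X <- cbind(1, responses$right - responses$left,
             responses$right + responses$left)
  Y <- cbind(responses$x, responses$y)
  solve(t(X) %*% X, t(X) %*% Y)
}

# Independent hexagonal-lattice enumeration: integer combinations of the
# basis vectors (s, 0) and (s/2, s*sqrt(3)/2), radius filter, rear exclusion.
oracle_hex_positions <- function(spacing, max_distance) {
  pts <- NULL
  rng <- -10:10
  for (i in rng) for (j in rng) {
    px <- i * spacing + j * spacing / 2
    py <- j * spacing * sqrt(3) / 2
    r <- sqrt(px^2 + py^2)
    if (r < 1e-9 || r > max_distance + 1e-9) next
    ang <- atan2(py, px) * 180 / pi
    if (abs(abs(ang) - 180) < 1e-6) next
    pts <- rbind(pts, c(px, py))
  }
  pts[order(round(pts[, 1], 9), round(pts[, 2], 9)), , drop = FALSE]
}

# Fine-step dead reckoning of a treadmill path by linear interpolation of
# the velocity samples at substep resolution.
oracle_dead_reckon_y <- function(forward, lateral, rotational, fs,
                                 substeps = 200) {
  n <- length(forward)
  dt <- 1 / (fs * substeps)
  h <- 0
  y <- 0
  for (i in seq_len(n)) {
    for (s in seq_len(substeps)) {
      y <- y + (forward[i] * sin(h) + lateral[i] * cos(h)) * dt
      h <- h + rotational[i] * pi / 180 * dt
    }
  }
  y
}
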