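# Hexagonal stimulation lattice, angular tuning and bilateral contrast.

#' Build the hexagonal stimulation lattice
#'
#' All non-origin points of a hexagonal lattice within `max_distance` of the
#' receiver's antennae, excluding points directly behind the fly (angle
#' 180 degrees, occupied by the body). With the defaults this yields 16
#' positions at distances {1, sqrt(3), 2} mm and 11 unique angles at 30
#' degree steps in [-150, 150].
#'
#' @param spacing lattice constant in mm (default 1).
#' @param max_distance maximal distance from the antennae in mm (default 2).
#' @return an object of class `hex_lattice` with a `positions` data.frame
#'   (`pos`, `x`, `y`, `distance`, `angle`).
#' @export
build_hex_lattice <- function(spacing = 1, max_distance = 2) {
  stopifnot(spacing > 0)
  if (max_distance < spacing) stop("max_distance must be >= spacing")
  m <- ceiling(max_distance / spacing) + 1
  ij <- expand.grid(i = -m:m, j = -m:m)
  x <- spacing * (ij$i + ij$j / 2)
  y <- spacing * ij$j * sqrt(3) / 2
  r <- sqrt(x^2 + y^2)
  keep <- r > 1e-9 & r <= max_distance + 1e-9
  x <- x[keep]; y <- y[keep]; r <- r[keep]
  ang <- wrap_angle(rad2deg(atan2(y, x)))
  behind <- abs(ang - 180) < 1e-6
  pos <- data.frame(x = x[!behind], y = y[!behind],
                    distance = r[!behind], angle = ang[!behind])
  pos <- pos[order(pos$distance, pos$angle), ]
  pos <- cbind(pos = seq_len(nrow(pos)), pos)
  rownames(pos) <- NULL
  structure(list(positions = pos, spacing = spacing,
                 max_distance = max_distance),
            class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  p <- x$positions
  cat(sprintf(
    "hexagonal lattice: %d positions, %d unique angles, distances {%s} mm\n",
    nrow(p), length(unique(round(p$angle, 6))),
    paste(sort(unique(round(p$distance, 3))), collapse = ", ")))
  invisible(x)
}

#' Bilateral contrast
#'
#' Signed difference of mean responses to ipsi- and contralateral stimulus
#' presentations.
#'
#' @param ipsi,contra mean responses (same window), numeric.
#' @return `ipsi - contra`.
#' @export
bilateral_contrast <- function(ipsi, contra) ipsi - contra

#' Angular tuning curves at a fixed lattice distance
#'
#' Mean left and right responses for the 11 lattice angles at the middle
#' (sqrt(3) mm) ring. At the six angles measured directly on that ring the
#' means are direct; at the five angles {0, +-60, +-120} the value is
#' linearly interpolated in distance between the 1 mm and 2 mm rings:
#' `v = v_1mm * (2 - sqrt(3)) + v_2mm * (sqrt(3) - 1)`.
#'
#' @param responses data.frame of bilateral responses (columns `fly`,
#'   `trial`, `pos`, `left`, `right`), e.g. from
#'   [generate_lattice_session()].
#' @param lattice the [build_hex_lattice()] the positions refer to.
#' @return data.frame with columns `angle`, `left`, `right`, `sem_left`,
#'   `sem_right`, `provenance` ("direct" or "interpolated").
#' @export
angular_tuning <- function(responses, lattice) {
  pos <- lattice$positions
  if (!all(pos$pos %in% responses$pos)) stop("responses must cover all positions")
  ring_mid <- sqrt(3) * lattice$spacing
  w1 <- 2 - sqrt(3)
  w2 <- sqrt(3) - 1
  # per-fly means per position, then mean and SEM across flies
  fly_means <- aggregate(cbind(left, right) ~ fly + pos, data = responses,
                         FUN = mean)
  fly_means <- merge(fly_means, pos[, c("pos", "distance", "angle")],
                     by = "pos")
  fly_means$distance <- round(fly_means$distance, 6)
  angles <- sort(unique(round(pos$angle, 6)))
  per_fly_angle <- do.call(rbind, lapply(angles, function(a) {
    sub <- fly_means[abs(fly_means$angle - a) < 1e-6, ]
    direct <- sub[abs(sub$distance - ring_mid) < 1e-6, ]
    if (nrow(direct) > 0) {
      data.frame(angle = a, fly = direct$fly, left = direct$left,
                 right = direct$right, provenance = "direct")
    } else {
      near <- sub[abs(sub$distance - lattice$spacing) < 1e-6, ]
      far <- sub[abs(sub$distance - 2 * lattice$spacing) < 1e-6, ]
      if (nrow(near) == 0 || nrow(far) == 0) {
        stop(sprintf("missing ring data at angle %g", a))
      }
      near <- near[order(near$fly), ]; far <- far[order(far$fly), ]
      stopifnot(identical(near$fly, far$fly))
      data.frame(angle = a, fly = near$fly,
                 left = near$left * w1 + far$left * w2,
                 right = near$right * w1 + far$right * w2,
                 provenance = "interpolated")
    }
  }))
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  out <- do.call(rbind, lapply(split(per_fly_angle, per_fly_angle$angle),
    function(g) data.frame(angle = g$angle[1],
                           left = mean(g$left), right = mean(g$right),
                           sem_left = sem(g$left), sem_right = sem(g$right),
                           provenance = g$provenance[1])))
  out <- out[order(out$angle), ]
  rownames(out) <- NULL
  out
}

#' Sine/cosine regressions of bilateral responses on angular position
#'
#' Ordinary least squares of the right-left difference on `sin(angle)` and
#' of the right+left sum on `cos(angle)`.
#'
#' @param angle angles in degrees.
#' @param left,right responses at those angles.
#' @return list with components `sin` and `cos`, each holding `slope`,
#'   `intercept` and `r_squared`.
#' @export
sincos_regression <- function(angle, left, right) {
  stopifnot(length(angle) >= 3)
  s <- sin(deg2rad(angle))
  co <- cos(deg2rad(angle))
  if (var(s) == 0 || var(co) == 0) stop("zero predictor variance")
  d <- right - left
  su <- right + left
  fit_d <- lm(d ~ s)
  fit_s <- lm(su ~ co)
  extract <- function(fit, y) {
    # R^2 computed directly (1 - RSS/TSS) so exact fits do not trip the
    # near-singular warning in summary.lm
    rss <- sum(residuals(fit)^2)
    tss <- sum((y - mean(y))^2)
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = 1 - rss / tss)
  }
  list(sin = extract(fit_d, d), cos = extract(fit_s, su))
}
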