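# Circular statistics: median direction and a nonparametric common-median
# test.

circ_dist_abs <- function(a, b) {
  # unsigned circular distance in degrees, in [0, 180]
  d <- abs(wrap_angle(a - b))
  d
}

#' Circular mean direction
#' @param angles angles in degrees.
#' @return mean direction in degrees, wrapped to (-180, 180].
#' @export
circular_mean <- function(angles) {
  th <- deg2rad(angles)
  wrap_angle(rad2deg(atan2(mean(sin(th)), mean(cos(th)))))
}

#' Circular median direction
#'
#' The direction minimizing the mean unsigned circular distance to the
#' sample; evaluated over the data points and all pairwise circular
#' midpoints (both antipodal midpoints), with ties broken toward the
#' circular mean.
#'
#' @param angles angles in degrees.
#' @return median direction in degrees, wrapped to (-180, 180].
#' @export
circular_median <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (length(angles) == 0) stop("empty sample")
  if (length(angles) == 1) return(wrap_angle(angles))
  prs <- combn(angles, 2)
  mids <- wrap_angle((prs[1, ] + prs[2, ]) / 2)
  cand <- unique(wrap_angle(c(angles, mids, mids + 180)))
  obj <- colMeans(abs(wrap_angle(outer(angles, cand, "-"))))
  best <- which(obj <= min(obj) + 1e-12)
  if (length(best) > 1) {
    mu <- circular_mean(angles)
    best <- best[which.min(circ_dist_abs(cand[best], mu))]
  }
  wrap_angle(cand[best])
}

#' Nonparametric test for a common circular median
#'
#' Fisher's chi-squared test that several circular samples share a common
#' median direction (a circular analogue of a nonparametric multi-sample
#' location test). Each sample's observations are classified by which side
#' of the pooled circular median they fall on; the statistic is
#' asymptotically chi-squared with (number of groups - 1) degrees of
#' freedom.
#'
#' @param ... two or more numeric vectors of angles in degrees (or a single
#'   list of them).
#' @return list of class `stat_report`: statistic, df, p-value, and the
#'   pooled median.
#' @export
circular_median_test <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2) stop("need at least two samples")
  if (any(vapply(groups, length, 1L) < 5)) {
    stop("each sample needs at least 5 angles")
  }
  all_angles <- unlist(groups)
  med <- circular_median(all_angles)
  n_i <- vapply(groups, length, 1L)
  N <- sum(n_i)
  # number of observations in each sample lying in the half circle
  # clockwise of the pooled median (signed deviation < 0)
  m_i <- vapply(groups, function(g) sum(wrap_angle(g - med) < 0), 1L)
  M <- sum(m_i)
  if (M == 0 || M == N) {
    stat <- 0
    p <- 1
  } else {
    stat <- N^2 / (M * (N - M)) * sum(m_i^2 / n_i) - N * M / (N - M)
    p <- stats::pchisq(stat, df = length(groups) - 1, lower.tail = FALSE)
  }
  structure(list(test = "common circular median test",
                 statistic = stat, df = length(groups) - 1, p_value = p,
                 pooled_median = med, design = "circular"),
            class = "stat_report")
}
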