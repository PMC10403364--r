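# Stimulus-response kinetics: cross-correlation lags, derivative model,
# speed regression, and the statistical dispatch policy.

#' Lag of maximal cross-correlation between a neural signal and stimulus
#' distance
#'
#' The distance signal is inverted (negated) before correlation so that
#' proximity drives the response; both signals are mean-subtracted and
#' variance-normalized. The lag maximizing the normalized cross-correlation
#' within `+-max_lag` is reported at the sample-grid resolution `1/fs`;
#' positive lags mean the stimulus leads and the neural response follows.
#'
#' @param neural a [dff_trace()].
#' @param distance stimulus distance (mm) sampled at the same rate and
#'   length as `neural`.
#' @param max_lag maximal lag searched, seconds (default 5).
#' @param invert negate the distance before correlating (default TRUE).
#' @return list of class `lag_result`: `lag` (s) and `correlation`.
#' @export
crosscorr_lag <- function(neural, distance, max_lag = 5, invert = TRUE) {
  stopifnot(inherits(neural, "dff_trace"))
  x <- neural$samples
  if (length(x) != length(distance)) stop("signals must have equal length")
  y <- if (invert) -distance else distance
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  fs <- neural$fs
  lag_max <- floor(max_lag * fs)
  cc <- ccf(x, y, lag.max = lag_max, plot = FALSE, demean = TRUE)
  # ccf(x, y) at lag k estimates cor(x[t + k], y[t]); positive k means the
  # neural signal follows the stimulus.
  k <- cc$lag[, 1, 1]
  r <- cc$acf[, 1, 1]
  best <- which.max(r)
  structure(list(lag = k[best] / fs, correlation = r[best], fs = fs),
            class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("cross-correlation lag: %.3f s (r = %.3f)\n",
              x$lag, x$correlation))
  invisible(x)
}

#' Positive first derivative of a response trace
#'
#' First difference scaled by the sampling rate, rectified at zero. Used to
#' model phasic, approach-speed-sensitive responses downstream of tonic
#' distance-tuned inputs. The output has one sample fewer than the input.
#'
#' @param lpn a smoothed [dff_trace()].
#' @return a [dff_trace()] of the rectified derivative (per second).
#' @export
positive_derivative_model <- function(lpn) {
  stopifnot(inherits(lpn, "dff_trace"))
  if (length(lpn$samples) < 2) stop("trace shorter than 2 samples")
  d <- pmax(diff(lpn$samples) * lpn$fs, 0)
  dff_trace(d, fs = lpn$fs, stim_onset = lpn$stim_onset,
            stim_offset = lpn$stim_offset,
            sweep_start = lpn$sweep_start + 1 / lpn$fs,
            roi = lpn$roi, side = lpn$side)
}

#' Regression of observed peaks on derivative-model peaks across speeds
#'
#' Ordinary least squares of observed third-order peak responses on the
#' peaks of the positive lPN response derivative, one point per approach
#' speed (or per speed x fly).
#'
#' @param derivative_peaks numeric vector of derivative-model peaks.
#' @param observed_peaks numeric vector of observed peaks, same length.
#' @param speeds optional speed labels stored with the result.
#' @return list of class `derivative_model_fit`: `slope`, `intercept`,
#'   `r_squared`, and the input table.
#' @export
speed_model_regression <- function(derivative_peaks, observed_peaks,
                                   speeds = NULL) {
  stopifnot(length(derivative_peaks) == length(observed_peaks),
            length(derivative_peaks) >= 2)
  if (var(derivative_peaks) == 0) stop("zero variance in predictor")
  fit <- lm(observed_peaks ~ derivative_peaks)
  rss <- sum(residuals(fit)^2)
  tss <- sum((observed_peaks - mean(observed_peaks))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = 1 - rss / tss,
                 data = data.frame(speed = if (is.null(speeds)) NA else speeds,
                                   derivative_peak = derivative_peaks,
                                   observed_peak = observed_peaks)),
            class = "derivative_model_fit")
}

#' @export
print.derivative_model_fit <- function(x, ...) {
  cat(sprintf(
    "derivative model regression: slope %.3f, intercept %.3f, R^2 %.3f\n",
    x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Normality-gated statistical test dispatch
#'
#' Applies the testing policy used for response comparisons: groups are
#' checked for normality (Shapiro-Wilk) and, for two unpaired groups, equal
#' variance (F test), both at alpha = 0.05. Two groups passing both gates
#' are compared with a t test, otherwise a Wilcoxon test. Multigroup
#' designs use Kruskal-Wallis followed by pairwise Wilcoxon tests with
#' Benjamini-Hochberg correction; repeated designs use a Friedman test
#' followed by paired Wilcoxon tests with Benjamini-Hochberg correction.
#'
#' @param groups list of numeric vectors (for `repeated`, equal lengths
#'   with subjects aligned across conditions).
#' @param design one of `"unpaired"`, `"paired"`, `"multigroup"`,
#'   `"repeated"`.
#' @param alpha gate level for the normality/variance checks.
#' @return list of class `stat_report`: `test`, `statistic`, `p_value`,
#'   optional `pairwise` table with BH-adjusted p-values, and the gate
#'   results.
#' @export
stat_dispatch <- function(groups, design = c("unpaired", "paired",
                                             "multigroup", "repeated"),
                          alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 3)) {
    stop("each group needs at least 3 observations")
  }
  shapiro_p <- vapply(groups, function(g) {
    if (length(unique(g)) < 3) return(0)
    shapiro.test(g)$p.value
  }, 1)
  gates <- list(shapiro_p = shapiro_p)
  if (design == "unpaired") {
    stopifnot(length(groups) == 2)
    f_p <- tryCatch(var.test(groups[[1]], groups[[2]])$p.value,
                    error = function(e) 0)
    gates$f_test_p <- f_p
    parametric <- all(shapiro_p > alpha) && f_p > alpha
    res <- if (parametric) {
      t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    } else {
      suppressWarnings(wilcox.test(groups[[1]], groups[[2]]))
    }
    test <- if (parametric) "unpaired t-test" else "Wilcoxon rank-sum test"
  } else if (design == "paired") {
    stopifnot(length(groups) == 2,
              length(groups[[1]]) == length(groups[[2]]))
    d <- groups[[1]] - groups[[2]]
    sh_d <- if (length(unique(d)) < 3) 0 else shapiro.test(d)$p.value
    gates$shapiro_diff_p <- sh_d
    parametric <- sh_d > alpha
    res <- if (parametric) {
      t.test(groups[[1]], groups[[2]], paired = TRUE)
    } else {
      suppressWarnings(wilcox.test(groups[[1]], groups[[2]], paired = TRUE))
    }
    test <- if (parametric) "paired t-test" else "paired Wilcoxon test"
  } else if (design == "multigroup") {
    res <- kruskal.test(groups)
    test <- "Kruskal-Wallis test"
  } else {
    mat <- do.call(cbind, groups)
    res <- friedman.test(mat)
    test <- "Friedman test"
  }
  report <- list(test = test, statistic = unname(res$statistic),
                 p_value = res$p.value, gates = gates, design = design)
  if (design %in% c("multigroup", "repeated")) {
    paired <- design == "repeated"
    combs <- combn(length(groups), 2)
    raw <- apply(combs, 2, function(ij) {
      suppressWarnings(
        wilcox.test(groups[[ij[1]]], groups[[ij[2]]],
                    paired = paired)$p.value)
    })
    report$pairwise <- data.frame(
      group1 = combs[1, ], group2 = combs[2, ], p_value = raw,
      p_adjusted = p.adjust(raw, method = "BH"))
  }
  class(report) <- "stat_report"
  report
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise Wilcoxon (Benjamini-Hochberg adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
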