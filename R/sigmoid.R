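# Four-parameter logistic distance-tuning fits.

#' Build a distance tuning curve from per-trial peak responses
#'
#' Groups per-fly, per-trial normalized peaks by stimulus distance and
#' summarizes with the mean and SEM across biological replicates (SEM over
#' flies of the per-fly trial means).
#'
#' @param peaks data.frame with columns `fly`, `trial`, `distance`,
#'   `response`.
#' @param cell_type optional label stored with the curve.
#' @return object of class `tuning_curve`: `data` (per-trial), `fly_means`
#'   (per fly x distance) and `summary` (per distance mean/sem/n).
#' @export
build_distance_tuning <- function(peaks, cell_type = NA_character_) {
  need <- c("fly", "trial", "distance", "response")
  if (!all(need %in% names(peaks))) {
    stop("peaks must have columns fly, trial, distance, response")
  }
  if (any(!is.finite(peaks$distance))) stop("missing distance annotation")
  fly_means <- aggregate(response ~ fly + distance, data = peaks, FUN = mean)
  summ <- do.call(rbind, lapply(split(fly_means, fly_means$distance),
    function(g) data.frame(
      distance = g$distance[1], mean = mean(g$response),
      sem = if (nrow(g) > 1) sd(g$response) / sqrt(nrow(g)) else 0,
      n_flies = nrow(g))))
  summ <- summ[order(summ$distance), ]
  rownames(summ) <- NULL
  structure(list(data = peaks, fly_means = fly_means, summary = summ,
                 cell_type = cell_type),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("distance tuning curve%s: %d distances, %d flies\n",
              if (is.na(x$cell_type)) "" else paste0(" (", x$cell_type, ")"),
              nrow(x$summary), length(unique(x$data$fly))))
  print(x$summary)
  invisible(x)
}

#' Fit a four-parameter logistic distance-tuning curve
#'
#' Nonlinear least squares fit of
#' `response = base + (top - base) / (1 + exp((d - ed50) / slope))`,
#' self-started by the logistic model. `ed50` is the distance of
#' half-maximal response and the residual standard error is
#' `sqrt(RSS / (n - 4))`.
#'
#' @param curve a [build_distance_tuning()] object, or a data.frame with
#'   columns `distance` and `response`.
#' @return object of class `sigmoid_fit`.
#' @export
fit_sigmoid <- function(curve) {
  df <- if (inherits(curve, "tuning_curve")) curve$data else curve
  stopifnot(all(c("distance", "response") %in% names(df)))
  df <- df[is.finite(df$distance) & is.finite(df$response), ]
  if (length(unique(df$distance)) < 4) {
    stop("need at least 4 distinct distances")
  }
  if (diff(range(df$response)) < .Machine$double.eps^0.5) {
    stop("degenerate flat data")
  }
  # SSfpl parameterization: A + (B - A) / (1 + exp((xmid - x)/scal)) with
  # A the response at small x; maps to (top, base, ed50, slope).
  fit <- tryCatch(
    nls(response ~ SSfpl(distance, top, base, ed50, slope), data = df,
        control = nls.control(maxiter = 200, scaleOffset = 1,
                              minFactor = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    start <- sigmoid_start(df)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ base + (top - base) / (1 + exp((distance - ed50) / slope)),
        data = df, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      stop("sigmoid fit did not converge: ", conditionMessage(fit))
    }
  }
  cf <- coef(fit)
  rss <- sum(residuals(fit)^2)
  n <- nrow(df)
  out <- structure(list(
    top = unname(cf["top"]), base = unname(cf["base"]),
    ed50 = unname(cf["ed50"]), slope = unname(cf["slope"]),
    rse = sqrt(rss / (n - 4)), n_obs = n, fit = fit,
    converged = TRUE), class = "sigmoid_fit")
  rng <- range(df$distance)
  if (out$ed50 < rng[1] || out$ed50 > rng[2]) {
    warning("fitted ED50 lies outside the range of measured distances")
  }
  out
}

# crude self-start used by the fallback optimizer
sigmoid_start <- function(df) {
  top <- max(df$response)
  base <- min(df$response)
  mid <- base + (top - base) / 2
  agg <- aggregate(response ~ distance, data = df, FUN = mean)
  agg <- agg[order(agg$distance), ]
  below <- which(agg$response <= mid)
  ed50 <- if (length(below)) agg$distance[below[1]] else median(agg$distance)
  list(top = top, base = base, ed50 = max(ed50, 1e-3),
       slope = max(diff(range(df$distance)) / 10, 1e-3))
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(top = object$top, base = object$base, ed50 = object$ed50,
    slope = object$slope)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("four-parameter logistic distance tuning fit\n")
  cat(sprintf("  top %.4g, base %.4g, ED50 %.4g mm, slope %.4g mm\n",
              x$top, x$base, x$ed50, x$slope))
  cat(sprintf("  RSE %.4g on %d observations\n", x$rse, x$n_obs))
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object$fit))
  d <- if (is.data.frame(newdata)) newdata$distance else newdata
  object$base + (object$top - object$base) /
    (1 + exp((d - object$ed50) / object$slope))
}

#' @export
summary.sigmoid_fit <- function(object, ...) {
  list(coefficients = coef(object), rse = object$rse, n_obs = object$n_obs,
       nls_summary = summary(object$fit))
}
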