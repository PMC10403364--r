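# Bivariate linear decoding of stimulus position from bilateral responses.

#' Fit a bivariate linear position decoder
#'
#' Least-squares model predicting the stimulus Cartesian coordinates from
#' the difference and the sum of right and left responses:
#' `x ~ (R - L) + (R + L)` and likewise for `y`.
#'
#' @param responses data.frame with columns `left`, `right`, `x`, `y`
#'   (single-trial responses and true positions).
#' @return an object of class `bilateral_decoder` with a 3 x 2 coefficient
#'   matrix (intercept, diff, sum) for outputs x and y.
#' @export
fit_decoder <- function(responses) {
  stopifnot(all(c("left", "right", "x", "y") %in% names(responses)))
  df <- data.frame(dif = responses$right - responses$left,
                   tot = responses$right + responses$left,
                   x = responses$x, y = responses$y)
  if (nrow(unique(df[, c("x", "y")])) < 3) {
    stop("need at least 3 distinct training positions")
  }
  X <- cbind(1, df$dif, df$tot)
  if (qr(X)$rank < 3) stop("rank-deficient predictors (diff, sum)")
  fit <- lm(cbind(x, y) ~ dif + tot, data = df)
  cf <- coef(fit)
  rownames(cf) <- c("intercept", "diff", "sum")
  structure(list(coefficients = cf, n_obs = nrow(df)),
            class = "bilateral_decoder")
}

#' @export
coef.bilateral_decoder <- function(object, ...) object$coefficients

#' @export
print.bilateral_decoder <- function(x, ...) {
  cat("bivariate linear decoder: (x, y) ~ (R - L) + (R + L)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.bilateral_decoder <- function(object, newdata, ...) {
  dif <- newdata$right - newdata$left
  tot <- newdata$right + newdata$left
  X <- cbind(1, dif, tot)
  pred <- X %*% object$coefficients
  data.frame(x = pred[, 1], y = pred[, 2])
}

#' Decode stimulus positions from bilateral responses
#'
#' Predicts (x, y) per trial, converts to a predicted angle
#' `atan2(y_hat, x_hat)` in degrees, and, when true positions are present,
#' reports wrapped angular errors (degrees, in [0, 180]) and Euclidean
#' position errors (mm).
#'
#' @param model a fitted [fit_decoder()] model.
#' @param responses data.frame with `left`, `right` and optionally true
#'   `x`, `y`.
#' @return an object of class `decoding_result`: per-trial predictions and
#'   errors plus summary statistics.
#' @export
decode <- function(model, responses) {
  stopifnot(inherits(model, "bilateral_decoder"))
  pred <- predict(model, responses)
  out <- data.frame(x_hat = pred$x, y_hat = pred$y,
                    angle_hat = wrap_angle(rad2deg(atan2(pred$y, pred$x))))
  summary <- list()
  if (all(c("x", "y") %in% names(responses))) {
    true_angle <- wrap_angle(rad2deg(atan2(responses$y, responses$x)))
    out$angle_true <- true_angle
    out$angle_error <- angle_diff(out$angle_hat, true_angle)
    out$position_error <- sqrt((pred$x - responses$x)^2 +
                               (pred$y - responses$y)^2)
    summary <- list(median_angle_error = median(out$angle_error),
                    mean_angle_error = mean(out$angle_error),
                    median_position_error = median(out$position_error),
                    mean_position_error = mean(out$position_error))
  }
  structure(list(predictions = out, summary = summary),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding result: %d trials\n", nrow(x$predictions)))
  if (length(x$summary)) {
    cat(sprintf("  angular error: median %.2f deg, mean %.2f deg\n",
                x$summary$median_angle_error, x$summary$mean_angle_error))
    cat(sprintf("  position error: median %.3f mm, mean %.3f mm\n",
                x$summary$median_position_error,
                x$summary$mean_position_error))
  }
  invisible(x)
}

#' Cross-validated or in-sample decoder evaluation
#'
#' @param responses data.frame with `left`, `right`, `x`, `y` and, for the
#'   cross-validated modes, `fly` and `trial` columns.
#' @param method `"loo_fly"` (leave one fly out, default), `"loo_trial"`
#'   (leave one trial index out) or `"insample"` (train and evaluate on the
#'   same data).
#' @return a `decoding_result` over all held-out trials.
#' @export
evaluate_decoder <- function(responses,
                             method = c("loo_fly", "loo_trial", "insample")) {
  method <- match.arg(method)
  if (method == "insample") {
    model <- fit_decoder(responses)
    return(decode(model, responses))
  }
  unit <- if (method == "loo_fly") responses$fly else responses$trial
  if (is.null(unit)) stop("cross-validation needs fly/trial columns")
  preds <- lapply(unique(unit), function(u) {
    train <- responses[unit != u, , drop = FALSE]
    test <- responses[unit == u, , drop = FALSE]
    model <- fit_decoder(train)
    decode(model, test)$predictions
  })
  out <- do.call(rbind, preds)
  summary <- list(median_angle_error = median(out$angle_error),
                  mean_angle_error = mean(out$angle_error),
                  median_position_error = median(out$position_error),
                  mean_position_error = mean(out$position_error))
  structure(list(predictions = out, summary = summary),
            class = "decoding_result")
}
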