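#' @export
print.prw_fit <- function(x, digits = 4, ...) {
  cat("Persistent random walk fit (", x$n_lags_used, " lags, weighting: ",
      x$weighting, ")\n", sep = "")
  cat("  S  = ", format(x$coefficients[["S"]], digits = digits),
      " um/min   P = ", format(x$coefficients[["P"]], digits = digits),
      " min\n", sep = "")
  cat("  mu = ", format(x$mu, digits = digits), " um^2/min\n", sep = "")
  if (!x$converged) cat("  WARNING: solver did not converge\n")
  if (isTRUE(x$degenerate)) cat("  NOTE: ", x$degenerate_reason, "\n",
                                sep = "")
  invisible(x)
}

#' @export
coef.prw_fit <- function(object, ...) object$coefficients

#' @export
vcov.prw_fit <- function(object, ...) {
  se <- object$standard_errors
  # only marginal variances are retained from the local quadratic model
  diag(se^2, nrow = 2, ncol = 2) |> `dimnames<-`(list(names(se), names(se)))
}

#' Summarize a persistent-random-walk fit
#'
#' @param object A `prw_fit` object.
#' @param ... Unused.
#' @return An object of class `summary.prw_fit`: the coefficient table
#'   (estimate, standard error), mu, fit diagnostics.
#' @export
summary.prw_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$standard_errors)
  structure(list(coefficients = tab, mu = object$mu,
                 residual_sum_squares = object$residual_sum_squares,
                 n_lags_used = object$n_lags_used,
                 converged = object$converged,
                 degenerate = object$degenerate,
                 degenerate_reason = object$degenerate_reason,
                 weighting = object$weighting),
            class = "summary.prw_fit")
}

#' @export
print.summary.prw_fit <- function(x, digits = 4, ...) {
  cat("Persistent random walk fit\n\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat("\nRandom motility coefficient mu = S^2 P / 2 = ",
      format(x$mu, digits = digits), " um^2/min\n", sep = "")
  cat("Residual sum of squares: ",
      format(x$residual_sum_squares, digits = digits),
      " (", x$n_lags_used, " lags, weighting: ", x$weighting, ")\n",
      sep = "")
  cat("Converged: ", x$converged, "\n", sep = "")
  if (isTRUE(x$degenerate)) cat("Degenerate: ", x$degenerate_reason, "\n",
                                sep = "")
  invisible(x)
}

#' Model MSD at new lag times
#'
#' @param object A `prw_fit`.
#' @param newdata Optional data frame with a `lag_min` column (or a numeric
#'   vector of lags); defaults to the fitted lags.
#' @param ... Unused.
#' @return Numeric vector of model MSD values, um^2.
#' @export
predict.prw_fit <- function(object, newdata = NULL, ...) {
  lags <- if (is.null(newdata)) object$curve$lag_min
          else if (is.numeric(newdata)) newdata
          else newdata$lag_min
  prw_msd(lags, object$coefficients[["S"]], object$coefficients[["P"]])
}

#' @export
residuals.prw_fit <- function(object, ...) {
  object$curve$msd_um2 - predict(object)
}

#' @export
fitted.prw_fit <- function(object, ...) predict(object)

#' Plot an MSD curve with its persistent-random-walk fit
#'
#' Observed MSD points and the fitted Fuerth curve on a dense lag grid.
#'
#' @param x A `prw_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.prw_fit <- function(x, ...) {
  graphics::plot(x$curve$lag_min, x$curve$msd_um2,
                 xlab = "lag time (min)", ylab = expression(MSD ~ (mu * m^2)),
                 pch = 19, ...)
  grid_t <- seq(0, max(x$curve$lag_min), length.out = 200)
  graphics::lines(grid_t, prw_msd(grid_t, x$coefficients[["S"]],
                                  x$coefficients[["P"]]), col = "firebrick")
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "S = %.2f um/min, P = %.2f min, mu = %.1f um^2/min",
    x$coefficients[["S"]], x$coefficients[["P"]], x$mu))
  invisible(x)
}

#' Simulate tracks from a fitted persistent-random-walk model
#'
#' Parametric simulation: generates new track sets from the fitted `S` and
#' `P` at the sampling interval of the fitted curve, via [simulate_prw()].
#'
#' @param object A `prw_fit`.
#' @param nsim Number of track sets to simulate.
#' @param seed Master seed (integer); replicate `i` uses `seed + i - 1`.
#' @param n_cells,n_frames Size of each simulated track set.
#' @param ... Unused.
#' @return A list of `nsim` [track_set()] objects.
#' @export
simulate.prw_fit <- function(object, nsim = 1, seed = 1L, n_cells = 50L,
                             n_frames = 11L, ...) {
  lapply(seq_len(nsim), function(i) {
    simulate_prw(prw_sim_config(
      speed_S = object$coefficients[["S"]],
      persistence_P = object$coefficients[["P"]],
      n_cells = n_cells, n_frames = n_frames,
      frame_interval = object$frame_interval,
      seed = as.integer(seed) + i - 1L,
      group_label = "simulated"))
  })
}
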