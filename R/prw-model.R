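#' Persistent-random-walk (Fuerth) mean-squared displacement
#'
#' Closed-form MSD of a two-dimensional persistent random walk with
#' root-mean-square speed `S` and persistence time `P`:
#' \deqn{\langle D^2(t) \rangle = 2 S^2 P \left[t - P(1 - e^{-t/P})\right].}
#' The curve interpolates ballistic motion (\eqn{S^2 t^2} for \eqn{t \ll P})
#' and diffusion (slope \eqn{2 S^2 P = 4\mu} for \eqn{t \gg P}).
#'
#' A frequently printed variant of this equation,
#' \eqn{2 S^2 [t - P(1 - e^{-t/P})]}, drops the leading factor of `P` and is
#' dimensionally inconsistent (um^2/min rather than um^2); the form used
#' here is the standard 2D Fuerth equation and the unique form consistent
#' with the random motility coefficient \eqn{\mu = S^2 P / 2} (diffusive
#' limit \eqn{4 \mu t}).
#'
#' For very small `t/P` the bracket suffers catastrophic cancellation, so a
#' Taylor expansion is substituted below `t/P < 1e-6`; the value is exactly 0
#' at t = 0.
#'
#' @param t Lag time(s), min; must be >= 0.
#' @param S Root-mean-square speed, um/min (>= 0).
#' @param P Persistence time, min (> 0).
#' @return Model MSD value(s), um^2.
#' @seealso [fit_prw()], [motility_coefficient()]
#' @examples
#' prw_msd(c(0, 1, 5, 30), S = 10, P = 2)
#' @export
prw_msd <- function(t, S, P) {
  if (any(t < 0)) stop("lag time t must be >= 0", call. = FALSE)
  if (!is.numeric(S) || any(S < 0)) stop("S must be >= 0", call. = FALSE)
  if (!is.numeric(P) || any(P <= 0)) stop("P must be > 0", call. = FALSE)
  r <- t / P
  small <- r < 1e-4
  out <- 2 * S^2 * P * (t - P * (1 - exp(-r)))
  # cancellation in the bracket costs ~2*eps/r^2 relative error, the series
  # truncation ~r^3/60; crossing over at r = 1e-4 keeps both below ~1e-8
  out[small] <- (S^2 * t^2 * (1 - r / 3 + r^2 / 12))[small]
  out
}

#' Random motility coefficient
#'
#' The effective diffusion coefficient of persistent-random-walk motion in
#' two dimensions, \eqn{\mu = \frac{1}{2} S^2 P} (the general relation is
#' \eqn{\mu = S^2 P / n_{dim}}). In the diffusive regime the MSD grows as
#' \eqn{4 \mu t}.
#'
#' @inheritParams prw_msd
#' @return mu in um^2/min.
#' @examples
#' motility_coefficient(S = 10, P = 2)  # 100
#' @export
motility_coefficient <- function(S, P) {
  if (!is.numeric(S) || any(S < 0)) stop("S must be >= 0", call. = FALSE)
  if (!is.numeric(P) || any(P <= 0)) stop("P must be > 0", call. = FALSE)
  0.5 * S^2 * P
}

#' Path-length speed of a trajectory
#'
#' The empirical (path-length) cell speed: total length of the polygonal
#' track divided by its duration. This is the direct, model-free counterpart
#' of the fitted root-mean-square speed `S`; the two are reported side by
#' side because back-and-forth motion gives a large path-length speed with
#' near-zero net displacement.
#'
#' @param traj A trajectory (see [trajectory()]).
#' @return Speed, um/min.
#' @export
empirical_speed <- function(traj) {
  validate_trajectory(traj)
  duration <- traj$time_min[nrow(traj)] - traj$time_min[1]
  if (duration <= 0) stop("zero-duration trajectory", call. = FALSE)
  steps <- sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2)
  sum(steps) / duration
}

#' Fit the persistent-random-walk model to an MSD curve
#'
#' Estimates the root-mean-square speed `S` and persistence time `P` by
#' bounded nonlinear least squares on the Fuerth equation (see [prw_msd()]),
#' and derives the random motility coefficient \eqn{\mu = S^2 P / 2}. The
#' lag-0 point is excluded. The objective can be bimodal near the ballistic
#' boundary, so the Levenberg-Marquardt solver is run from three
#' deterministic starts -- \eqn{S_0} from the short-lag ballistic estimate
#' \eqn{\sqrt{msd_1}/t_1} with \eqn{P_0 \in \{\Delta t, T/10, T\}} where `T`
#' is the longest lag -- plus the user-supplied `init` if given; the lowest
#' residual sum of squares wins. `P` is constrained to
#' \eqn{[\Delta t / 10, 10 T]}.
#'
#' The fit is flagged *degenerate* when the fitted persistence falls below
#' the sampling interval (`P < dt`, persistence unresolvable at the frame
#' rate) or is pinned at the upper bound (persistence exceeds the
#' observation window; ballistic-looking data).
#'
#' @param curve An [msd_curve()] (or data frame with columns `lag_min`,
#'   `msd_um2`, optionally `n_intervals`) with at least 3 positive-lag
#'   points.
#' @param weighting `"none"` for ordinary least squares (the default) or
#'   `"interval_count"` to weight each lag by its number of contributing
#'   non-overlapping intervals.
#' @param init Optional named vector/list with starting values `S` and `P`,
#'   added to the deterministic multi-start set.
#' @return An object of class `prw_fit`; see [coef.prw_fit()],
#'   [summary.prw_fit()], [predict.prw_fit()], [plot.prw_fit()],
#'   [simulate.prw_fit()]. Key components: `coefficients` (`S`, `P`), `mu`,
#'   `residual_sum_squares`, `n_lags_used`, `converged`,
#'   `standard_errors`, `degenerate`, `degenerate_reason`.
#' @examples
#' lags <- seq(0.5, 15, by = 0.5)
#' curve <- data.frame(lag_min = lags, msd_um2 = prw_msd(lags, S = 10, P = 2))
#' fit <- fit_prw(curve)
#' coef(fit)
#' @export
fit_prw <- function(curve, weighting = c("none", "interval_count"),
                    init = NULL) {
  weighting <- match.arg(weighting)
  if (!is.data.frame(curve) ||
      !all(c("lag_min", "msd_um2") %in% names(curve))) {
    stop("curve must be a data frame with columns lag_min and msd_um2",
         call. = FALSE)
  }
  d <- as.data.frame(curve)[curve$lag_min > 0, , drop = FALSE]
  d <- d[is.finite(d$msd_um2), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 positive-lag MSD points",
                        call. = FALSE)
  if (all(d$msd_um2 == 0)) {
    stop("degenerate input: all-zero MSD (immotile population)",
         call. = FALSE)
  }
  d <- d[order(d$lag_min), ]
  w <- if (weighting == "interval_count") {
    if (!"n_intervals" %in% names(d)) {
      stop("interval_count weighting needs an n_intervals column",
           call. = FALSE)
    }
    as.numeric(d$n_intervals)
  } else rep(1, nrow(d))

  dt <- d$lag_min[1]
  T_max <- d$lag_min[nrow(d)]
  lower <- c(S = 0, P = dt / 10)
  upper <- c(S = Inf, P = 10 * T_max)

  S0 <- sqrt(max(d$msd_um2[1], .Machine$double.eps)) / d$lag_min[1]
  starts <- list(c(S = S0, P = dt), c(S = S0, P = T_max / 10),
                 c(S = S0, P = T_max))
  if (!is.null(init)) {
    init <- unlist(init)[c("S", "P")]
    if (anyNA(init)) stop("init must provide S and P", call. = FALSE)
    starts <- c(list(init), starts)
  }

  best <- NULL
  best_rss <- Inf
  for (st in starts) {
    st["P"] <- min(max(st["P"], lower["P"]), upper["P"])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        msd_um2 ~ prw_msd(lag_min, S, P), data = d,
        start = as.list(st), lower = lower, upper = upper, weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }

  if (is.null(best)) {
    res <- list(coefficients = c(S = NA_real_, P = NA_real_), mu = NA_real_,
                residual_sum_squares = NA_real_, n_lags_used = nrow(d),
                converged = FALSE, standard_errors = c(S = NA_real_,
                                                       P = NA_real_),
                degenerate = TRUE, degenerate_reason = "no solver run converged",
                weighting = weighting, curve = d, fitted.values = NULL,
                frame_interval = dt, call = match.call())
    class(res) <- "prw_fit"
    return(res)
  }

  est <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) c(S = NA_real_, P = NA_real_))
  names(se) <- names(est)
  degen_reason <- NULL
  if (est[["P"]] < dt) {
    degen_reason <- "fitted persistence below sampling interval"
  } else if (est[["P"]] > 0.99 * upper[["P"]]) {
    degen_reason <- "fitted persistence pinned at upper bound (ballistic; persistence exceeds observation window)"
  }

  res <- list(coefficients = c(S = unname(est[["S"]]), P = unname(est[["P"]])),
              mu = motility_coefficient(est[["S"]], est[["P"]]),
              residual_sum_squares = best_rss,
              n_lags_used = nrow(d),
              converged = isTRUE(best$convInfo$isConv),
              standard_errors = se,
              degenerate = !is.null(degen_reason),
              degenerate_reason = degen_reason %||% NA_character_,
              weighting = weighting,
              curve = d,
              fitted.values = stats::fitted(best),
              frame_interval = dt,
              call = match.call())
  class(res) <- "prw_fit"
  res
}
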