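#' Squared net displacements over non-overlapping intervals
#'
#' Partitions the frame index range of one trajectory into consecutive,
#' disjoint segments of `k` steps anchored at the first frame, and returns
#' the squared net displacement of each segment. The trailing remainder
#' (fewer than `k` steps) is discarded, so a track of `n` frames yields
#' exactly `floor((n - 1) / k)` values. Using disjoint segments keeps the
#' squared displacements uncorrelated for a memoryless walk, unlike the
#' sliding-window estimator.
#'
#' @param traj A trajectory (see [trajectory()]).
#' @param k Lag in frames, `1 <= k <= n_frames - 1`.
#' @return Numeric vector of squared displacements, um^2.
#' @export
squared_displacements <- function(traj, k) {
  validate_trajectory(traj)
  n <- nrow(traj)
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 1 || k > n - 1) {
    stop("lag k must satisfy 1 <= k <= n_frames - 1 (here n_frames = ", n,
         ")", call. = FALSE)
  }
  m <- (n - 1L) %/% k
  starts <- seq(1L, by = k, length.out = m)
  (traj$x_um[starts + k] - traj$x_um[starts])^2 +
    (traj$y_um[starts + k] - traj$y_um[starts])^2
}

#' Mean-squared displacement curve by non-overlapping intervals
#'
#' Computes \eqn{\langle D^2(t) \rangle} at lags \eqn{t = k \Delta t} for
#' `k = 1 .. floor(max_lag_fraction * (n_frames - 1))`, from a single
#' trajectory or a [track_set()]. For a track set the default (`"pooled"`)
#' estimator pools every non-overlapping squared displacement across cells
#' and averages once -- the cumulative population curve; the alternative
#' `"per_cell_mean"` averages per-cell MSD values with equal weight per cell.
#' The lag-0 point (0, 0) is stored for completeness but excluded from model
#' fitting by default. Lags to which no track contributes are omitted.
#'
#' @param tracks A trajectory data frame or a [track_set()].
#' @param max_lag_fraction Fraction of the maximum available lag to report,
#'   in (0, 1]. The default 0.5 guarantees at least two non-overlapping
#'   intervals per contributing cell at every reported lag, limiting
#'   estimator variance at long lags.
#' @param pooling `"pooled"` (cumulative over cells) or `"per_cell_mean"`.
#' @return An object of classes `msd_curve` and `data.frame` with columns
#'   `lag_min`, `msd_um2`, `n_intervals`; attributes `scope` (`"cell"` or
#'   `"group"`), `group`, `frame_interval`, `source_ids`, `pooling`.
#' @export
msd_curve <- function(tracks, max_lag_fraction = 0.5,
                      pooling = c("pooled", "per_cell_mean")) {
  pooling <- match.arg(pooling)
  if (!is.numeric(max_lag_fraction) || max_lag_fraction <= 0 ||
      max_lag_fraction > 1) {
    stop("max_lag_fraction must be in (0, 1]", call. = FALSE)
  }
  if (inherits(tracks, "track_set")) {
    trajs <- tracks$trajectories
    if (length(trajs) == 0) stop("empty track set", call. = FALSE)
    dt <- tracks$frame_interval
    scope <- "group"
    group <- tracks$group_label
  } else {
    validate_trajectory(tracks)
    trajs <- list(cell = tracks)
    dt <- diff(tracks$time_min)[1]
    scope <- "cell"
    group <- NA_character_
  }
  n_frames <- vapply(trajs, nrow, integer(1))
  kmax <- floor(max_lag_fraction * (max(n_frames) - 1))
  if (kmax < 1) stop("no usable lags: tracks too short for max_lag_fraction ",
                     max_lag_fraction, call. = FALSE)
  rows <- lapply(seq_len(kmax), function(k) {
    contrib <- trajs[n_frames - 1L >= k]
    if (length(contrib) == 0) return(NULL)
    sq <- lapply(contrib, squared_displacements, k = k)
    msd <- if (pooling == "pooled" || scope == "cell") {
      mean(unlist(sq, use.names = FALSE))
    } else {
      mean(vapply(sq, mean, numeric(1)))
    }
    data.frame(lag_min = k * dt, msd_um2 = msd,
               n_intervals = length(unlist(sq, use.names = FALSE)))
  })
  curve <- rbind(data.frame(lag_min = 0, msd_um2 = 0,
                            n_intervals = NA_integer_),
                 do.call(rbind, rows))
  rownames(curve) <- NULL
  structure(curve,
            class = c("msd_curve", "data.frame"),
            scope = scope, group = group, frame_interval = dt,
            source_ids = names(trajs), pooling = pooling)
}

#' @export
print.msd_curve <- function(x, ...) {
  cat("MSD curve (", attr(x, "scope"), " scope",
      if (!is.na(attr(x, "group"))) paste0(", group '", attr(x, "group"), "'"),
      "): ", nrow(x) - 1, " positive lags, dt = ",
      attr(x, "frame_interval"), " min\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Per-cell MSD table
#'
#' Computes one MSD curve per cell of a track set and stacks them into a
#' long table, the replicate-level input expected by [msd_anova()]. Lags a
#' short track cannot reach are simply absent from that cell's rows (never
#' recorded as zero). The pooled group curve of [msd_curve()] equals the
#' interval-count-weighted mean of this table at every lag.
#'
#' @inheritParams msd_curve
#' @param trackset A [track_set()].
#' @return Data frame with columns `cell_id`, `lag_min`, `msd_um2`,
#'   `n_intervals`, `group`. Lag-0 rows are not included.
#' @export
per_cell_msd_table <- function(trackset, max_lag_fraction = 0.5) {
  stopifnot(inherits(trackset, "track_set"))
  if (length(trackset$trajectories) == 0) stop("empty track set",
                                               call. = FALSE)
  out <- lapply(names(trackset$trajectories), function(id) {
    cv <- msd_curve(trackset$trajectories[[id]],
                    max_lag_fraction = max_lag_fraction)
    cv <- cv[cv$lag_min > 0, ]
    if (nrow(cv) == 0) return(NULL)
    data.frame(cell_id = id, lag_min = cv$lag_min, msd_um2 = cv$msd_um2,
               n_intervals = cv$n_intervals,
               group = trackset$group_label)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
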