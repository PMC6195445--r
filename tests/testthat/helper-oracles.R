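# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths.

# Closed-form 2D Fuerth MSD, written independently of prw_msd().
furth_oracle <- function(t, S, P) 2 * S^2 * P * (t - P * (1 - exp(-t / P)))

# Brute-force non-overlapping MSD: explicit enumeration of the disjoint
# segments 0 -> k, k -> 2k, ... over the index range.
brute_sq_disp <- function(x, y, k) {
  n <- length(x)
  out <- numeric(0)
  s <- 1
  while (s + k <= n) {
    out <- c(out, (x[s + k] - x[s])^2 + (y[s + k] - y[s])^2)
    s <- s + k
  }
  out
}

random_traj <- function(n_frames, dt = 1.5) {
  trajectory(x = cumsum(stats::rnorm(n_frames)),
             y = cumsum(stats::rnorm(n_frames)),
             frame_interval = dt)
}

make_track_set <- function(trajs, dt = 1.5, group = "g") {
  track_set(trajs, frame_interval = dt, group_label = group)
}

# Exact Fuerth curve sampled as an msd-curve-shaped data frame.
exact_curve <- function(S, P, lags, n_intervals = 100L) {
  data.frame(lag_min = lags, msd_um2 = furth_oracle(lags, S, P),
             n_intervals = n_intervals)
}
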