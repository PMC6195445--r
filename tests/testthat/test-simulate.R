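test_that("simulation configs are validated with the offending field named", {
  expect_error(prw_sim_config(speed_S = -1, persistence_P = 2), "speed_S")
  expect_error(prw_sim_config(speed_S = 1, persistence_P = 0),
               "persistence_P")
  expect_error(prw_sim_config(speed_S = 1, persistence_P = 1, n_frames = 1),
               "n_frames")
  expect_error(prw_sim_config(speed_S = 1, persistence_P = 1,
                              frame_interval = 0), "frame_interval")
  expect_error(prw_sim_config(speed_S = 1, persistence_P = 1,
                              localization_noise_sd = -0.1),
               "localization_noise_sd")
})

test_that("same config and seed give bit-identical tracks", {
  cfg <- prw_sim_config(speed_S = 8, persistence_P = 1.5, n_cells = 10,
                        n_frames = 11, frame_interval = 1.5, seed = 7,
                        localization_noise_sd = 0.3)
  a <- simulate_prw(cfg)
  b <- simulate_prw(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- simulate_prw(prw_sim_config(speed_S = 8, persistence_P = 1.5,
                                   n_cells = 10, n_frames = 11,
                                   frame_interval = 1.5, seed = 8,
                                   localization_noise_sd = 0.3))
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
})

test_that("per-cell streams depend only on cell index, not on n_cells", {
  base <- prw_sim_config(speed_S = 10, persistence_P = 2, n_cells = 3,
                         n_frames = 21, frame_interval = 0.5, seed = 11)
  bigger <- prw_sim_config(speed_S = 10, persistence_P = 2, n_cells = 6,
                           n_frames = 21, frame_interval = 0.5, seed = 11)
  a <- simulate_prw(base)
  b <- simulate_prw(bigger)
  expect_identical(a$trajectories[["cell_2"]], b$trajectories[["cell_2"]])
})

test_that("velocity process is stationary: no variance transient over frames", {
  ts <- simulate_prw(prw_sim_config(speed_S = 10, persistence_P = 2,
                                    n_cells = 400, n_frames = 41,
                                    frame_interval = 0.5, seed = 3))
  # pooled variance of per-step displacement, early frames vs late frames
  steps <- sapply(ts$trajectories, function(tr) {
    sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  })  # 40 x 400
  early <- as.numeric(steps[1:10, ])^2
  late <- as.numeric(steps[31:40, ])^2
  expect_lt(abs(mean(early) / mean(late) - 1), 0.1)
})

test_that("simulated population MSD follows the Fuerth curve within 3 SE", {
  S <- 10; P <- 2; dt <- 0.5; nf <- 200; nc <- 500
  ts <- simulate_prw(prw_sim_config(speed_S = S, persistence_P = P,
                                    n_cells = nc, n_frames = nf,
                                    frame_interval = dt, seed = 1))
  for (k in c(1, 2, 5, 10, 20, 40)) {
    per_cell <- vapply(ts$trajectories, function(tr) {
      mean(brute_sq_disp(tr$x_um, tr$y_um, k))
    }, numeric(1))
    # cells are independent; segments within a cell are not, so the standard
    # error comes from the spread of per-cell means
    se <- stats::sd(per_cell) / sqrt(length(per_cell))
    expect_lt(abs(mean(per_cell) - furth_oracle(k * dt, S, P)), 3 * se)
  }
})

test_that("recorded statistics are invariant to simulation substeps", {
  S <- 10; P <- 2
  msd_lag1 <- function(substeps, seed) {
    ts <- simulate_prw(prw_sim_config(speed_S = S, persistence_P = P,
                                      n_cells = 300, n_frames = 50,
                                      frame_interval = 1.5, seed = seed,
                                      substeps = substeps))
    msd_curve(ts)$msd_um2[2]
  }
  truth <- furth_oracle(1.5, S, P)
  expect_lt(abs(msd_lag1(1, 5) / truth - 1), 0.1)
  expect_lt(abs(msd_lag1(4, 5) / truth - 1), 0.1)
})

test_that("localization noise inflates short-lag MSD by about 4 sigma^2", {
  S <- 5; P <- 2; sig <- 3
  clean <- simulate_prw(prw_sim_config(speed_S = S, persistence_P = P,
                                       n_cells = 600, n_frames = 30,
                                       frame_interval = 1.5, seed = 9))
  noisy <- simulate_prw(prw_sim_config(speed_S = S, persistence_P = P,
                                       n_cells = 600, n_frames = 30,
                                       frame_interval = 1.5, seed = 9,
                                       localization_noise_sd = sig))
  gap <- msd_curve(noisy)$msd_um2[2] - msd_curve(clean)$msd_um2[2]
  # independent noise on both endpoints of both axes: 4 sigma^2 offset
  expect_lt(abs(gap / (4 * sig^2) - 1), 0.15)
})

test_that("transwell count fixtures behave like the implied Poisson law", {
  expect_identical(simulate_transwell_counts(0, 50, seed = 1),
                   rep(0L, 50))
  a <- simulate_transwell_counts(2.9e6, 100, seed = 4)
  expect_identical(a, simulate_transwell_counts(2.9e6, 100, seed = 4))
  expect_lt(abs(mean(simulate_transwell_counts(2.9e6, 4000, seed = 2)) / 290
                - 1), 0.02)
  expect_error(simulate_transwell_counts(-1, 10), "true_concentration")
})

test_that("competitive fixtures recover the programmed enrichment", {
  null_fix <- simulate_competitive_counts(1, 1, 1e5, seed = 3)
  expect_lt(abs(competitive_ratio(null_fix$tissue, null_fix$injected) - 1),
            0.03)
  expect_identical(simulate_competitive_counts(1, 2, 1e4, seed = 6),
                   simulate_competitive_counts(1, 2, 1e4, seed = 6))
  expect_error(simulate_competitive_counts(1, 1, 0), "n_cells_sampled")
})
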