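test_that("Fuerth MSD has the right values, zero point and limits", {
  expect_equal(prw_msd(0, 10, 2), 0)
  expect_equal(prw_msd(3, 0, 2), 0)
  t <- 4
  expect_equal(prw_msd(t, 10, 2), furth_oracle(t, 10, 2))
  expect_error(prw_msd(-1, 10, 2), "t must be")
  expect_error(prw_msd(1, 10, 0), "P must be")
})

test_that("short- and long-lag limits match ballistic and diffusive forms", {
  set.seed(19)
  for (i in 1:10) {
    S <- runif(1, 2, 20)
    P <- runif(1, 0.5, 5)
    t0 <- P / 1000
    expect_lt(abs(prw_msd(t0, S, P) / (S^2 * t0^2) - 1), 0.001)
    # local slope at t = 1000 P approaches 4 mu = 2 S^2 P
    t1 <- 1000 * P
    h <- P / 100
    slope <- (prw_msd(t1 + h, S, P) - prw_msd(t1 - h, S, P)) / (2 * h)
    expect_lt(abs(slope / (2 * S^2 * P) - 1), 0.005)
  }
})

test_that("small-lag series expansion agrees with the direct form at the cutoff", {
  S <- 10; P <- 2
  t <- P * c(0.99e-4, 1.01e-4)   # either side of the series cutoff
  v <- prw_msd(t, S, P)          # series branch, then direct branch
  direct <- 2 * S^2 * P * (t - P * (1 - exp(-t / P)))
  expect_lt(abs(v[1] / direct[1] - 1), 1e-7)
  expect_identical(v[2], direct[2])
  # and both stay on the ballistic asymptote
  expect_lt(max(abs(v / (S^2 * t^2) - 1)), 1e-4)
})

test_that("motility coefficient is mu = S^2 P / 2 with its scaling laws", {
  expect_equal(motility_coefficient(10, 2), 100)
  expect_equal(motility_coefficient(0, 5), 0)
  expect_equal(motility_coefficient(20, 2), 4 * motility_coefficient(10, 2))
  expect_equal(motility_coefficient(10, 4), 2 * motility_coefficient(10, 2))
})

test_that("empirical speed is path length over time, not net displacement", {
  straight <- trajectory(x = 0:10, y = rep(0, 11), frame_interval = 1)
  expect_equal(empirical_speed(straight), 1)
  still <- trajectory(rep(0, 11), rep(0, 11), frame_interval = 1)
  expect_equal(empirical_speed(still), 0)
  zigzag <- trajectory(x = rep(c(0, 1), 6), y = rep(0, 12),
                       frame_interval = 1)
  expect_equal(empirical_speed(zigzag), 1)
})

test_that("fitting a noiseless model curve recovers S and P to 1e-6", {
  curve <- exact_curve(10, 2, seq(0.5, 15, by = 0.5))
  fit <- fit_prw(curve)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_lt(abs(coef(fit)[["S"]] / 10 - 1), 1e-6)
  expect_lt(abs(coef(fit)[["P"]] / 2 - 1), 1e-6)
  expect_equal(fit$mu, 0.5 * coef(fit)[["S"]]^2 * coef(fit)[["P"]])
  expect_lt(fit$residual_sum_squares, 1e-12)
})

test_that("mu identity and inversion hold across the parameter range", {
  set.seed(4)
  for (i in 1:6) {
    S <- runif(1, 2, 20)
    P <- runif(1, 0.5, 5)
    fit <- fit_prw(exact_curve(S, P, seq(0.5, 15, by = 0.5)))
    expect_lt(abs(coef(fit)[["S"]] / S - 1), 1e-6)
    expect_lt(abs(coef(fit)[["P"]] / P - 1), 1e-6)
    expect_identical(fit$mu,
                     motility_coefficient(coef(fit)[["S"]],
                                          coef(fit)[["P"]]))
  }
})

test_that("a ballistic curve pins P at the upper bound and is flagged", {
  lags <- seq(1.5, 15, by = 1.5)
  fit <- fit_prw(data.frame(lag_min = lags, msd_um2 = 100 * lags^2))
  expect_true(fit$degenerate)
  expect_match(fit$degenerate_reason, "upper bound")
  expect_gt(coef(fit)[["P"]], 0.99 * 10 * max(lags))
})

test_that("degenerate inputs raise informative errors", {
  lags <- c(1.5, 3, 4.5)
  expect_error(fit_prw(data.frame(lag_min = lags, msd_um2 = c(0, 0, 0))),
               "immotile")
  expect_error(fit_prw(data.frame(lag_min = c(1, 2), msd_um2 = c(1, 2))),
               "at least 3")
})

test_that("changing the lag unit rescales S and P by exactly the unit factor", {
  lags_min <- seq(0.5, 15, by = 0.5)
  curve_min <- exact_curve(10, 2, lags_min)
  curve_sec <- data.frame(lag_min = lags_min * 60,
                          msd_um2 = curve_min$msd_um2, n_intervals = 100L)
  f_min <- fit_prw(curve_min)
  f_sec <- fit_prw(curve_sec)
  expect_lt(abs(coef(f_sec)[["P"]] / (60 * coef(f_min)[["P"]]) - 1), 1e-6)
  expect_lt(abs(coef(f_sec)[["S"]] * 60 / coef(f_min)[["S"]] - 1), 1e-6)
})

test_that("interval-count weighting and user starts are honoured", {
  curve <- exact_curve(6, 1.5, seq(1.5, 12, by = 1.5),
                       n_intervals = c(8, 4, 2, 2, 1, 1, 1, 1))
  fw <- fit_prw(curve, weighting = "interval_count")
  expect_lt(abs(coef(fw)[["S"]] / 6 - 1), 1e-6)
  fi <- fit_prw(curve, init = c(S = 5, P = 1))
  expect_lt(abs(coef(fi)[["P"]] / 1.5 - 1), 1e-6)
  expect_error(fit_prw(curve[, 1:2], weighting = "interval_count"),
               "n_intervals")
})

test_that("prw_fit methods expose the model coherently", {
  curve <- exact_curve(10, 2, seq(0.5, 15, by = 0.5))
  fit <- fit_prw(curve)
  expect_named(coef(fit), c("S", "P"))
  expect_equal(predict(fit, 0), 0)
  expect_equal(predict(fit, c(1, 5)),
               prw_msd(c(1, 5), coef(fit)[["S"]], coef(fit)[["P"]]))
  expect_lt(max(abs(residuals(fit))), 1e-6)
  expect_output(print(fit), "mu")
  expect_output(print(summary(fit)), "Std. Error")
  sims <- simulate(fit, nsim = 2, seed = 3, n_cells = 4, n_frames = 6)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "track_set")
  expect_identical(sims[[1]]$frame_interval, 0.5)
  v <- vcov(fit)
  expect_identical(dimnames(v), list(c("S", "P"), c("S", "P")))
})

test_that("simulation-based recovery: fitted mu tracks the truth direction", {
  # two groups whose true mu differ 10-fold must order correctly
  fit_group <- function(S, P, seed) {
    ts <- simulate_prw(prw_sim_config(speed_S = S, persistence_P = P,
                                      n_cells = 50, n_frames = 10,
                                      frame_interval = 1.5, seed = seed))
    fit_prw(msd_curve(ts))$mu
  }
  expect_gt(fit_group(12, 2.5, seed = 2), fit_group(6, 1, seed = 1))
})
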