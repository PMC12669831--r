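# The synthetic-data generator: burst trains, fascicle kinematics,
# EMG synthesis, ground-truth force, and the full dataset grid.

test_that("activation bursts: determinism, support, peak value", {
  a <- generate_activation(3, 0.5, duty = 0.4, fs = 1000, jitter = 0, seed = 1)
  expect_length(a, 1500)
  expect_equal(max(a), 1.0)
  expect_true(all(a >= 0 & a <= 1))
  # three identical bursts
  s1 <- a[1:500]; s2 <- a[501:1000]; s3 <- a[1001:1500]
  expect_identical(s1, s2)
  expect_identical(s2, s3)
  # burst support: odd raised-cosine support of 201 samples with zero
  # endpoints -> 199 strictly positive samples per stride
  expect_equal(sum(s1 > 0), 199)
  # same seed -> identical; different seed -> different (with jitter)
  b1 <- generate_activation(5, 0.5, jitter = 0.2, seed = 42)
  b2 <- generate_activation(5, 0.5, jitter = 0.2, seed = 42)
  b3 <- generate_activation(5, 0.5, jitter = 0.2, seed = 43)
  expect_identical(b1, b2)
  expect_false(identical(b1, b3))
  expect_error(generate_activation(3, 0.5, duty = 1.2), "duty")
  expect_error(generate_activation(3, -1), "positive")
})

test_that("fascicle trajectories: bounds, zero-amplitude, analytic derivative", {
  f0 <- generate_fascicle(4, 0.5, fs = 1000, amp = 0, mean_l = 1.1, seed = 1)
  expect_true(all(f0$lce == 1.1))
  expect_lt(max(abs(f0$vce)), 1e-9)
  f1 <- generate_fascicle(6, 0.8, fs = 1000, amp = 0.06, mean_l = 1,
                          jitter = 0.2, seed = 5)
  expect_true(all(f1$lce >= 1 - 0.06 - 1e-12 & f1$lce <= 1 + 0.06 + 1e-12))
  # pure sinusoid at 1 Hz: velocity amplitude ~ amp * 2*pi within 2%
  f2 <- generate_fascicle(4, 1.0, fs = 1000, amp = 0.05, mean_l = 1,
                          jitter = 0, seed = 1, phase = 0)
  core <- f2$vce[500:3500]
  expect_equal(max(abs(core)), 0.05 * 2 * pi, tolerance = 0.02)
  expect_error(generate_fascicle(3, 0.5, amp = 1.2, mean_l = 1), "amp")
})

test_that("generated velocity integrates back to the length trajectory", {
  f <- generate_fascicle(8, 0.5, fs = 500, amp = 0.08, jitter = 0.15, seed = 9)
  dt <- 1 / 500
  n <- length(f$lce)
  # cumulative trapezoid of vce
  rec <- f$lce[1] + c(0, cumsum((f$vce[-1] + f$vce[-n]) / 2 * dt))
  core <- 100:(n - 100)
  rel_rms <- sqrt(mean((rec[core] - f$lce[core])^2)) /
    sqrt(mean((f$lce[core] - mean(f$lce[core]))^2))
  expect_lt(rel_rms, 0.01)
})

test_that("raw EMG synthesis: zero activation, zero mean, round trip", {
  fs <- 1000
  a <- generate_activation(5, 0.7, duty = 0.4, fs = fs, jitter = 0.1, seed = 2)
  expect_true(all(generate_raw_emg(rep(0, 3000), fs, noise_sd = 0, seed = 1) == 0))
  emg <- generate_raw_emg(a, fs = fs, noise_sd = 0, seed = 3)
  expect_lt(abs(mean(emg)), 0.01 * sd(emg))
  env <- process_emg(emg, fs)
  act <- finalize_activation(env, compute_activation_scale(env, 0.1), fs)
  expect_gt(cor(act, a), 0.95)
  expect_error(generate_raw_emg(a, fs, carrier_band = c(10, 400)), "carrier")
  expect_error(generate_raw_emg(a, fs, carrier_band = c(100, 600)), "carrier")
})

test_that("force synthesis reduces to the Hill model and adds history", {
  p <- hill_params(0.12, 6.5, 0.22, 1.5, 4, 0.95)
  set.seed(11)
  n <- 800; fs <- 500
  a <- runif(n, 0, 1); l <- 1 + 0.1 * sin(seq(0, 20, length.out = n))
  v <- velocity_from_length(l, fs)
  f0 <- synthesize_force(a, l, v, p, 20, history_gain = 0, noise_sd_force = 0)
  expect_equal(f0, hill_force(a, l, v, p, 20), tolerance = 1e-12)
  # zero activation below PEE slack -> zero force
  fz <- synthesize_force(rep(0, n), rep(0.9, n), rep(0, n), p, 20)
  expect_true(all(fz == 0))
  # identical (a, l, v) points with different stretch history give
  # different force when history_gain > 0
  a2 <- c(rep(0.5, 400), rep(0.5, 400))
  l2 <- c(rep(1, 400), 1 + 0.1 * sin(pi * seq(0, 1, length.out = 400)))
  l2[800] <- 1
  v2 <- rep(0, 800); v2[401:799] <- (l2[402:800] - l2[400:798]) * fs / 2
  v2[800] <- 0
  fh <- synthesize_force(a2, l2, v2, p, 20, history_gain = 0.3, fs = fs)
  # samples 400 and 800: same (a, l, v) = (0.5, 1, 0), different history
  expect_equal(a2[400], a2[800]); expect_equal(l2[400], l2[800])
  expect_equal(v2[400], v2[800])
  expect_gt(abs(fh[800] - fh[400]), 1e-3)
  expect_error(synthesize_force(a[1:10], l, v, p, 20), "equal length")
})

test_that("dataset grid, determinism and obstacle perturbations", {
  cfg <- synthetic_config(n_birds = 2, muscles = c("LG", "DF"),
                          speeds = c(1.8, 3.8, 4.5), obstacle_heights = 0,
                          fs = 250, n_strides = 4, seed = 7)
  ds <- generate_dataset(cfg)
  expect_length(ds, 2 * 2 * 3 * 1)
  ds2 <- generate_dataset(cfg)
  expect_identical(lapply(ds, function(tr) tr$data),
                   lapply(ds2, function(tr) tr$data))
  meta <- trial_meta(ds)
  expect_true(all(c("bird_id", "muscle", "speed", "f_max") %in% names(meta)))
  # invariants on every trial
  for (tr in ds) {
    d <- tr$data
    expect_true(all(diff(d$t) > 0))
    expect_equal(diff(range(diff(d$t))), 0, tolerance = 1e-12)
    expect_true(all(d$lce > 0))
    expect_true(all(is.finite(as.matrix(d[-1]))))
    expect_true(all(d$force >= 0))
  }
  # obstacle trials have perturbed strides: larger activation peaks
  cfg_o <- synthetic_config(n_birds = 1, muscles = "LG", speeds = 3.8,
                            obstacle_heights = c(0, 7), fs = 250,
                            n_strides = 10, seed = 7)
  ds_o <- generate_dataset(cfg_o)
  lev <- filter_trials(ds_o, obstacle = 0)[[1]]
  obs <- filter_trials(ds_o, obstacle = 7)[[1]]
  expect_gt(max(obs$data$activation), 1.15 * max(lev$data$activation))
  expect_gt(max(obs$data$lce), max(lev$data$lce))
})

test_that("activation scale errors divide the recorded channel only", {
  cfg1 <- synthetic_config(n_birds = 1, muscles = c("LG", "DF"), speeds = 1.8,
                           obstacle_heights = 0, fs = 250, n_strides = 4,
                           activation_scale_error = c(LG = 1, DF = 1),
                           noise_sd_force = 0, noise_sd_emg = 0, seed = 3)
  cfg2 <- synthetic_config(n_birds = 1, muscles = c("LG", "DF"), speeds = 1.8,
                           obstacle_heights = 0, fs = 250, n_strides = 4,
                           activation_scale_error = c(LG = 1, DF = 1.3),
                           noise_sd_force = 0, noise_sd_emg = 0, seed = 3)
  d1 <- generate_dataset(cfg1); d2 <- generate_dataset(cfg2)
  df1 <- filter_trials(d1, muscle = "DF")[[1]]
  df2 <- filter_trials(d2, muscle = "DF")[[1]]
  expect_equal(df1$data$activation, df2$data$activation * 1.3)
  expect_identical(df1$data$force, df2$data$force)  # force untouched
  lg1 <- filter_trials(d1, muscle = "LG")[[1]]
  lg2 <- filter_trials(d2, muscle = "LG")[[1]]
  expect_identical(lg1$data$activation, lg2$data$activation)
})

test_that("dataset serialization round-trips through CSV + JSON manifest", {
  cfg <- synthetic_config(n_birds = 1, muscles = "LG", speeds = 1.8,
                          obstacle_heights = 0, fs = 250, n_strides = 3,
                          seed = 2)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_length(back, length(ds))
  expect_equal(back[[1]]$data, ds[[1]]$data, tolerance = 1e-12)
  expect_equal(back[[1]]$meta$f_max, ds[[1]]$meta$f_max)
})
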