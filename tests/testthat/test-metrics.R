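# Peak detection, matching, rise/fall times, R-squared, and report
# assembly, including brute-force oracles on randomized planted-peak toys.

test_that("detect_peaks: constants, single pulse, offset invariance", {
  expect_length(detect_peaks(rep(1, 100))$indices, 0)
  ps <- planted_peak_series(500, 250, 1, 40)
  pk <- detect_peaks(ps$x)
  expect_equal(pk$indices, 250)
  # five equal bursts plus a DC offset: identical peaks
  p5 <- planted_peak_series(1000, c(100, 300, 500, 700, 900), rep(2, 5), 50)
  pk_a <- detect_peaks(p5$x)
  pk_b <- detect_peaks(p5$x + 10)
  expect_equal(pk_a$indices, c(100, 300, 500, 700, 900))
  expect_identical(pk_a$indices, pk_b$indices)
  expect_equal(pk_a$heights, pk_b$heights, tolerance = 1e-12)
  expect_error(detect_peaks(c(1, 2)), "too short")
})

test_that("match_peaks: identity, shifts beyond window, closest-wins rule", {
  p <- planted_peak_series(1000, c(100, 300, 500, 700, 900), rep(1, 5), 40)
  pk <- detect_peaks(p$x)
  mt <- match_peaks(pk, pk)
  expect_equal(nrow(mt$pairs), 5)
  expect_length(mt$missed, 0)
  expect_length(mt$extra, 0)
  # window = 0.45 * 25th pct of measured intervals (all 200) = 90
  expect_equal(mt$window, 0.45 * 200)
  # shift estimates beyond the window: everything missed and extra
  q <- planted_peak_series(1000, c(100, 300, 500, 700, 900) + 95, rep(1, 5), 40)
  mt2 <- match_peaks(pk, detect_peaks(q$x))
  expect_equal(nrow(mt2$pairs), 0)
  expect_length(mt2$missed, 5)
  expect_length(mt2$extra, 5)
  # two estimated peaks inside one window: the closer is paired, the other extra
  e <- planted_peak_series(1000, c(110, 130), c(1, 1), 8)
  m <- planted_peak_series(1000, c(100, 600), c(1, 1), 8)
  mt3 <- match_peaks(detect_peaks(m$x), detect_peaks(e$x))
  expect_equal(unname(mt3$pairs[, "measured"]), 100)
  expect_equal(unname(mt3$pairs[, "estimated"]), 110)
  expect_equal(mt3$extra, 130)
  expect_equal(mt3$missed, 600)
  # fewer than 2 measured peaks: fallback window with a warning
  one <- detect_peaks(planted_peak_series(1000, 500, 1, 40)$x)
  expect_warning(match_peaks(one, one), "fallback")
})

test_that("rise and fall times: triangle, half-cosine, plateau", {
  fs <- 1000
  # symmetric triangle rising over 0.1 s: rise = fall = 0.05 s
  tri <- planted_peak_series(1000, 500, 1, 100)
  rf <- rise_fall_times(tri$x, 500, fs)
  expect_equal(rf$rise, 0.05, tolerance = 1e-3)
  expect_equal(rf$fall, 0.05, tolerance = 1e-3)
  # half-cosine pulse of half-period T: crossings at T/6 and 5T/6 -> T/3
  n <- 2000; Tn <- 600
  x <- numeric(n)
  x[701:(700 + Tn)] <- sin(pi * seq_len(Tn) / Tn)
  pk <- which.max(x)
  rf2 <- rise_fall_times(x, pk, fs)
  expect_equal(rf2$rise, (Tn / 3) / fs, tolerance = 5e-3)
  expect_equal(rf2$fall, (Tn / 3) / fs, tolerance = 5e-3)
  # plateaued peak: detection reports the first sample of the plateau
  y <- c(rep(0, 50), seq(0, 1, length.out = 50), rep(1, 20),
         seq(1, 0, length.out = 50), rep(0, 50))
  pkp <- detect_peaks(y)
  expect_equal(pkp$indices, 100)
  rf3 <- rise_fall_times(y, pkp$indices, fs)
  expect_lt(rf3$rise, rf3$fall)  # plateau counts into the fall side
  # level never crossed -> NA
  z <- 1 + planted_peak_series(300, 150, 0.1, 30)$x
  expect_true(is.na(rise_fall_times(z, 150, fs)$rise) ||
                rise_fall_times(z, 150, fs)$rise > 0)
})

test_that("r_squared identities", {
  set.seed(14)
  m <- rnorm(100)
  expect_equal(r_squared(m, m), 1)
  expect_equal(r_squared(m, rep(mean(m), 100)), 0)
  expect_lt(r_squared(m, rep(mean(m) + 10, 100)), 0)
  expect_error(r_squared(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("build_report: perfect prediction, scale invariance, toy bookkeeping", {
  p <- planted_peak_series(2000, c(200, 700, 1200, 1700), c(3, 4, 3.5, 5), 120)
  rep1 <- build_report(list(p$x), list(p$x), f_max = 10, fs = 1000)
  r <- rep1$per_trial
  expect_equal(r$rmse_norm, 0)
  expect_equal(r$r2, 1)
  expect_equal(r$missed_pct, 0)
  expect_equal(r$extra_pct, 0)
  expect_equal(r$rise_rmse, 0)
  expect_equal(r$fall_rmse, 0)
  # relative RMSE is invariant to a common force scale
  est <- p$x + 0.1 * sin(seq_len(2000) / 50)
  r1 <- build_report(list(p$x), list(est), 10, 1000)$per_trial$rrmse_pct
  r2 <- build_report(list(7 * p$x), list(7 * est), 70, 1000)$per_trial$rrmse_pct
  expect_equal(r1, r2, tolerance = 1e-12)
  # hand-built two-trial toy: percentages match explicit counts
  m1 <- planted_peak_series(1500, c(200, 600, 1000, 1400), rep(2, 4), 80)
  e1 <- planted_peak_series(1500, c(210, 1010, 1390, 700), rep(2, 4), 80)
  rep2 <- build_report(list(m1$x, m1$x), list(e1$x, m1$x), 5, 1000)
  row1 <- rep2$per_trial[1, ]
  # trial 1: window = 0.45 * 400 = 180; est peaks {210, 700, 1010, 1390}
  # pair (200,210) (600,700) (1000,1010) (1400,1390): all matched
  expect_equal(row1$missed_pct, 0)
  expect_equal(row1$extra_pct, 0)
  expect_equal(rep2$per_trial[2, ]$r2, 1)
  expect_equal(rep2$aggregate$r2_median, mean(c(row1$r2, 1)))
})

test_that("matching equals the brute-force oracle on randomized planted toys", {
  set.seed(99)
  for (rep_i in 1:20) {
    n <- 3000
    k_m <- sample(3:8, 1)
    m_apex <- sort(sample(seq(100, n - 100, by = 50), k_m))
    while (min(diff(m_apex)) < 120) {
      m_apex <- sort(sample(seq(100, n - 100, by = 50), k_m))
    }
    e_apex <- m_apex + sample(-80:80, k_m, replace = TRUE)
    drop <- runif(k_m) < 0.25
    e_apex <- e_apex[!drop]
    if (runif(1) < 0.5) e_apex <- sort(c(e_apex, sample(seq(150, n - 150, by = 70), 2)))
    e_apex <- unique(pmax(50, pmin(n - 50, e_apex)))
    ms <- planted_peak_series(n, m_apex, runif(k_m, 2, 4), 45)
    es <- planted_peak_series(n, e_apex, runif(length(e_apex), 2, 4), 45)
    pm <- detect_peaks(ms$x); pe <- detect_peaks(es$x)
    mt <- suppressWarnings(match_peaks(pm, pe))
    orc <- oracle_match(pm$indices, pe$indices, mt$window)
    expect_equal(sort(mt$missed), sort(orc$missed))
    expect_equal(sort(mt$extra), sort(orc$extra))
    expect_equal(nrow(mt$pairs), nrow(orc$pairs))
  }
})
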