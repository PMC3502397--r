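scan_threshold <- function(amps, dur, target) {
  ua <- sort(unique(amps))
  devs <- sapply(ua, function(a)
    abs(sum(amps >= a) / dur - target) / target)
  list(threshold = ua[which.min(devs)], dev = min(devs))
}

test_that("bisection threshold equals exhaustive scan on random streams", {
  set.seed(42)
  for (rep in 1:20) {
    ev <- plateau_stream(peak_s = 3600, peak_hz = runif(1, 8, 15), seed = rep)
    amps <- ev$amplitudes[ev$times >= 2700 & ev$times < 4500]
    target <- sample(c(2.5, 5.0, 7.5), 1)
    sel <- select_threshold(ev, target_rate = target, window = c(2700, 4500))
    ref <- scan_threshold(amps, 1800, target)
    expect_equal(sel$threshold, ref$threshold)
    expect_equal(sel$relative_deviation, ref$dev, tolerance = 1e-12)
  }
})

test_that("all four target rates are reached with deviation < 0.7%", {
  mua_rate <- rep(2, 120); mua_rate[46:75] <- 12
  mua <- binned_series(mua_rate * 60, 60)   # counts proportional to rate
  ev <- plateau_stream(peak_s = 3600, peak_hz = 12, seed = 5)
  for (target in c(2.5, 5.0, 7.5, 10.0)) {
    sel <- select_threshold(ev, mua, target)
    expect_lt(sel$relative_deviation, 0.007)
    expect_equal(sel$achieved_rate, target, tolerance = 0.01)
  }
})

test_that("threshold selection is exact for exactly achievable targets", {
  # 18,000 distinct-amplitude events in the window: 10 Hz; half -> exactly 5 Hz
  set.seed(9)
  times <- sort(runif(18000, 0, 1800)); times <- times + seq_along(times) * 1e-9
  amps <- sample(seq_len(18000)) / 100
  ev <- event_stream(times, amps)
  sel <- select_threshold(ev, target_rate = 5, window = c(0, 1800))
  expect_equal(sel$relative_deviation, 0)
  expect_equal(sel$achieved_rate, 5)
  expect_equal(sel$threshold, sort(amps, decreasing = TRUE)[9000])

  # target equal to the full in-window rate: lowest amplitude, deviation 0
  sel_full <- select_threshold(ev, target_rate = 10, window = c(0, 1800))
  expect_equal(sel_full$threshold, min(amps))
  expect_equal(sel_full$relative_deviation, 0)
})

test_that("higher targets give lower thresholds; unreachable targets fail", {
  ev <- plateau_stream(peak_s = 3600, peak_hz = 12, seed = 6)
  th <- sapply(c(2.5, 5.0, 7.5, 10.0), function(tr)
    select_threshold(ev, target_rate = tr, window = c(2700, 4500))$threshold)
  expect_true(all(diff(th) < 0))

  tiny <- event_stream(c(3000, 3100, 3200), c(1, 2, 3))
  expect_error(select_threshold(tiny, target_rate = 2.5,
                                window = c(2700, 4500)),
               "selection failed|exceeds")
})

test_that("thresholded binning is monotone and reproduces the full stream", {
  ev <- plateau_stream(seed = 7)
  full <- bin_thresholded(ev, threshold = min(ev$amplitudes), bin_width = 1,
                          t_end = 7200)
  expect_equal(sum(full$counts), length(ev$times))
  expect_equal(full$bin_width, 1)

  hi <- bin_thresholded(ev, threshold = max(ev$amplitudes) * 1.01,
                        bin_width = 1, t_end = 7200)
  expect_true(all(hi$counts == 0))

  t1 <- quantile(ev$amplitudes, 0.3); t2 <- quantile(ev$amplitudes, 0.7)
  b1 <- bin_thresholded(ev, t1, t_end = 7200)
  b2 <- bin_thresholded(ev, t2, t_end = 7200)
  expect_true(all(b2$counts <= b1$counts))
})
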