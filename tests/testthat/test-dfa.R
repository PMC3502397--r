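test_that("scale grids are log-uniform integer grids within the 4-window cap", {
  g <- build_scale_grid(400, 4, 100, 4)
  expect_true(all(g >= 4 & g <= 100))
  expect_true(all(diff(g) > 0))
  expect_true(4 %in% g && 100 %in% g)
  ratios <- g[-1] / g[-length(g)]
  expect_equal(median(ratios), 10^(1 / 4), tolerance = 0.15)

  expect_error(build_scale_grid(400, 4, 101), "4 non-overlapping")
  expect_equal(as.integer(build_scale_grid(400, 10, 10)), 10L)
})

test_that("constant series has exactly zero fluctuations at every scale", {
  s <- binned_series(rep(5, 400), 10)
  ff <- fluctuation_function(s, build_scale_grid(400, 10, 100))
  expect_true(all(abs(ff$F) < 1e-10))
  expect_error(fit_exponent(ff), "degenerate")
})

test_that("F(4) of the 12-point series matches the hand-computed oracle", {
  x <- c(1, 2, 1, 3, 1, 2, 1, 4, 1, 2, 1, 3)
  ff <- fluctuation_function(binned_series(x, 1, nonneg = FALSE),
                             structure(4L, class = "scale_grid"),
                             order = 1, min_windows = 3)
  # frozen from the explicit per-window least-squares oracle (= sqrt(4/15))
  expect_equal(ff$F, 0.516397779494322, tolerance = 1e-12)
})

test_that("production DFA equals the naive reference on random series", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(200:2000, 1)
    x <- switch(sample(3, 1),
                rnorm(n), cumsum(rnorm(n)), rpois(n, 10))
    ord <- sample(1:2, 1)
    grid <- build_scale_grid(n, ord + 3, n %/% 4, 4)
    ff <- fluctuation_function(binned_series(x, 1, nonneg = FALSE), grid,
                               order = ord)
    ref <- dfa_reference(x, ff$scales, order = ord)
    expect_equal(ff$F, ref, tolerance = 1e-9)
  }
})

test_that("F(n) is amplitude-equivariant and offset-invariant", {
  set.seed(7)
  x <- rnorm(3000)
  grid <- build_scale_grid(3000, 10)
  f1 <- fluctuation_function(binned_series(x, 1, nonneg = FALSE), grid)
  f2 <- fluctuation_function(binned_series(3.7 * x, 1, nonneg = FALSE), grid)
  f3 <- fluctuation_function(binned_series(x + 42, 1, nonneg = FALSE), grid)
  expect_equal(f2$F, 3.7 * f1$F, tolerance = 1e-12)
  expect_equal(f3$F, f1$F, tolerance = 1e-10)
  expect_equal(fit_exponent(f2)$alpha, fit_exponent(f1)$alpha,
               tolerance = 1e-10)
  expect_equal(local_slope(f2)$slope, local_slope(f1)$slope,
               tolerance = 1e-10)
})

test_that("fit_exponent returns an exact fit on an exact power law", {
  ff <- structure(list(scales = c(10L, 18L, 32L, 56L, 100L),
                       scales_s = c(100, 180, 320, 560, 1000),
                       F = 0.05 * c(100, 180, 320, 560, 1000)^1.0,
                       windows_used = rep(10L, 5), order = 2L,
                       bin_width = 10, n_series = 4000, series_sd = 1),
                  class = "fluctuation_function")
  fit <- fit_exponent(ff)
  expect_equal(fit$alpha, 1.0, tolerance = 1e-12)
  expect_equal(fit$r2, 1.0, tolerance = 1e-12)
  expect_error(fit_exponent(ff, c(100, 320)), "fewer than 5")
})

test_that("white noise and Brownian motion hit their analytic exponents", {
  set.seed(21)
  aw <- replicate(3, alpha_hat(rnorm(2^15)))
  ab <- replicate(3, alpha_hat(cumsum(rnorm(2^15))))
  expect_equal(mean(aw), 0.5, tolerance = 0.03)
  expect_equal(mean(ab), 1.5, tolerance = 0.05)
})

test_that("local slopes are flat for power laws and detect the in vitro crossover", {
  ff <- structure(list(scales = round(10^seq(1, 3, by = 0.125)),
                       scales_s = 10 * round(10^seq(1, 3, by = 0.125)),
                       F = 2 * (10 * round(10^seq(1, 3, by = 0.125)))^1.0,
                       windows_used = rep(10L, 17), order = 2L,
                       bin_width = 10, n_series = 1e5, series_sd = 1),
                  class = "fluctuation_function")
  ls <- local_slope(ff, 5)
  expect_true(all(abs(ls$slope - 1.0) < 1e-10))
  expect_error(local_slope(ff, 4), "odd")
  expect_error(local_slope(ff, 19), "fewer points")

  # white noise: local slope ~0.5 across mid scales
  set.seed(3)
  ffw <- fluctuation_function(binned_series(rnorm(2^15), 1, nonneg = FALSE),
                              build_scale_grid(2^15, 10))
  lsw <- local_slope(ffw)
  mid <- lsw$scale_s >= 30 & lsw$scale_s <= 2000
  expect_lt(max(abs(lsw$slope[mid] - 0.5)), 0.15)

  # in-vitro-like synthetic: ~0.5 at 1-6 min, > 1.5 at 2-5 h
  iv <- generate_mua(synthetic_spec("invitro_like", 14400, bin_width = 10,
                                    circadian_amplitude = 10, noise_sd = 1,
                                    seed = 7))
  ffi <- fluctuation_function(iv, build_scale_grid(14400, 10))
  lsi <- local_slope(ffi)
  expect_equal(mean_local_slope(lsi, 60, 360), 0.5, tolerance = 0.1)
  expect_gt(mean_local_slope(lsi, 7200, 18000), 1.5)
})

test_that("gapped input is rejected with a pointer to the down-sampling path", {
  g <- generate_mua(synthetic_spec("white", 200, gap_every = 30, seed = 1))
  expect_error(fluctuation_function(g), "downsample_pipeline")
})
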