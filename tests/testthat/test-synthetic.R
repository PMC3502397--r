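test_that("identical spec and seed give bit-identical series", {
  sp <- synthetic_spec("spectral", 4096, spectral_beta = 1,
                       circadian_amplitude = 2, count_mode = "poisson",
                       baseline = 50, noise_sd = 5, gap_every = 30, seed = 9)
  a <- generate_mua(sp); b <- generate_mua(sp)
  expect_identical(a$counts, b$counts)
  expect_identical(a$missing, b$missing)
})

test_that("zero-noise white generator returns the constant baseline", {
  s <- generate_mua(synthetic_spec("white", 100, noise_sd = 0, baseline = 3,
                                   seed = 1))
  expect_equal(s$counts, rep(3, 100))
})

test_that("fGn autocorrelation matches the closed-form autocovariance", {
  r1 <- function(x) cor(x[-1], x[-length(x)])
  s5 <- generate_mua(synthetic_spec("fgn", 2^16, hurst = 0.5, seed = 2))
  expect_lt(abs(r1(s5$counts)), 0.02)          # H = 0.5 is white noise
  s8 <- generate_mua(synthetic_spec("fgn", 2^16, hurst = 0.8, seed = 2))
  expect_equal(r1(s8$counts), 2^(2 * 0.8 - 1) - 1, tolerance = 0.05)
  expect_equal(var(s8$counts), 1, tolerance = 0.1)
})

test_that("DFA recovers the Hurst parameter of generated fGn", {
  for (H in c(0.6, 0.8)) {
    a <- sapply(1:10, function(s) alpha_hat(
      generate_mua(synthetic_spec("fgn", 2^16, hurst = H, seed = s))$counts))
    expect_lt(abs(mean(a) - H), 0.05)
  }
})

test_that("DFA recovers alpha = (beta + 1) / 2 from spectral synthesis", {
  for (beta in c(0, 1, 2)) {
    a <- sapply(1:10, function(s) alpha_hat(
      generate_mua(synthetic_spec("spectral", 2^16, spectral_beta = beta,
                                  seed = s))$counts))
    expect_lt(abs(mean(a) - (beta + 1) / 2), 0.05)
  }
})

test_that("cross-check: rescaled-range Hurst of generated fGn is near H", {
  skip_if_not_installed("pracma")
  h <- sapply(1:5, function(s) pracma::hurstexp(
    generate_mua(synthetic_spec("fgn", 2^14, hurst = 0.7, seed = s))$counts,
    display = FALSE)$Hs)
  expect_equal(mean(h), 0.7, tolerance = 0.1)
})

test_that("running sum raises the DFA exponent by one", {
  a <- replicate(5, {
    x <- rnorm(2^15)
    alpha_hat(cumsum(x)) - alpha_hat(x)
  })
  expect_lt(abs(mean(a) - 1), 0.05)
})

test_that("shuffle surrogate preserves the value multiset and kills correlations", {
  s <- generate_mua(synthetic_spec("fgn", 2^16, hurst = 0.9, seed = 3))
  sh <- shuffle_surrogate(s, seed = 4)
  expect_equal(sort(sh$counts), sort(s$counts))
  expect_false(identical(sh$counts, s$counts))
  expect_equal(alpha_hat(sh$counts), 0.5, tolerance = 0.03)

  const <- binned_series(rep(2, 50), 10)
  expect_equal(shuffle_surrogate(const, 1)$counts, const$counts)

  gappy <- generate_mua(synthetic_spec("white", 100, gap_every = 10, seed = 1))
  expect_error(shuffle_surrogate(gappy), "gap-free")
})

test_that("gap pattern masks gap_length bins every gap_every bins", {
  s <- generate_mua(synthetic_spec("white", 90, gap_every = 30, gap_length = 2,
                                   seed = 1))
  expect_equal(which(s$missing), c(29, 30, 59, 60, 89, 90))
})

test_that("poisson count mode produces integer counts and rejects negative rates", {
  sp <- synthetic_spec("white", 1000, baseline = 20, noise_sd = 2,
                       count_mode = "poisson", seed = 5)
  s <- generate_mua(sp)
  expect_true(all(s$counts == round(s$counts)))
  expect_equal(mean(s$counts), 20, tolerance = 0.1)
  bad <- synthetic_spec("white", 1000, baseline = 0, noise_sd = 2,
                        count_mode = "poisson", seed = 5)
  expect_error(generate_mua(bad), "negative Poisson rate")
})

test_that("spec validation enforces generator-specific parameters", {
  expect_error(synthetic_spec("fgn", 100, hurst = 1.2), "hurst")
  expect_error(synthetic_spec("fgn", 100), "hurst")
  expect_error(synthetic_spec("spectral", 100), "spectral_beta")
  expect_error(synthetic_spec("invitro_like", 100), "circadian_amplitude")
  expect_error(synthetic_spec("white", 100, gap_every = 2, gap_length = 5),
               "gap")
})

test_that("event streams realize the requested inhomogeneous Poisson rates", {
  prof0 <- binned_series(rep(0, 10), 100)
  expect_length(generate_event_stream(prof0, seed = 1)$times, 0)

  prof <- binned_series(rep(10, 10), 100)   # 10 Hz for 1000 s
  ev <- generate_event_stream(prof, seed = 2)
  expect_lt(abs(length(ev$times) - 10000), 4 * sqrt(10000))
  expect_true(all(diff(ev$times) > 0))
  expect_true(all(ev$amplitudes > 0))

  # plateau profile: per-bin counts consistent with the rate profile
  nb <- 120
  rate <- rep(2, nb); rate[46:75] <- 10     # 30-min plateau in 60-s bins
  profp <- binned_series(rate, 60)
  evp <- generate_event_stream(profp, seed = 3)
  obs <- tabulate(floor(evp$times / 60) + 1, nbins = nb)
  expected <- rate * 60
  chi2 <- sum((obs - expected)^2 / expected)
  expect_gt(pchisq(chi2, df = nb, lower.tail = FALSE), 0.01)
})
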