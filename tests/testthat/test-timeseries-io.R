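test_that("read_series parses a uniform grid and infers gaps", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,count", "0,5", "10,0", "20,7"), p)
  s <- read_series(p)
  expect_equal(s$bin_width, 10)
  expect_equal(s$counts, c(5, 0, 7))
  expect_false(any(s$missing))

  writeLines(c("time_s,count", "0,5", "10,2", "30,7"), p)
  s <- read_series(p)
  expect_length(s$counts, 4)
  expect_equal(s$missing, c(FALSE, FALSE, TRUE, FALSE))

  writeLines(c("time_s,count", "0,5", "10,-1", "20,7"), p)
  expect_error(read_series(p), "negative")

  writeLines(c("time_s,count", "0,5", "10,1", "23,7"), p)
  expect_error(read_series(p), "not uniform")
})

test_that("write -> read round trip reproduces counts, mask and bin width", {
  set.seed(4)
  miss <- runif(50) < 0.1
  cnt <- rpois(50, 20); cnt[miss] <- NA
  s <- binned_series(cnt, 10, start_time = 30, missing = miss)
  p <- withr::local_tempfile(fileext = ".csv")
  write_series(s, p)
  r <- read_series(p)
  expect_equal(r$counts, s$counts)
  expect_equal(r$missing, s$missing)
  expect_equal(r$bin_width, s$bin_width)
  expect_equal(r$start_time, s$start_time)
})

test_that("rebin sums counts, propagates gaps, and conserves totals", {
  s <- binned_series(c(1, 2, 3, 4), 10)
  expect_equal(rebin(s, 20)$counts, c(3, 7))
  expect_identical(rebin(s, 10), s)
  expect_error(rebin(s, 15), "multiple")

  # 360 bins of 10 s, bin 100 missing, 600-s epochs: epoch 2 missing,
  # the rest equal brute-force sums of their 60 bins
  cnt <- rpois(360, 5)
  miss <- rep(FALSE, 360); miss[100] <- TRUE
  cnt[100] <- NA
  s <- binned_series(cnt, 10, missing = miss)
  r <- rebin(s, 600)
  expect_length(r$counts, 6)
  expect_equal(r$missing, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  brute <- sapply(0:5, function(e) sum(cnt[(e * 60 + 1):((e + 1) * 60)]))
  expect_equal(r$counts[-2], brute[-2])
})

test_that("rebin conserves total count over fully observed epochs (property)", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(60:600, 1)
    k <- sample(c(2, 3, 5, 6), 1)
    cnt <- rpois(n, 10)
    miss <- runif(n) < 0.05
    cnt[miss] <- NA
    s <- binned_series(cnt, 10, missing = miss)
    r <- rebin(s, 10 * k)
    full <- !r$missing
    epoch_of_bin <- rep(seq_len(n %/% k), each = k)
    byhand <- as.vector(tapply(cnt[seq_len(k * (n %/% k))], epoch_of_bin, sum))
    expect_equal(r$counts[full], byhand[full])
  }
})

test_that("contiguous_segments returns maximal disjoint gap-free runs", {
  cnt <- rpois(201, 5)
  miss <- rep(FALSE, 201); miss[101] <- TRUE; cnt[101] <- NA
  s <- binned_series(cnt, 10, missing = miss)

  segs <- contiguous_segments(s, 50)
  expect_length(segs, 2)
  expect_equal(sapply(segs, function(x) length(x$counts)), c(100, 100))
  expect_equal(segs[[2]]$start_time, 101 * 10)
  expect_length(contiguous_segments(s, 101), 0)

  s2 <- binned_series(rpois(100, 5), 10)
  segs2 <- contiguous_segments(s2, 2)
  expect_length(segs2, 1)
  expect_equal(segs2[[1]]$counts, s2$counts)

  # reconstruction: segments plus skipped bins cover the input exactly
  covered <- unlist(lapply(segs, function(x)
    seq(x$start_time / 10 + 1, length.out = length(x$counts))))
  expect_equal(sort(c(covered, 101)), 1:201)
})

test_that("split_by_schedule assigns bins to phases by start time", {
  sch <- light_schedule(24, 0.5, phase = 0, mode = "LD")
  s <- binned_series(rep(1, 48 * 6), 600, schedule = sch)  # 48 h of 10-min bins
  sp <- split_by_schedule(s)
  expect_length(sp$light, 2)
  expect_length(sp$dark, 2)
  expect_equal(sp$light[[2]]$start_time, 24 * 3600)
  expect_true(all(sapply(c(sp$light, sp$dark), function(x) length(x$counts)) == 72))

  # 30-h series: second light segment truncated at 30 h
  s30 <- binned_series(rep(1, 30 * 6), 600, schedule = sch)
  sp30 <- split_by_schedule(s30)
  expect_length(sp30$light, 2)
  expect_length(sp30$dark, 1)
  expect_equal(length(sp30$light[[2]]$counts), 36)

  sdd <- binned_series(rep(1, 288), 600,
                       schedule = light_schedule(24, mode = "DD"))
  expect_error(split_by_schedule(sdd), "LD")
  expect_error(split_by_schedule(binned_series(rep(1, 10), 600)), "schedule")
})

test_that("series validation rejects malformed input", {
  expect_error(binned_series(c(1, -2, 3), 10), "non-negative")
  expect_error(binned_series(5, 10), "at least 2")
  expect_error(binned_series(c(1, 2), -1), "positive")
  expect_error(event_stream(c(1, 1), c(2, 2)), "strictly increasing")
  expect_error(event_stream(c(1, 2), c(2, -1)), "positive")
  expect_error(light_schedule(24, 0, mode = "LD"), "light_fraction")
})
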