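# Naive reference DFA, independent of the production implementation:
# explicit window loops, raw-polynomial lm() per window, forward pass plus
# backward pass pooled when the scale does not divide the length.
dfa_reference <- function(x, scales, order = 2, min_windows = 4) {
  N <- length(x)
  Y <- cumsum(x - mean(x))
  vapply(scales, function(n) {
    k <- N %/% n
    if (n < order + 2 || k < min_windows) return(NA_real_)
    t <- seq_len(n)
    fit_resid <- function(seg) {
      df <- data.frame(seg = seg, t = t)
      f <- switch(as.character(order),
                  "1" = lm(seg ~ t, data = df),
                  "2" = lm(seg ~ t + I(t^2), data = df),
                  "3" = lm(seg ~ t + I(t^2) + I(t^3), data = df))
      sum(resid(f)^2)
    }
    ssq <- 0
    for (w in seq_len(k))
      ssq <- ssq + fit_resid(Y[((w - 1) * n + 1):(w * n)])
    m <- k * n
    if (m < N) {
      for (w in seq_len(k))
        ssq <- ssq + fit_resid(Y[(N - m + (w - 1) * n + 1):(N - m + w * n)])
      sqrt(ssq / (2 * m))
    } else {
      sqrt(ssq / m)
    }
  }, numeric(1))
}

# Estimated DFA-2 exponent of a plain vector over the default grading grid
alpha_hat <- function(x, min_scale = 10, max_scale = NULL, order = 2) {
  ff <- fluctuation_function(
    binned_series(x, 1, nonneg = FALSE),
    build_scale_grid(length(x), min_scale, max_scale), order = order)
  fit_exponent(ff)$alpha
}

# Log-normal-amplitude event stream with a 30-min high-rate plateau centered
# at `peak_s`, used by subpopulation tests
plateau_stream <- function(peak_s = 3600, base_hz = 2, peak_hz = 12,
                           dur_s = 7200, seed = 1) {
  nb <- dur_s / 60
  rate <- rep(base_hz, nb)
  t0 <- (seq_len(nb) - 1) * 60
  rate[t0 >= peak_s - 900 & t0 < peak_s + 900] <- peak_hz
  prof <- binned_series(rate, 60)
  generate_event_stream(prof, meanlog = 0, sdlog = 1, seed = seed)
}
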