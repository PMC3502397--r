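#' Single-harmonic circadian fit
#'
#' Least-squares fit of `mesor + A * cos(2*pi*(t - acrophase)/period)` to a
#' binned series (bin start times, hours). Fitting the cosine and sine
#' quadrature components by linear regression is exact for noiseless
#' sinusoidal input; the amplitude is reported non-negative with the
#' acrophase normalized into `[0, period)`.
#'
#' @param x a `binned_series` spanning at least 1.5 periods. Missing bins are
#'   ignored.
#' @param period fitted period in hours (default 24; the period is an input,
#'   not an inference target).
#' @return object of class `rhythm_summary`: `amplitude` (counts),
#'   `acrophase` (hours in `[0, period)`), `mesor` (counts), `period`.
#' @export
fit_circadian <- function(x, period = 24) {
  stopifnot(inherits(x, "binned_series"))
  if (series_duration(x) < 1.5 * period * 3600)
    stop("series must span at least 1.5 periods for a circadian fit")
  t_h <- bin_times(x) / 3600
  y <- x$counts
  ok <- !x$missing
  th <- 2 * pi * t_h[ok] / period
  fit <- stats::lm(y[ok] ~ cos(th) + sin(th))
  co <- stats::coef(fit)
  a <- unname(co[2]); b <- unname(co[3])
  amp <- sqrt(a^2 + b^2)
  acro <- (atan2(b, a) / (2 * pi) * period) %% period
  if (amp < .Machine$double.eps^0.5) acro <- 0
  structure(list(amplitude = amp, acrophase = acro, mesor = unname(co[1]),
                 period = period),
            class = "rhythm_summary")
}

#' @export
print.rhythm_summary <- function(x, ...) {
  cat(sprintf("<rhythm_summary> amplitude %.3f, acrophase %.2f h, mesor %.3f (period %g h)\n",
              x$amplitude, x$acrophase, x$mesor, x$period))
  invisible(x)
}

# centered running mean; partial = TRUE shrinks the window at the edges,
# partial = FALSE returns NA there
running_mean <- function(v, w, partial = TRUE) {
  n <- length(v)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (!partial) out[i - h < 1L | i + h > n] <- NA_real_
  out
}

# centered running mean with symmetric (reflection) edge padding: every
# position averages a full window, a constant input stays exactly constant,
# and no edge inflation can displace a maximum
running_mean_reflect <- function(v, w) {
  n <- length(v)
  h <- (w - 1L) %/% 2L
  if (h == 0L) return(v)
  h <- min(h, n - 1L)
  pad <- c(v[(h + 1L):2L], v, v[(n - 1L):(n - h)])
  cs <- cumsum(c(0, pad))
  i <- seq_len(n) + h
  (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
}

#' Ultradian (sub-12-hour) variation
#'
#' RMS amplitude of the fluctuations at time scales at or below `max_scale`
#' hours: the series is first detrended by its circadian fit, then a centered
#' moving average of window `max_scale` removes the remaining slow structure;
#' the RMS of what is left quantifies the ultradian variation. A pure 24-h
#' rhythm gives ~0; white noise of sd sigma passes through at ~sigma.
#'
#' @param x a gap-free `binned_series` spanning at least `2 * max_scale`
#'   hours.
#' @param max_scale cutoff scale in hours (default 12).
#' @param period circadian period passed to [fit_circadian()].
#' @return RMS of the sub-`max_scale` residual (counts).
#' @export
ultradian_variation <- function(x, max_scale = 12, period = 24) {
  stopifnot(inherits(x, "binned_series"))
  if (series_duration(x) < 2 * max_scale * 3600)
    stop("series must span at least 2 * max_scale")
  circ <- fit_circadian(x, period)
  t_h <- bin_times(x) / 3600
  fitted <- circ$mesor + circ$amplitude *
    cos(2 * pi * (t_h - circ$acrophase) / period)
  r <- x$counts - fitted
  w <- max(3L, round(max_scale * 3600 / x$bin_width))
  if (w %% 2L == 0L) w <- w + 1L
  ma <- running_mean(r, w, partial = FALSE)
  res <- r - ma
  sqrt(mean(res^2, na.rm = TRUE))
}

#' Time of the multi-unit activity peak
#'
#' The series is smoothed with a centered moving average (window
#' `smooth_window` minutes; edges handled by symmetric reflection so that a
#' constant series stays exactly constant) and the start time of the bin with
#' the maximum smoothed value is returned; ties go to the earliest bin.
#'
#' @param x a `binned_series` (missing bins are treated as absent from the
#'   average).
#' @param smooth_window smoothing window in minutes (default 30).
#' @return peak time in seconds since recording onset.
#' @export
mua_peak_time <- function(x, smooth_window = 30) {
  stopifnot(inherits(x, "binned_series"))
  v <- x$counts
  v[x$missing] <- 0
  wgt <- as.numeric(!x$missing)
  w <- max(1L, round(smooth_window * 60 / x$bin_width))
  if (w %% 2L == 0L) w <- w + 1L
  num <- running_mean_reflect(v, w)
  den <- running_mean_reflect(wgt, w)
  sm <- ifelse(den > 0, num / den, -Inf)
  bin_times(x)[which.max(sm)]
}
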