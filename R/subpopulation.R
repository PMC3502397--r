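#' Select an amplitude threshold hitting a target firing rate
#'
#' Reproduces the offline subpopulation-selection procedure: a threshold on
#' action-potential amplitude is sought such that the average rate of
#' threshold-crossing events in the 30-minute window centered at the
#' multi-unit activity peak is close to a target level (e.g. 2.5, 5.0, 7.5 or
#' 10.0 Hz), with a relative deviation below 0.7%. The achievable rates form
#' a discrete ladder (one step per distinct amplitude value, with tied
#' amplitudes counted together); the threshold attaining the minimal
#' deviation is located by bisection on that ladder, and selection fails if
#' even the best deviation reaches 0.7%.
#'
#' @param events an [event_stream()].
#' @param mua the simultaneous multi-unit `binned_series`, used to locate the
#'   peak via [mua_peak_time()]; ignored when `window` is given.
#' @param target_rate target rate in Hz.
#' @param window optional explicit `c(start_s, end_s)` selection window
#'   (e.g. to center on a secondary peak of a bimodal profile); default is
#'   the 30 minutes centered at the global smoothed MUA peak.
#' @param max_deviation relative-deviation tolerance (default 0.007).
#' @return object of class `threshold_selection`: `threshold`, `target_rate`,
#'   `achieved_rate`, `relative_deviation`, `window`, `n_window_events`.
#' @export
select_threshold <- function(events, mua = NULL, target_rate,
                             window = NULL, max_deviation = 0.007) {
  stopifnot(inherits(events, "event_stream"))
  if (is.null(window)) {
    if (is.null(mua)) stop("either 'mua' or an explicit 'window' is required")
    peak <- mua_peak_time(mua)
    window <- c(peak - 900, peak + 900)
  }
  dur <- window[2] - window[1]
  inw <- events$times >= window[1] & events$times < window[2]
  amps <- events$amplitudes[inw]
  if (length(amps) == 0L) stop("no events inside the selection window")
  full_rate <- length(amps) / dur
  if (target_rate > full_rate)
    stop(sprintf("target %.3g Hz exceeds the full in-window rate %.3g Hz",
                 target_rate, full_rate))
  ua <- sort(unique(amps))                       # ascending candidate ladder
  # exact ladder of counts: n_ge[i] = number of events with amplitude >= ua[i]
  n_ge <- rev(cumsum(rev(tabulate(match(amps, ua), nbins = length(ua)))))
  count_at <- function(i) n_ge[i]
  target_count <- target_rate * dur
  lo <- 1L; hi <- length(ua)
  # counts are non-increasing in the ladder index; bisect to bracket the
  # target count, then pick the closer of the two bracketing thresholds
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (count_at(mid) > target_count) lo <- mid else hi <- mid
  }
  cand <- unique(c(lo, hi))
  devs <- vapply(cand, function(i)
    abs(count_at(i) / dur - target_rate) / target_rate, numeric(1))
  best <- cand[which.min(devs)]
  dev <- min(devs)
  if (dev >= max_deviation)
    stop(sprintf("selection failed: best achievable deviation %.3f%% >= %.3f%%",
                 100 * dev, 100 * max_deviation))
  structure(list(threshold = ua[best], target_rate = target_rate,
                 achieved_rate = count_at(best) / dur,
                 relative_deviation = dev,
                 window = window, n_window_events = length(amps)),
            class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf("<threshold_selection> threshold %.4g -> %.4g Hz (target %g Hz, dev %.3f%%)\n",
              x$threshold, x$achieved_rate, x$target_rate,
              100 * x$relative_deviation))
  invisible(x)
}

#' Bin a thresholded event stream
#'
#' Counts of events with amplitude at or above the threshold per bin
#' (default 1-s bins, the subpopulation sampling resolution). Raising the
#' threshold can never increase any bin count.
#'
#' @param events an [event_stream()].
#' @param threshold amplitude threshold (> 0); comparison is `>=`.
#' @param bin_width bin width in seconds (default 1).
#' @param t_start,t_end binning span in seconds; defaults to `0` and the last
#'   event time rounded up to a whole bin.
#' @return a [binned_series()] of event counts.
#' @export
bin_thresholded <- function(events, threshold, bin_width = 1,
                            t_start = 0, t_end = NULL) {
  stopifnot(inherits(events, "event_stream"))
  if (threshold <= 0) stop("'threshold' must be positive")
  if (is.null(t_end))
    t_end <- if (length(events$times)) t_start +
      ceiling((max(events$times) - t_start) / bin_width) * bin_width
    else t_start + 2 * bin_width
  n <- max(2L, as.integer(round((t_end - t_start) / bin_width)))
  keep <- events$amplitudes >= threshold &
    events$times >= t_start & events$times < t_start + n * bin_width
  idx <- floor((events$times[keep] - t_start) / bin_width) + 1L
  counts <- tabulate(idx, nbins = n)
  binned_series(counts, bin_width, start_time = t_start)
}
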