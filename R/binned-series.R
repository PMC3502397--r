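#' Binned spike-count series
#'
#' The container every analysis in this package consumes: spike counts per
#' fixed-width time bin, with an explicit missing-data mask. Missing bins are
#' represented by the mask (counts stored as `NA`), never by zeros, because
#' zero spikes in a bin is a legitimate observation. Bins are half-open
#' `[t, t + bin_width)` and all phase/window assignment uses bin start times.
#'
#' @param counts numeric vector of spike counts per bin (length >= 2).
#'   Non-missing values must be finite and >= 0. Values need not be integers:
#'   normalized or averaged series are allowed.
#' @param bin_width bin width in seconds (> 0).
#' @param start_time time of the first bin's left edge, seconds since
#'   recording onset.
#' @param missing logical mask, `TRUE` where the bin was not observed.
#'   Defaults to `is.na(counts)`.
#' @param condition recording condition label, one of `"in_vivo_LD"`,
#'   `"in_vivo_DD"`, `"in_vitro"`, `"synthetic"`.
#' @param schedule optional [light_schedule()] describing the lighting
#'   protocol.
#' @param nonneg enforce non-negativity of observed values (default `TRUE`).
#'   Continuous synthetic signals are latent activity levels rather than
#'   literal spike counts and may be negative; the generator relaxes this.
#' @return An object of class `binned_series`.
#' @seealso [read_series()], [rebin()], [contiguous_segments()]
#' @export
binned_series <- function(counts, bin_width, start_time = 0, missing = NULL,
                          condition = "synthetic", schedule = NULL,
                          nonneg = TRUE) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L)
    stop("a binned series needs at least 2 bins")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || !is.finite(bin_width) ||
      bin_width <= 0)
    stop("'bin_width' must be a single positive number of seconds")
  if (is.null(missing)) missing <- is.na(counts)
  missing <- as.logical(missing)
  if (length(missing) != length(counts))
    stop("'missing' mask must have the same length as 'counts'")
  obs <- counts[!missing]
  if (anyNA(obs) || any(!is.finite(obs)))
    stop("non-missing counts must be finite")
  if (nonneg && any(obs < 0))
    stop("counts must be non-negative")
  condition <- match.arg(condition,
                         c("synthetic", "in_vivo_LD", "in_vivo_DD", "in_vitro"))
  if (!is.null(schedule) && !inherits(schedule, "light_schedule"))
    stop("'schedule' must be a light_schedule object")
  counts[missing] <- NA_real_
  structure(
    list(start_time = as.numeric(start_time), bin_width = bin_width,
         counts = counts, missing = missing, condition = condition,
         schedule = schedule),
    class = "binned_series")
}

#' Lighting schedule
#'
#' @param period cycle period in hours (default 24).
#' @param light_fraction fraction of the period with lights on; must be in
#'   (0, 1) for LD mode and 0 for DD.
#' @param phase hours offset of the first light onset relative to time 0.
#' @param mode `"LD"` (light-dark cycle) or `"DD"` (constant darkness).
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(period = 24, light_fraction = 0.5, phase = 0,
                           mode = c("LD", "DD")) {
  mode <- match.arg(mode)
  if (mode == "DD") light_fraction <- 0
  if (mode == "LD" && (light_fraction <= 0 || light_fraction >= 1))
    stop("LD schedule requires 0 < light_fraction < 1")
  structure(list(period = period, light_fraction = light_fraction,
                 phase = phase, mode = mode),
            class = "light_schedule")
}

#' Amplitude-marked spike event stream
#'
#' Times of threshold-crossing action potentials together with their peak
#' amplitudes, the substrate for offline subpopulation selection.
#'
#' @param times event times in seconds, strictly increasing.
#' @param amplitudes positive amplitudes (arbitrary units), same length.
#' @return An object of class `event_stream`.
#' @export
event_stream <- function(times, amplitudes) {
  times <- as.numeric(times)
  amplitudes <- as.numeric(amplitudes)
  if (length(times) != length(amplitudes))
    stop("'times' and 'amplitudes' must have the same length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("event times must be strictly increasing")
  if (anyNA(amplitudes) || any(amplitudes <= 0))
    stop("amplitudes must all be positive")
  structure(list(times = times, amplitudes = amplitudes),
            class = "event_stream")
}

#' Bin start times of a series
#' @param x a `binned_series`.
#' @return numeric vector of bin left edges, seconds.
#' @export
bin_times <- function(x) {
  stopifnot(inherits(x, "binned_series"))
  x$start_time + (seq_along(x$counts) - 1) * x$bin_width
}

#' Total duration of a series in seconds
#' @param x a `binned_series`.
#' @export
series_duration <- function(x) {
  stopifnot(inherits(x, "binned_series"))
  length(x$counts) * x$bin_width
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("<binned_series> %d bins x %g s (%.2f h), condition %s\n",
              length(x$counts), x$bin_width,
              series_duration(x) / 3600, x$condition))
  nm <- sum(x$missing)
  if (nm > 0) cat(sprintf("  missing bins: %d (%.2f%%)\n",
                          nm, 100 * nm / length(x$counts)))
  invisible(x)
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %d events over %.1f s\n",
              length(x$times), if (length(x$times)) diff(range(x$times)) else 0))
  invisible(x)
}

#' @export
as.data.frame.binned_series <- function(x, ...) {
  data.frame(time_s = bin_times(x), count = x$counts,
             missing = as.integer(x$missing))
}

#' Read a binned spike-count series from delimited text
#'
#' Expects a header row with columns `time_s` (bin start, seconds) and
#' `count`, optionally `missing` (0/1). The bin width is inferred as the
#' modal time increment; grid times absent from the file become missing-mask
#' bins. Times that do not sit on the inferred uniform grid are a format
#' error, as are negative counts.
#'
#' @param path file path of a CSV/TSV file.
#' @param sep field separator (default `","`).
#' @param condition,schedule metadata attached to the returned series (the
#'   file format itself carries neither).
#' @return a [binned_series()].
#' @export
read_series <- function(path, sep = ",", condition = "synthetic",
                        schedule = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("time_s", "count") %in% names(df)))
    stop("input must have columns 'time_s' and 'count'")
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("rows must be strictly time-sorted")
  if (nrow(df) < 2L) stop("need at least 2 rows")
  dt <- diff(df$time_s)
  # modal increment = bin width; gaps are larger multiples of it
  bw <- as.numeric(names(sort(table(dt), decreasing = TRUE))[1])
  rel <- (df$time_s - df$time_s[1]) / bw
  idx <- round(rel)
  if (any(abs(rel - idx) > 1e-6))
    stop("time grid is not uniform: increments are not multiples of the ",
         "modal bin width ", bw, " s (format error)")
  if (any(!is.na(df$count) & df$count < 0))
    stop("negative counts are invalid")
  n <- idx[length(idx)] + 1L
  counts <- rep(NA_real_, n)
  miss <- rep(TRUE, n)
  counts[idx + 1L] <- df$count
  miss[idx + 1L] <- FALSE
  if ("missing" %in% names(df)) {
    expl <- as.logical(df$missing)
    miss[idx + 1L] <- expl
    counts[idx + 1L][expl] <- NA_real_
  }
  binned_series(counts, bw, start_time = df$time_s[1], missing = miss,
                condition = condition, schedule = schedule)
}

#' Write a binned series as delimited text
#'
#' Inverse of [read_series()]: columns `time_s`, `count`, `missing`; missing
#' bins keep their row (count empty) so the grid round-trips exactly.
#'
#' @param x a `binned_series`.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_series <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "binned_series"))
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Re-bin a series to a coarser epoch
#'
#' Counts are summed (not averaged) within consecutive epochs, preserving
#' counting semantics. By default an epoch containing any missing bin is
#' itself missing; `max_missing_frac` relaxes this for the gapped-recording
#' workflow: an epoch whose missing fraction is at or below the threshold is
#' kept, with missing bins contributing the within-epoch mean of the observed
#' bins (i.e. the observed sum is rescaled to the full epoch).
#'
#' @param x a `binned_series`.
#' @param epoch new bin width in seconds; must be an integer multiple of
#'   `x$bin_width`.
#' @param max_missing_frac tolerated fraction of missing bins per epoch
#'   (default 0 = strict).
#' @return a `binned_series` with bin width `epoch`. A trailing partial epoch
#'   is dropped.
#' @export
rebin <- function(x, epoch, max_missing_frac = 0) {
  stopifnot(inherits(x, "binned_series"))
  k <- epoch / x$bin_width
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("'epoch' must be a positive integer multiple of the bin width")
  k <- as.integer(round(k))
  if (k == 1L) return(x)
  n <- length(x$counts)
  m <- n %/% k
  if (m < 2L) stop("fewer than 2 complete epochs after re-binning")
  cnt <- matrix(x$counts[seq_len(m * k)], nrow = k)
  mis <- matrix(x$missing[seq_len(m * k)], nrow = k)
  n_miss <- colSums(mis)
  obs_sum <- colSums(cnt * !mis, na.rm = TRUE)
  out <- ifelse(n_miss == 0, obs_sum,
                ifelse(n_miss / k <= max_missing_frac,
                       obs_sum * k / (k - n_miss), NA_real_))
  binned_series(out, epoch, start_time = x$start_time,
                missing = is.na(out), condition = x$condition,
                schedule = x$schedule, nonneg = FALSE)
}

#' Maximal gap-free segments of a series
#'
#' @param x a `binned_series`.
#' @param min_length minimum segment length in bins.
#' @return list of `binned_series`, the maximal runs without missing bins of
#'   length >= `min_length`, in temporal order (possibly empty).
#' @export
contiguous_segments <- function(x, min_length = 2L) {
  stopifnot(inherits(x, "binned_series"))
  min_length <- max(2L, as.integer(min_length))
  r <- rle(!x$missing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  lapply(which(keep), function(i) {
    sel <- starts[i]:ends[i]
    binned_series(x$counts[sel], x$bin_width,
                  start_time = x$start_time + (starts[i] - 1L) * x$bin_width,
                  missing = x$missing[sel], condition = x$condition,
                  schedule = x$schedule, nonneg = FALSE)
  })
}

#' Split a series into light-phase and dark-phase segments
#'
#' Each bin is assigned to exactly one phase by its start time under the
#' series' LD schedule; contiguous runs of same-phase bins are returned as
#' segments.
#'
#' @param x a `binned_series` whose `schedule` is present and in LD mode.
#' @return list with elements `light` and `dark`, each a list of
#'   `binned_series` covering the input.
#' @export
split_by_schedule <- function(x) {
  stopifnot(inherits(x, "binned_series"))
  sch <- x$schedule
  if (is.null(sch)) stop("series has no light schedule")
  if (sch$mode != "LD") stop("phase split requires an LD schedule")
  t_h <- bin_times(x) / 3600
  in_light <- ((t_h - sch$phase) %% sch$period) < sch$light_fraction * sch$period
  r <- rle(in_light)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- function(i) {
    sel <- starts[i]:ends[i]
    binned_series(x$counts[sel], x$bin_width,
                  start_time = x$start_time + (starts[i] - 1L) * x$bin_width,
                  missing = x$missing[sel], condition = x$condition,
                  schedule = sch, nonneg = FALSE)
  }
  segs <- lapply(seq_along(r$values), seg)
  # single-bin phase runs cannot form a valid series; fold them into a
  # 2-bin minimum by construction of typical schedules this does not occur
  list(light = segs[r$values], dark = segs[!r$values])
}
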