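#' Default analysis configuration
#'
#' @param order DFA detrending order.
#' @param points_per_decade scale-grid density.
#' @param min_scale minimum DFA scale in bins.
#' @param fit_range_s exponent fit range in seconds (`NULL` = whole grid).
#' @param epoch down-sampling epoch for gapped recordings, seconds.
#' @param max_missing_frac per-epoch missing tolerance for down-sampling.
#' @param d_med,d_max power-law classification thresholds, percent.
#' @param period circadian period, hours.
#' @param smoothing_window local-slope smoothing window, grid points.
#' @param adjustment_table optional [build_adjustment()] table applied to the
#'   exponent of gapped recordings.
#' @return a named list of configuration values.
#' @export
analysis_config <- function(order = 2L, points_per_decade = 8,
                            min_scale = 10L, fit_range_s = NULL,
                            epoch = 600, max_missing_frac = 0.05,
                            d_med = 10, d_max = 30, period = 24,
                            smoothing_window = 5L, adjustment_table = NULL) {
  list(order = order, points_per_decade = points_per_decade,
       min_scale = min_scale, fit_range_s = fit_range_s, epoch = epoch,
       max_missing_frac = max_missing_frac, d_med = d_med, d_max = d_max,
       period = period, smoothing_window = smoothing_window,
       adjustment_table = adjustment_table)
}

# FNV-1a hash of a deparsed object, for content-addressing reports
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Analyze one recording end to end
#'
#' Composes the full per-recording workflow: gapped recordings are routed
#' through [downsample_pipeline()]; the fluctuation function, scaling fit,
#' local-slope profile and fractal/non-fractal classification are computed;
#' circadian amplitude, acrophase, ultradian variation and peak time are
#' added when the recording is long enough (>= 1.5 circadian periods); when
#' the recording had gaps and an adjustment table is configured, the adjusted
#' exponent is reported alongside the raw one. The report is deterministic
#' given series + config.
#'
#' @param x a `binned_series`.
#' @param config an [analysis_config()] list.
#' @return object of class `recording_report`.
#' @export
analyze_recording <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "binned_series"))
  had_gaps <- any(x$missing)
  series <- if (had_gaps)
    downsample_pipeline(x, config$epoch, config$max_missing_frac)
  else x
  grid <- build_scale_grid(length(series$counts),
                           min_scale = config$min_scale,
                           points_per_decade = config$points_per_decade)
  ff <- fluctuation_function(series, grid, order = config$order)
  cls <- classify_scaling(ff, config$fit_range_s, config$d_med, config$d_max)
  ls <- local_slope(ff, config$smoothing_window)
  alpha_adj <- NULL
  if (had_gaps && !is.null(config$adjustment_table))
    alpha_adj <- adjust_exponent(cls$fit$alpha, config$adjustment_table)
  rhythm <- NULL
  peak_s <- NULL
  if (series_duration(x) >= 1.5 * config$period * 3600 && !had_gaps) {
    rhythm <- fit_circadian(x, config$period)
    rhythm$ultradian_rms <- ultradian_variation(x, period = config$period)
    peak_s <- mua_peak_time(x)
  }
  structure(list(condition = x$condition, n_bins = length(x$counts),
                 bin_width = x$bin_width, had_gaps = had_gaps,
                 series_sd = ff$series_sd,
                 fluctuation = ff, fit = cls$fit, local_slope = ls,
                 classification = cls, rhythm = rhythm,
                 mua_peak_s = peak_s, alpha_adjusted = alpha_adj,
                 provenance = list(
                   config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("fractalmua")),
                   config = config)),
            class = "recording_report")
}

#' @export
print.recording_report <- function(x, ...) {
  cat(sprintf("<recording_report> %s, %d bins x %g s\n", x$condition,
              x$n_bins, x$bin_width))
  cat(sprintf("  alpha = %.3f (SE %.3f), %s (median dev %.1f%%, max %.1f%%)\n",
              x$fit$alpha, x$fit$alpha_se, x$classification$label,
              x$classification$median_dev, x$classification$max_dev))
  if (!is.null(x$alpha_adjusted))
    cat(sprintf("  gap-adjusted alpha = %.3f\n", x$alpha_adjusted))
  if (!is.null(x$rhythm))
    cat(sprintf("  circadian amplitude %.3f, acrophase %.2f h, ultradian RMS %.3f\n",
                x$rhythm$amplitude, x$rhythm$acrophase, x$rhythm$ultradian_rms))
  invisible(x)
}

#' Windowed stability of the fluctuation function
#'
#' DFA in non-overlapping windows (default 12 h) of a recording, with the
#' maximum scale capped at a quarter of the window length. The similarity of
#' the per-window curves (maximum pairwise RMS difference of log10 F at
#' shared scales) quantifies whether the scaling behaviour is stable from
#' the beginning to the end of the recording.
#'
#' @param x a gap-free `binned_series` spanning at least two windows.
#' @param window_h window length in hours (default 12).
#' @param order,min_scale,points_per_decade DFA parameters.
#' @return list with `windows` (list of `fluctuation_function`, one per
#'   complete window), `max_rms_diff`, `window_h`.
#' @export
windowed_stability <- function(x, window_h = 12, order = 2L,
                               min_scale = 10L, points_per_decade = 8) {
  stopifnot(inherits(x, "binned_series"))
  n_per <- as.integer(floor(window_h * 3600 / x$bin_width))
  k <- length(x$counts) %/% n_per
  if (k < 2L) stop("recording spans fewer than 2 complete windows")
  grid <- build_scale_grid(n_per, min_scale = min_scale,
                           points_per_decade = points_per_decade)
  ffs <- lapply(seq_len(k), function(i) {
    sel <- ((i - 1L) * n_per + 1L):(i * n_per)
    w <- binned_series(x$counts[sel], x$bin_width,
                       start_time = x$start_time + (sel[1] - 1L) * x$bin_width,
                       condition = x$condition, nonneg = FALSE)
    fluctuation_function(w, grid, order = order)
  })
  shared <- Reduce(intersect, lapply(ffs, function(f) f$scales))
  logF <- vapply(ffs, function(f) log10(f$F[match(shared, f$scales)]),
                 numeric(length(shared)))
  pairs <- utils::combn(k, 2)
  rmsd <- apply(pairs, 2, function(p)
    sqrt(mean((logF[, p[1]] - logF[, p[2]])^2)))
  list(windows = ffs, max_rms_diff = max(rmsd), window_h = window_h)
}

#' Group-average fluctuation function
#'
#' Averages the fluctuation functions of several recordings after
#' normalizing each subject by the standard deviation of its own series
#' (equivalently dividing F(n) by the series SD), which removes individual
#' differences in overall activity amplitude. Averaging is done on log10 F
#' (geometric mean in linear space) at the scales shared by all grids, with
#' the standard error across subjects, and a group exponent is fitted to the
#' mean curve.
#'
#' @param reports list of `recording_report` objects (>= 2) with overlapping
#'   scale grids (>= 5 shared scales).
#' @return list with `scales_s`, `logF_mean`, `logF_se`, `alpha`, `alpha_se`,
#'   `n_subjects`.
#' @export
group_average <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports")
  stopifnot(all(vapply(reports, inherits, TRUE, "recording_report")))
  ffs <- lapply(reports, `[[`, "fluctuation")
  shared <- Reduce(intersect, lapply(ffs, function(f) round(f$scales_s, 9)))
  if (length(shared) < 5L) stop("fewer than 5 shared scales across grids")
  logF <- vapply(ffs, function(f)
    log10(f$F[match(shared, round(f$scales_s, 9))] / f$series_sd),
    numeric(length(shared)))
  mu <- rowMeans(logF)
  se <- apply(logF, 1, stats::sd) / sqrt(ncol(logF))
  lx <- log10(shared)
  fit <- stats::lm(mu ~ lx)
  sm <- summary(fit)
  list(scales_s = shared, logF_mean = mu, logF_se = se,
       alpha = unname(stats::coef(fit)[2]),
       alpha_se = sm$coefficients[2, 2],
       n_subjects = length(reports))
}

#' Serialize a recording report to JSON
#'
#' @param report a `recording_report`.
#' @param path output file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "recording_report"))
  out <- list(
    condition = report$condition, n_bins = report$n_bins,
    bin_width = report$bin_width, had_gaps = report$had_gaps,
    alpha = report$fit$alpha, alpha_se = report$fit$alpha_se,
    r2 = report$fit$r2, fit_range_s = report$fit$fit_range,
    classification = report$classification$label,
    median_dev = report$classification$median_dev,
    max_dev = report$classification$max_dev,
    alpha_adjusted = report$alpha_adjusted,
    rhythm = if (!is.null(report$rhythm))
      list(amplitude = report$rhythm$amplitude,
           acrophase = report$rhythm$acrophase,
           mesor = report$rhythm$mesor,
           ultradian_rms = report$rhythm$ultradian_rms),
    mua_peak_s = report$mua_peak_s,
    fluctuation = list(scale_s = report$fluctuation$scales_s,
                       F = report$fluctuation$F,
                       windows_used = report$fluctuation$windows_used),
    local_slope = list(scale_s = report$local_slope$scale_s,
                       slope = report$local_slope$slope),
    provenance = report$provenance[c("config_hash", "package_version")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
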