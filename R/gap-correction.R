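#' Down-sample a gapped recording for DFA
#'
#' Recordings with missing data every few minutes cannot feed DFA directly,
#' which needs gap-free segments. The workflow re-bins to a coarse epoch
#' (default 600 s), treating an epoch as observed when its missing-bin
#' fraction is at most `max_missing_frac` (missing bins then contribute the
#' within-epoch mean of the observed bins), and extracts the longest
#' remaining gap-free segment.
#'
#' @param x a `binned_series`, possibly with gaps.
#' @param epoch target epoch in seconds (default 600).
#' @param max_missing_frac per-epoch tolerated missing fraction (default
#'   0.05).
#' @param max_scale optional intended maximum DFA scale in epochs; if given,
#'   the returned segment is guaranteed to support at least `min_windows`
#'   non-overlapping windows of that scale, otherwise an error is raised
#'   (mirroring the exclusion of overly fragmented recordings).
#' @param min_windows minimum windows at `max_scale` (default 4).
#' @return a gap-free `binned_series` with bin width `epoch`.
#' @export
downsample_pipeline <- function(x, epoch = 600, max_missing_frac = 0.05,
                                max_scale = NULL, min_windows = 4L) {
  stopifnot(inherits(x, "binned_series"))
  reb <- if (epoch == x$bin_width) x else rebin(x, epoch, max_missing_frac)
  segs <- contiguous_segments(reb, min_length = 2L)
  if (length(segs) == 0L)
    stop("no gap-free segment after down-sampling: recording too fragmented")
  seg <- segs[[which.max(vapply(segs, function(s) length(s$counts), 1))]]
  if (!is.null(max_scale) &&
      length(seg$counts) < min_windows * max_scale)
    stop(sprintf(paste0("insufficient contiguous data: longest segment has %d",
                        " epochs but %d are needed for %d windows of scale %d"),
                 length(seg$counts), min_windows * max_scale, min_windows,
                 max_scale))
  seg
}

#' Scaling exponent through the gapped-recording pipeline
#'
#' Convenience composition used both for analysis of gapped recordings and
#' inside [build_adjustment()]: down-sample, run DFA, fit the exponent over
#' the full down-sampled grid.
#'
#' @inheritParams downsample_pipeline
#' @param order DFA detrending order.
#' @param min_scale,points_per_decade grid parameters (epoch units for
#'   `min_scale`).
#' @return the fitted exponent (numeric scalar).
#' @export
gap_pipeline_exponent <- function(x, epoch = 600, max_missing_frac = 0.05,
                                  order = 2L, min_scale = 10L,
                                  points_per_decade = 8) {
  ds <- downsample_pipeline(x, epoch, max_missing_frac)
  grid <- build_scale_grid(length(ds$counts), min_scale = min_scale,
                           points_per_decade = points_per_decade)
  ff <- fluctuation_function(ds, grid, order = order)
  fit_exponent(ff)$alpha
}

#' Simulate the exponent bias of the gap/down-sampling pipeline
#'
#' The combined effect of periodic missing data and the compensatory 600-s
#' down-sampling biases the estimated exponent; the bias is estimated by
#' simulation. For each true exponent alpha on `alpha_grid`, `reps` synthetic
#' series are generated by spectral synthesis (PSD slope beta = 2 alpha - 1),
#' the gap pattern is imposed, the full pipeline
#' ([gap_pipeline_exponent()]) is run, and the mean estimation error
#' (alpha_hat - alpha_true) is recorded. The resulting bias curve feeds
#' [adjust_exponent()].
#'
#' @param gap_pattern list with `gap_every` and `gap_length` (bins); default
#'   1 missing bin every 30 bins.
#' @param epoch down-sampling epoch, seconds.
#' @param alpha_grid true exponents to simulate; must lie within (0.3, 1.7).
#' @param reps simulations per grid point (>= 50).
#' @param seed integer base seed.
#' @param n_bins,bin_width simulated recording geometry (default 2^15 bins of
#'   10 s, about 91 h).
#' @return object of class `adjustment_table`: `alpha_grid`, `bias`, `reps`,
#'   `gap_pattern`, `epoch`, `seed`, `n_bins`, `bin_width`.
#' @export
build_adjustment <- function(gap_pattern = list(gap_every = 30L, gap_length = 1L),
                             epoch = 600, alpha_grid = seq(0.5, 1.5, by = 0.25),
                             reps = 50L, seed = 1L, n_bins = 2^15,
                             bin_width = 10) {
  if (any(alpha_grid <= 0.3 | alpha_grid >= 1.7))
    stop("'alpha_grid' must lie within (0.3, 1.7)")
  if (reps < 50L) stop("'reps' must be >= 50 for a stable bias curve")
  bias <- vapply(seq_along(alpha_grid), function(i) {
    a <- alpha_grid[i]
    err <- vapply(seq_len(reps), function(r) {
      spec <- synthetic_spec("spectral", n_bins = n_bins, bin_width = bin_width,
                             spectral_beta = 2 * a - 1,
                             gap_every = gap_pattern$gap_every,
                             gap_length = gap_pattern$gap_length,
                             seed = seed + 1000L * i + r)
      gap_pipeline_exponent(generate_mua(spec), epoch = epoch) - a
    }, numeric(1))
    mean(err)
  }, numeric(1))
  structure(list(alpha_grid = alpha_grid, bias = bias, reps = as.integer(reps),
                 gap_pattern = gap_pattern, epoch = epoch, seed = seed,
                 n_bins = n_bins, bin_width = bin_width),
            class = "adjustment_table")
}

#' @export
print.adjustment_table <- function(x, ...) {
  cat(sprintf("<adjustment_table> %d alpha points, %d reps, gaps %d/%d bins, epoch %g s\n",
              length(x$alpha_grid), x$reps, x$gap_pattern$gap_length,
              x$gap_pattern$gap_every, x$epoch))
  print(data.frame(alpha = x$alpha_grid, bias = round(x$bias, 4)))
  invisible(x)
}

#' Adjust a pipeline exponent for gap/down-sampling bias
#'
#' Solves `alpha + bias(alpha) = alpha_hat` for the true exponent by
#' fixed-point iteration on the interpolated bias curve (tolerance 1e-4), so
#' that the returned value, pushed through the simulated pipeline, would on
#' average reproduce the observed `alpha_hat`.
#'
#' @param alpha_hat exponent estimated by [gap_pipeline_exponent()].
#' @param table an [build_adjustment()] table whose grid covers the solution.
#' @return adjusted exponent (numeric scalar).
#' @export
adjust_exponent <- function(alpha_hat, table) {
  stopifnot(inherits(table, "adjustment_table"))
  bias_at <- function(a) stats::approx(table$alpha_grid, table$bias,
                                       xout = a, rule = 1)$y
  a <- alpha_hat
  for (i in seq_len(100L)) {
    b <- bias_at(min(max(a, min(table$alpha_grid)), max(table$alpha_grid)))
    a_new <- alpha_hat - b
    if (a_new < min(table$alpha_grid) - 0.1 ||
        a_new > max(table$alpha_grid) + 0.1)
      stop("alpha_hat outside the adjustment table's interpolation range")
    if (abs(a_new - a) < 1e-4) return(a_new)
    a <- a_new
  }
  a
}
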