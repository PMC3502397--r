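#' Percent deviation of F(n) from its power-law fit
#'
#' For each grid scale, the relative deviation (in percent, computed in
#' linear space) of the observed fluctuation amplitude from the fitted
#' power law, together with the exceedance curve: for each threshold on a
#' standard ladder, the fraction of grid points (uniformly distributed in log
#' scale) whose deviation exceeds the threshold. A fractal signal fitted over
#' an appropriate range shows small deviations everywhere; fitting a
#' power law to a non-fractal F(n) is erroneous and leaves large deviations
#' at almost all scales.
#'
#' @param ff a `fluctuation_function`.
#' @param fit a `scaling_fit` obtained from the same grid.
#' @param thresholds deviation thresholds in percent for the exceedance
#'   curve.
#' @return object of class `deviation_profile`: `scale_s`,
#'   `percent_deviation`, `thresholds`, `exceedance`.
#' @export
percent_deviation <- function(ff, fit,
                              thresholds = c(1, 2, 5, 10, 15, 20, 25, 30, 40, 50)) {
  stopifnot(inherits(ff, "fluctuation_function"), inherits(fit, "scaling_fit"))
  fhat <- 10^(fit$intercept + fit$alpha * log10(ff$scales_s))
  pct <- 100 * abs(ff$F - fhat) / fhat
  exc <- vapply(thresholds, function(d) mean(pct > d), numeric(1))
  structure(list(scale_s = ff$scales_s, percent_deviation = pct,
                 thresholds = thresholds, exceedance = exc),
            class = "deviation_profile")
}

#' Classify a fluctuation function as fractal or non-fractal
#'
#' Fits a power law over `fit_range` and labels the scaling "fractal" iff,
#' over the grid points inside the fit range, (a) the median percent
#' deviation is at most `d_med` and (b) no point deviates by more than
#' `d_max`. The numeric thresholds (defaults 10% and 30%) are this package's
#' operational rule, calibrated to separate 1/f-like signals from
#' white-noise-plus-circadian-trend signals; both are configurable.
#' Loosening either threshold can never flip a fractal label to non-fractal.
#'
#' @param ff a `fluctuation_function`.
#' @param fit_range `c(min_s, max_s)` seconds (default whole grid).
#' @param d_med median-deviation threshold, percent.
#' @param d_max maximum-deviation threshold, percent.
#' @return list with `label` (`"fractal"` or `"non_fractal"`), `fit`,
#'   `deviation` (full-grid `deviation_profile`), `median_dev`, `max_dev`
#'   (both over the fit range), `d_med`, `d_max`.
#' @export
classify_scaling <- function(ff, fit_range = NULL, d_med = 10, d_max = 30) {
  stopifnot(inherits(ff, "fluctuation_function"))
  fit <- fit_exponent(ff, fit_range)
  dev <- percent_deviation(ff, fit)
  sel <- dev$scale_s >= fit$fit_range[1] & dev$scale_s <= fit$fit_range[2]
  med <- stats::median(dev$percent_deviation[sel])
  mx <- max(dev$percent_deviation[sel])
  label <- if (med <= d_med && mx <= d_max) "fractal" else "non_fractal"
  list(label = label, fit = fit, deviation = dev,
       median_dev = med, max_dev = mx, d_med = d_med, d_max = d_max)
}
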