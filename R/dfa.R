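#' Log-uniform grid of DFA window sizes
#'
#' Scales are unique integers log-uniformly spaced at `points_per_decade`
#' per decade, with both endpoints included. The largest scale may not exceed
#' a quarter of the series length, so that at least 4 non-overlapping windows
#' are available at every scale — the minimum for a reliable estimate of
#' F(n).
#'
#' @param series_length series length in bins.
#' @param min_scale smallest window size in bins (default 10; must be at
#'   least detrending order + 2).
#' @param max_scale largest window size in bins (default
#'   `floor(series_length / 4)`).
#' @param points_per_decade grid density (default 8).
#' @return integer vector of scales (class `scale_grid`).
#' @export
build_scale_grid <- function(series_length, min_scale = 10L,
                             max_scale = NULL, points_per_decade = 8) {
  series_length <- as.integer(series_length)
  if (is.null(max_scale)) max_scale <- series_length %/% 4L
  min_scale <- as.integer(min_scale); max_scale <- as.integer(max_scale)
  if (max_scale > series_length %/% 4L)
    stop("max_scale exceeds series_length/4: at least 4 non-overlapping ",
         "windows are required at every scale")
  if (min_scale < 3L) stop("min_scale must be >= 3 (order + 2 bins)")
  if (min_scale > max_scale) stop("min_scale must be <= max_scale")
  if (min_scale == max_scale) return(structure(min_scale, class = "scale_grid"))
  npt <- ceiling(points_per_decade * log10(max_scale / min_scale)) + 1L
  g <- unique(round(10^seq(log10(min_scale), log10(max_scale),
                           length.out = max(npt, 2L))))
  g <- sort(unique(c(g, min_scale, max_scale)))
  structure(as.integer(g), class = "scale_grid")
}

#' Detrended fluctuation function
#'
#' Order-`order` detrended fluctuation analysis of a gap-free binned series:
#' (i) the mean-subtracted series is integrated (cumulative sum); (ii) the
#' profile is partitioned into non-overlapping windows of size n, in a
#' forward pass from the start and, when n does not divide the length, a
#' backward pass from the end (both pooled so no samples are discarded);
#' (iii) an order-`order` polynomial is fitted in each window (the local
#' trend); (iv) the trend is subtracted; (v) F(n) is the root mean square of
#' all pooled residuals. Repeating over the scale grid gives F(n).
#'
#' Scales with fewer than `min_windows` complete forward windows are dropped
#' with a warning.
#'
#' @param x a gap-free `binned_series` (route gapped recordings through
#'   [downsample_pipeline()] first), or a plain numeric vector (bin width 1 s
#'   assumed).
#' @param grid a [build_scale_grid()] result, or `NULL` for the default grid.
#' @param order polynomial detrending order (default 2, which removes
#'   linear and quadratic trends in the raw signal).
#' @param min_windows minimum complete windows per retained scale (default 4).
#' @return object of class `fluctuation_function`: list with `scales` (bins),
#'   `scales_s` (seconds), `F`, `windows_used`, `order`, `bin_width`,
#'   `n_series`, `series_sd`.
#' @export
fluctuation_function <- function(x, grid = NULL, order = 2L,
                                 min_windows = 4L) {
  if (is.numeric(x)) x <- binned_series(x, 1, nonneg = FALSE)
  stopifnot(inherits(x, "binned_series"))
  if (any(x$missing))
    stop("series has missing bins; use downsample_pipeline() first")
  v <- x$counts
  N <- length(v)
  order <- as.integer(order)
  if (is.null(grid))
    grid <- build_scale_grid(N, min_scale = max(10L, order + 2L))
  scales <- as.integer(grid)
  Y <- cumsum(v - mean(v))
  Fv <- rep(NA_real_, length(scales))
  wu <- integer(length(scales))
  for (j in seq_along(scales)) {
    n <- scales[j]
    k <- N %/% n
    if (n < order + 2L || k < min_windows) next
    X <- cbind(1, stats::poly(seq_len(n), degree = order))
    qx <- qr(X)
    fwd <- matrix(Y[seq_len(k * n)], nrow = n)
    ssq <- sum(qr.resid(qx, fwd)^2)
    m <- k * n
    if (m < N) {                       # backward pass over the tail remainder
      bwd <- matrix(Y[(N - m + 1L):N], nrow = n)
      ssq <- ssq + sum(qr.resid(qx, bwd)^2)
      wu[j] <- 2L * k
      Fv[j] <- sqrt(ssq / (2 * m))
    } else {
      wu[j] <- k
      Fv[j] <- sqrt(ssq / m)
    }
  }
  keep <- !is.na(Fv)
  if (!any(keep)) stop("no scale retained: series too short for the grid")
  if (!all(keep))
    warning(sprintf("%d scale(s) dropped (< %d complete windows)",
                    sum(!keep), min_windows))
  structure(list(scales = scales[keep], scales_s = scales[keep] * x$bin_width,
                 F = Fv[keep], windows_used = wu[keep], order = order,
                 bin_width = x$bin_width, n_series = N,
                 series_sd = stats::sd(v)),
            class = "fluctuation_function")
}

#' @export
print.fluctuation_function <- function(x, ...) {
  cat(sprintf("<fluctuation_function> DFA-%d, %d scales (%g-%g s), n = %d\n",
              x$order, length(x$scales), min(x$scales_s), max(x$scales_s),
              x$n_series))
  invisible(x)
}

#' Fit the scaling exponent alpha
#'
#' Ordinary least squares of log10 F(n) on log10 n (n in seconds) over the
#' grid points inside `fit_range`, each point weighted equally. The slope is
#' the scaling exponent alpha: 0.5 for uncorrelated noise, ~1.0 for 1/f-like
#' fractal correlations, 1.5 for Brownian motion.
#'
#' @param ff a `fluctuation_function`.
#' @param fit_range `c(min_s, max_s)` in seconds, or `NULL` for the whole
#'   grid. At least 5 grid points must fall inside.
#' @return object of class `scaling_fit`: `alpha`, `intercept` (log10 units),
#'   `alpha_se`, `r2`, `fit_range` (seconds), `n_points`.
#' @export
fit_exponent <- function(ff, fit_range = NULL) {
  stopifnot(inherits(ff, "fluctuation_function"))
  if (is.null(fit_range)) fit_range <- range(ff$scales_s)
  sel <- ff$scales_s >= fit_range[1] & ff$scales_s <= fit_range[2]
  if (sum(sel) < 5L)
    stop("fewer than 5 grid points inside the fit range")
  if (any(ff$F[sel] <= 0))
    stop("non-positive F(n) in fit range (degenerate input, e.g. constant series)")
  lx <- log10(ff$scales_s[sel]); ly <- log10(ff$F[sel])
  np <- sum(sel)
  sxx <- sum((lx - mean(lx))^2)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sxx
  icpt <- mean(ly) - slope * mean(lx)
  rss <- sum((ly - icpt - slope * lx)^2)
  tss <- sum((ly - mean(ly))^2)
  structure(list(alpha = slope,
                 intercept = icpt,
                 alpha_se = sqrt(rss / (np - 2) / sxx),
                 r2 = if (tss > 0) 1 - rss / tss else 1,
                 fit_range = as.numeric(fit_range),
                 n_points = np),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> alpha = %.3f (SE %.3f), r2 = %.4f, %d points over %g-%g s\n",
              x$alpha, x$alpha_se, x$r2, x$n_points,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Local slope of the fluctuation function
#'
#' Least-squares slope of log10 F versus log10 n within a centered window of
#' `smoothing_window` grid points, evaluated at each interior grid point.
#' A scale-dependent (non-constant) local slope is the signature of a
#' crossover, i.e. absence of a single power law.
#'
#' @param ff a `fluctuation_function`.
#' @param smoothing_window odd number of grid points (default 5).
#' @return object of class `local_slope_profile`: `scale_s` (window-center
#'   scales, seconds), `slope`, `smoothing_window`.
#' @export
local_slope <- function(ff, smoothing_window = 5L) {
  stopifnot(inherits(ff, "fluctuation_function"))
  w <- as.integer(smoothing_window)
  if (w < 3L || w %% 2L == 0L) stop("'smoothing_window' must be odd and >= 3")
  m <- length(ff$scales)
  if (m < w) stop("grid has fewer points than the smoothing window")
  h <- (w - 1L) %/% 2L
  lx <- log10(ff$scales_s); ly <- log10(ff$F)
  idx <- (h + 1L):(m - h)
  slopes <- vapply(idx, function(i) {
    s <- (i - h):(i + h)
    xs <- lx[s] - mean(lx[s])
    sum(xs * ly[s]) / sum(xs^2)
  }, numeric(1))
  if (any(!is.finite(slopes))) stop("non-finite local slope (degenerate F)")
  structure(list(scale_s = ff$scales_s[idx], slope = slopes,
                 smoothing_window = w),
            class = "local_slope_profile")
}

#' Mean local slope over a scale band
#'
#' @param profile a `local_slope_profile`.
#' @param min_s,max_s band limits in seconds (inclusive).
#' @return mean slope over window-center scales inside the band.
#' @export
mean_local_slope <- function(profile, min_s, max_s) {
  stopifnot(inherits(profile, "local_slope_profile"))
  sel <- profile$scale_s >= min_s & profile$scale_s <= max_s
  if (!any(sel)) stop("no local-slope points inside the requested band")
  mean(profile$slope[sel])
}
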