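#' Specification of a synthetic multi-unit activity signal
#'
#' A full, reproducible recipe for a synthetic binned series. Generators:
#' \describe{
#'   \item{`fgn`}{fractional Gaussian noise with Hurst parameter `hurst`
#'     (exact circulant-embedding synthesis); theoretical DFA exponent
#'     alpha = H, so this covers the anti-persistent-to-1/f range alpha < 1.}
#'   \item{`spectral`}{Fourier synthesis with power spectral density
#'     proportional to 1/f^`spectral_beta` and random phases; theoretical
#'     DFA exponent alpha = (beta + 1) / 2. beta = 1 gives the alpha ~ 1.0
#'     regime seen in vivo.}
#'   \item{`brownian`}{running sum of white noise (alpha = 1.5).}
#'   \item{`white`}{i.i.d. Gaussian noise (alpha = 0.5).}
#'   \item{`invitro_like`}{white noise plus a circadian sinusoid — white-noise
#'     behaviour at minute scales and trend-dominated behaviour at hour
#'     scales, emulating the isolated-SCN recordings.}
#' }
#' A circadian sinusoid of amplitude `circadian_amplitude` is added to any
#' generator when the amplitude is positive (additive modulation keeps the
#' exponent of the stochastic component analyzable). `count_mode = "poisson"`
#' treats the latent signal as a per-bin Poisson mean.
#'
#' @param generator one of `"fgn"`, `"spectral"`, `"brownian"`, `"white"`,
#'   `"invitro_like"`.
#' @param n_bins number of bins (>= 2).
#' @param bin_width bin width in seconds (default 10, the native MUA epoch).
#' @param hurst Hurst parameter in (0, 1); required for `fgn`.
#' @param spectral_beta PSD slope beta >= 0; required for `spectral`.
#' @param circadian_amplitude,circadian_period,circadian_phase sinusoid
#'   amplitude (signal units), period (hours, default 24) and phase (hours).
#' @param baseline constant added to the signal (mean level).
#' @param noise_sd standard deviation of the stochastic component (>= 0).
#' @param count_mode `"continuous"` (default) or `"poisson"`.
#' @param gap_every,gap_length optional periodic gap pattern: the last
#'   `gap_length` bins of every `gap_every`-bin block are masked missing
#'   (default pattern emulating gapped rat DD recordings is 1 bin in 30).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return an object of class `synthetic_spec`.
#' @seealso [generate_mua()]
#' @export
synthetic_spec <- function(generator = c("fgn", "spectral", "brownian",
                                         "white", "invitro_like"),
                           n_bins, bin_width = 10, hurst = NULL,
                           spectral_beta = NULL, circadian_amplitude = 0,
                           circadian_period = 24, circadian_phase = 0,
                           baseline = 0, noise_sd = 1,
                           count_mode = c("continuous", "poisson"),
                           gap_every = NULL, gap_length = 1L, seed = NULL) {
  generator <- match.arg(generator)
  count_mode <- match.arg(count_mode)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be >= 2")
  if (generator == "fgn") {
    if (is.null(hurst) || hurst <= 0 || hurst >= 1)
      stop("fgn generator requires 'hurst' in (0, 1)")
  }
  if (generator == "spectral") {
    if (is.null(spectral_beta) || spectral_beta < 0)
      stop("spectral generator requires 'spectral_beta' >= 0")
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (circadian_amplitude < 0) stop("'circadian_amplitude' must be >= 0")
  if (generator == "invitro_like" && circadian_amplitude == 0)
    stop("invitro_like requires circadian_amplitude > 0")
  if (!is.null(gap_every)) {
    gap_every <- as.integer(gap_every); gap_length <- as.integer(gap_length)
    if (gap_every < 2L || gap_length < 1L || gap_length >= gap_every)
      stop("gap pattern requires 1 <= gap_length < gap_every")
  }
  structure(list(generator = generator, n_bins = n_bins, bin_width = bin_width,
                 hurst = hurst, spectral_beta = spectral_beta,
                 circadian_amplitude = circadian_amplitude,
                 circadian_period = circadian_period,
                 circadian_phase = circadian_phase, baseline = baseline,
                 noise_sd = noise_sd, count_mode = count_mode,
                 gap_every = gap_every, gap_length = gap_length, seed = seed),
            class = "synthetic_spec")
}

# Exact fractional Gaussian noise by circulant embedding (Davies-Harte).
# Returns n values with unit variance and autocovariance
# g(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) / 2.
fgn_circulant <- function(n, H) {
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(g, rev(g[2:n]))          # length 2n
  lam <- Re(stats::fft(circ))
  if (min(lam) < -1e-8 * max(lam))
    stop("circulant embedding not non-negative definite")  # cannot occur for fGn
  lam[lam < 0] <- 0
  m <- 2L * n
  v <- stats::rnorm(m)
  w <- complex(length.out = m)
  w[1] <- sqrt(lam[1] / m) * v[1]
  w[n + 1] <- sqrt(lam[n + 1] / m) * v[n + 1]
  i <- 2:n
  w[i] <- sqrt(lam[i] / (2 * m)) * complex(real = v[i], imaginary = v[m + 2 - i])
  w[m + 2 - i] <- Conj(w[i])
  Re(stats::fft(w))[seq_len(n)]
}

# 1/f^beta noise by Fourier synthesis with random phases, normalized to
# unit sample standard deviation (DFA is amplitude-invariant).
spectral_noise <- function(n, beta) {
  nf <- n %/% 2L
  amp <- (1:nf)^(-beta / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- amp * exp(1i * ph)
  if (n %% 2L == 0L) {
    spec[nf + 1] <- amp[nf] * cos(ph[nf]) # Nyquist bin must be real
    spec[n:(nf + 2)] <- Conj(spec[2:nf])
  } else {
    spec[n:(nf + 2)] <- Conj(spec[2:(nf + 1)])
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic binned series from a spec
#'
#' @param spec a [synthetic_spec()].
#' @param condition condition label for the output series.
#' @return a [binned_series()] of length `spec$n_bins`, bit-identical across
#'   runs for identical spec and seed. The resolved spec is attached as
#'   attribute `"spec"`; under `count_mode = "poisson"` the latent-rate shift
#'   applied is recorded there too.
#' @export
generate_mua <- function(spec, condition = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_bins
    x <- switch(spec$generator,
      white = ,
      invitro_like = stats::rnorm(n) * spec$noise_sd,
      brownian = cumsum(stats::rnorm(n)) * spec$noise_sd,
      fgn = fgn_circulant(n, spec$hurst) * spec$noise_sd,
      spectral = spectral_noise(n, spec$spectral_beta) * spec$noise_sd)
    if (spec$circadian_amplitude > 0) {
      t_h <- (seq_len(n) - 1) * spec$bin_width / 3600
      x <- x + spec$circadian_amplitude *
        cos(2 * pi * (t_h - spec$circadian_phase) / spec$circadian_period)
    }
    x <- x + spec$baseline
    if (spec$count_mode == "poisson") {
      if (any(x < 0))
        stop("negative Poisson rate: raise 'baseline' so all rates are >= 0")
      x <- stats::rpois(n, x)
    }
    miss <- rep(FALSE, n)
    if (!is.null(spec$gap_every)) {
      pos <- (seq_len(n) - 1L) %% spec$gap_every
      miss <- pos >= (spec$gap_every - spec$gap_length)
    }
    x[miss] <- NA_real_
    out <- binned_series(x, spec$bin_width, missing = miss,
                         condition = condition,
                         nonneg = spec$count_mode == "poisson")
    attr(out, "spec") <- spec
    out
  })
}

#' Shuffle surrogate of a series
#'
#' Uniformly random permutation of the counts: the value distribution is
#' preserved exactly while all temporal correlations are destroyed, so the
#' surrogate of any long-range-correlated series has DFA exponent 0.5.
#'
#' @param x a gap-free `binned_series`.
#' @param seed integer RNG seed.
#' @return a `binned_series` with permuted counts.
#' @export
shuffle_surrogate <- function(x, seed = NULL) {
  stopifnot(inherits(x, "binned_series"))
  if (any(x$missing))
    stop("shuffle surrogate requires a gap-free series")
  with_seed(seed, {
    binned_series(sample(x$counts), x$bin_width, start_time = x$start_time,
                  condition = x$condition, schedule = x$schedule,
                  nonneg = FALSE)
  })
}

#' Simulate an amplitude-marked spike event stream
#'
#' Inhomogeneous Poisson process whose intensity is piecewise constant over
#' the bins of `rate_profile` (counts interpreted as mean firing rate in Hz),
#' with independent log-normal amplitude marks. The action-potential
#' amplitude distribution of real recordings is unknown; log-normal is a
#' synthetic stand-in.
#'
#' @param rate_profile a `binned_series` of non-negative rates (Hz); missing
#'   bins contribute no events.
#' @param meanlog,sdlog log-normal amplitude parameters.
#' @param seed integer RNG seed.
#' @return an [event_stream()]. Expected event count equals
#'   `sum(rate * bin_width)` over observed bins.
#' @export
generate_event_stream <- function(rate_profile, meanlog = 0, sdlog = 1,
                                  seed = NULL) {
  stopifnot(inherits(rate_profile, "binned_series"))
  r <- rate_profile$counts
  r[rate_profile$missing] <- 0
  if (any(r < 0)) stop("rates must be non-negative")
  with_seed(seed, {
    bw <- rate_profile$bin_width
    n_ev <- stats::rpois(length(r), r * bw)
    t0 <- bin_times(rate_profile)
    times <- sort(unlist(lapply(which(n_ev > 0), function(i)
      t0[i] + stats::runif(n_ev[i]) * bw)))
    amps <- stats::rlnorm(length(times), meanlog, sdlog)
    if (length(times) == 0)
      return(structure(list(times = numeric(0), amplitudes = numeric(0)),
                       class = "event_stream"))
    event_stream(times, amps)
  })
}
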