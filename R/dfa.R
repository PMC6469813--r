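#' Detrended fluctuation analysis
#'
#' Estimates the self-similarity exponent `alpha` of a univariate series.
#' The series is mean-subtracted and integrated (the "profile"); for each
#' window size `n` the profile is split into non-overlapping windows (a
#' trailing partial window is discarded), a polynomial trend of order
#' `detrend_order` is removed per window, and `F(n)` is the RMS of the
#' pooled residuals. `alpha` is the least-squares slope of
#' `log10 F(n)` vs `log10 n` restricted to `fit_range`.
#'
#' Interpretation at 1 kHz sampling: `alpha ~ 0.5` for uncorrelated
#' fluctuations, `0.5 < alpha < 1` long-range temporal correlations,
#' `alpha = 1` for 1/f noise, `alpha ~ 1.5` for a random walk; for a power
#' spectrum `S(f) ~ 1/f^v` the exponents are related by `v = 2*alpha - 1`.
#'
#' @param series Numeric series (samples at `dt` ms spacing; population
#'   activity `A(t)` or any univariate signal).
#' @param window_sizes Window sizes in samples. Default: 20 log-spaced
#'   values per decade between 100 and 20000.
#' @param detrend_order Polynomial detrending order (default 1, DFA-1).
#' @param fit_range Two-element range (samples = ms at 1 kHz) over which the
#'   exponent is fitted; default 4--14 s.
#' @return Object of class `cros_dfa`: list with `window_sizes`, `F`,
#'   `alpha`, `fit_range`, `detrend_order`.
#' @examples
#' x <- rnorm(2^14)
#' d <- dfa(x, window_sizes = dfa_windows(100, 4000), fit_range = c(100, 4000))
#' d$alpha # close to 0.5
#' @export
dfa <- function(series, window_sizes = dfa_windows(),
                detrend_order = 1L, fit_range = c(4000, 14000)) {
  series <- as.numeric(series)
  window_sizes <- sort(unique(as.integer(window_sizes)))
  window_sizes <- window_sizes[window_sizes >= detrend_order + 2L]
  n_tot <- length(series)
  window_sizes <- window_sizes[window_sizes <= n_tot %/% 4L]
  if (length(window_sizes) < 2L)
    stop("series too short for the requested window sizes")
  prof <- cumsum(series - mean(series))
  F_n <- vapply(window_sizes, function(n) .dfa_fluct(prof, n, detrend_order),
                numeric(1))
  in_fit <- window_sizes >= fit_range[1] & window_sizes <= fit_range[2]
  if (sum(in_fit) < 2L)
    stop("fewer than 2 window sizes inside the fit range")
  fit <- stats::lm.fit(cbind(1, log10(window_sizes[in_fit])),
                       log10(F_n[in_fit]))
  structure(list(window_sizes = window_sizes, F = F_n,
                 alpha = unname(fit$coefficients[2]),
                 fit_range = fit_range, detrend_order = detrend_order),
            class = "cros_dfa")
}

#' Log-spaced DFA window sizes
#'
#' @param min_size,max_size Smallest and largest window (samples).
#' @param per_decade Number of window sizes per decade (default 20).
#' @return Integer vector of unique window sizes.
#' @export
dfa_windows <- function(min_size = 100, max_size = 20000, per_decade = 20) {
  n_dec <- log10(max_size / min_size)
  sizes <- min_size * 10^(seq(0, n_dec, by = 1 / per_decade))
  unique(as.integer(round(sizes)))
}

# RMS fluctuation at one window size: vectorised per-window polynomial
# detrending (order 0, 1 via closed forms; higher orders via a shared
# projection since the design matrix is identical across windows).
.dfa_fluct <- function(prof, n, order) {
  m <- length(prof) %/% n
  Y <- matrix(prof[seq_len(m * n)], nrow = n)
  if (order == 0L) {
    res <- Y - matrix(colMeans(Y), nrow = n, ncol = m, byrow = TRUE)
  } else if (order == 1L) {
    t_c <- seq_len(n) - (n + 1) / 2      # centred time, mean zero
    stt <- sum(t_c^2)
    slope <- as.numeric(crossprod(t_c, Y)) / stt
    res <- Y - matrix(colMeans(Y), nrow = n, ncol = m, byrow = TRUE) -
      outer(t_c, slope)
  } else {
    X <- stats::poly(seq_len(n), degree = order)
    X <- cbind(1, X)
    Q <- qr.Q(qr(X))
    res <- Y - Q %*% crossprod(Q, Y)
  }
  sqrt(mean(res^2))
}

#' @exportS3Method base::print
print.cros_dfa <- function(x, ...) {
  cat(sprintf("DFA-%d: alpha = %.3f (fit range %g-%g samples, %d window sizes)\n",
              x$detrend_order, x$alpha, x$fit_range[1], x$fit_range[2],
              length(x$window_sizes)))
  invisible(x)
}

#' Alpha-band amplitude envelope
#'
#' Zero-phase band-pass filtering with the squared magnitude response of a
#' Butterworth design (default 5th order, 8--16 Hz at 1 kHz sampling),
#' followed by the amplitude envelope, i.e. the modulus of the analytic
#' signal obtained from the Hilbert transform. The filter is applied in
#' the frequency domain: multiplying the spectrum by `|H(f)|^2` with zero
#' phase is the exact counterpart of forward--backward (filtfilt)
#' application of the recursive design, without the coefficient round-off
#' that high-order narrow-band recursive realizations suffer. Output
#' length equals input length; trim the edges (see `trim_ms` in
#' [dfa_band()]) before estimating scaling exponents, since the envelope
#' is distorted near the ends.
#'
#' @param series Numeric series sampled at `fs` Hz.
#' @param band_hz Pass band in Hz (default `c(8, 16)`).
#' @param filter_order Butterworth order (default 5).
#' @param fs Sampling rate in Hz (default 1000).
#' @return Numeric envelope series of the same length.
#' @examples
#' x <- sin(2 * pi * 12 * (0:9999) / 1000)
#' env <- band_envelope(x)
#' mean(env[2000:8000]) # close to 1
#' @export
band_envelope <- function(series, band_hz = c(8, 16), filter_order = 5L,
                          fs = 1000) {
  series <- as.numeric(series)
  nyq <- fs / 2
  if (band_hz[1] <= 0 || band_hz[2] >= nyq || band_hz[1] >= band_hz[2])
    stop("pass band must lie strictly inside (0, Nyquist)")
  n <- length(series)
  k <- 0:(n - 1)
  f <- abs(ifelse(k <= n / 2, k, k - n)) * fs / n
  # squared Butterworth band-pass magnitude (forward + backward pass)
  g2 <- .butter_bandpass_gain2(f, band_hz, filter_order)
  filtered <- Re(stats::fft(stats::fft(series) * g2, inverse = TRUE)) / n
  Mod(.analytic_signal(filtered))
}

# |H(f)|^2 of the analog Butterworth band-pass prototype of given order:
# 1 / (1 + ((f^2 - f1 f2) / (f (f2 - f1)))^(2 order)); exactly 1 at the
# centre frequency sqrt(f1 f2), 1/4 (two passes) at the band edges
.butter_bandpass_gain2 <- function(f, band_hz, order) {
  f1 <- band_hz[1]; f2 <- band_hz[2]
  x <- ifelse(f > 0, (f^2 - f1 * f2) / (pmax(f, .Machine$double.eps) *
                                          (f2 - f1)), Inf)
  1 / (1 + x^(2 * order))
}

# Analytic signal via the frequency-domain construction: double positive
# frequencies, zero negative ones (Nyquist/DC kept), inverse transform.
.analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' DFA of the band-filtered amplitude envelope
#'
#' Convenience composition used on the population activity: band-pass the
#' series ([band_envelope()]), trim `trim_ms` from each end, then run
#' [dfa()] on the envelope.
#'
#' @inheritParams dfa
#' @inheritParams band_envelope
#' @param trim_ms Samples (ms at 1 kHz) discarded from each end of the
#'   envelope before DFA, to suppress filter edge effects.
#' @return A `cros_dfa` object with `variant = "band_envelope"`.
#' @export
dfa_band <- function(series, band_hz = c(8, 16), filter_order = 5L,
                     fs = 1000, trim_ms = 1000,
                     window_sizes = dfa_windows(), detrend_order = 1L,
                     fit_range = c(4000, 14000)) {
  env <- band_envelope(series, band_hz, filter_order, fs)
  if (2 * trim_ms >= length(env)) stop("series too short to trim edges")
  env <- env[(trim_ms + 1):(length(env) - trim_ms)]
  out <- dfa(env, window_sizes, detrend_order, fit_range)
  out$variant <- "band_envelope"
  out
}
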