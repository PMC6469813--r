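#' Smoothed power spectrum of the population activity
#'
#' FFT periodogram of `A(t)`, normalized by the network size (`L^2`) and
#' the total simulated time, then smoothed by averaging over nonoverlapping
#' blocks of `smooth_bins` consecutive raw frequency bins (500 bins of
#' ~9e-4 Hz each for a `2^20` ms trace, i.e. one smoothed point every
#' ~0.45 Hz). The DC bin is excluded before smoothing. Each smoothed point
#' also carries the within-block standard error, used by
#' [order_parameter()] to decide whether a spectral peak is significant.
#'
#' @param trace A `cros_trace`, or a numeric series (then `L` defaults to 1
#'   and `fs` gives the sampling rate).
#' @param smooth_bins Raw bins per smoothing block (default 500).
#' @param fs Sampling rate in Hz (default 1000; ignored when `trace` is a
#'   `cros_trace`, whose `dt` defines it).
#' @param L Network side used in the normalization (taken from the trace
#'   when available).
#' @return Object of class `cros_spectrum`: list with `freq` (Hz, block
#'   centres), `power`, `se` (block standard errors), `df_raw` (raw bin
#'   width, Hz), `smooth_bins`.
#' @examples
#' x <- oscillatory_signal(10, amp = 2, noise_sd = 1, n = 2^16, seed = 1)
#' sp <- power_spectrum(x, smooth_bins = 50)
#' sp$freq[which.max(sp$power)] # close to 10 Hz
#' @export
power_spectrum <- function(trace, smooth_bins = 500L, fs = 1000, L = 1L) {
  if (inherits(trace, "cros_trace")) {
    A <- as.numeric(trace$A)
    fs <- 1000 / trace$dt
    L <- trace$L
  } else {
    A <- as.numeric(trace)
  }
  n <- length(A)
  if (n < 2L * smooth_bins)
    stop("trace shorter than one smoothing block")
  total_time <- n / fs
  raw <- Mod(stats::fft(A))^2 / (L^2 * total_time)
  df <- fs / n
  # positive-frequency bins, DC excluded
  n_pos <- n %/% 2
  raw <- raw[2:(n_pos + 1)]
  m <- n_pos %/% smooth_bins
  idx <- matrix(seq_len(m * smooth_bins), nrow = smooth_bins)
  power <- colMeans(matrix(raw[idx], nrow = smooth_bins))
  sds <- apply(matrix(raw[idx], nrow = smooth_bins), 2, stats::sd)
  freq <- (colMeans(matrix(seq_len(m * smooth_bins), nrow = smooth_bins))) * df
  structure(list(freq = freq, power = power,
                 se = sds / sqrt(smooth_bins),
                 df_raw = df, smooth_bins = as.integer(smooth_bins)),
            class = "cros_spectrum")
}

#' @exportS3Method base::print
print.cros_spectrum <- function(x, ...) {
  cat(sprintf("Smoothed spectrum: %d points, %.3g-%.3g Hz (%.3g Hz spacing)\n",
              length(x$freq), min(x$freq), max(x$freq),
              x$freq[2] - x$freq[1]))
  invisible(x)
}

#' Spectral order parameter of the oscillation peak
#'
#' Quantifies how much spectral mass is concentrated in the oscillation
#' peak. The peak frequency `f_peak` is the argmax of the smoothed spectrum
#' within `search_band`; `f_minus` is the nearest local minimum below the
#' peak inside `minimum_band` (first sign change of the discrete derivative
#' moving down-frequency, ties toward higher frequency); the upper bound is
#' the symmetric reflection `f_plus = f_peak + (f_peak - f_minus)`. A chord
#' is drawn between the spectrum values at `f_minus` and `f_plus`; the area
#' of the spectrum above the chord is `phi_p`, the area under the chord is
#' `phi_u` (trapezoidal quadrature), and the order parameter is
#' `phi = phi_p / (phi_p + phi_u)`. When no qualifying peak exists --- the
#' argmax does not exceed the chord by at least `peak_z` local standard
#' errors, or no local minimum is found --- `phi = 0`.
#'
#' @param spectrum A [power_spectrum()] result.
#' @param search_band Peak search band, Hz (default 4--45).
#' @param minimum_band Band searched for the local minimum below the peak,
#'   Hz (default 4--18).
#' @param peak_z Peak qualification: required excess of the peak over the
#'   chord in units of the local smoothed-spectrum standard error.
#' @return Object of class `cros_orderparam`: list with `phi`, `f_minus`,
#'   `f_peak`, `f_plus`, `phi_p`, `phi_u`, `peak_found`.
#' @export
order_parameter <- function(spectrum, search_band = c(4, 45),
                            minimum_band = c(4, 18), peak_z = 2) {
  stopifnot(inherits(spectrum, "cros_spectrum"))
  f <- spectrum$freq
  p <- spectrum$power
  no_peak <- structure(list(phi = 0, f_minus = NA_real_, f_peak = NA_real_,
                            f_plus = NA_real_, phi_p = 0, phi_u = 0,
                            peak_found = FALSE),
                       class = "cros_orderparam")
  sel <- which(f >= search_band[1] & f <= search_band[2])
  if (length(sel) < 3) return(no_peak)
  i_peak <- sel[which.max(p[sel])]
  f_peak <- f[i_peak]
  # walk down-frequency from the peak to the first local minimum inside
  # the minimum band (ties broken toward higher frequency by taking the
  # first index where the derivative changes sign)
  i_min <- NA_integer_
  i <- i_peak - 1L
  while (i >= 2L && f[i] >= minimum_band[1]) {
    if (f[i] <= minimum_band[2] && p[i - 1L] >= p[i] && p[i] <= p[i + 1L]) {
      i_min <- i
      break
    }
    i <- i - 1L
  }
  if (is.na(i_min) && i == 1L && f[1] <= minimum_band[2] &&
      f[1] >= minimum_band[1] && p[1] <= p[2]) {
    i_min <- 1L
  }
  if (is.na(i_min)) return(no_peak)
  f_minus <- f[i_min]
  f_plus <- f_peak + (f_peak - f_minus)
  if (f_plus > max(f)) {
    warning("symmetric upper bound beyond the spectrum range; clipped")
    f_plus <- max(f)
  }
  in_band <- which(f >= f_minus & f <= f_plus)
  if (length(in_band) < 3) return(no_peak)
  fb <- f[in_band]
  pb <- p[in_band]
  chord <- p[i_min] + (pb[length(pb)] - p[i_min]) * (fb - f_minus) /
    (fb[length(fb)] - f_minus)
  # peak significance: excess over the chord at the argmax, in units of
  # the typical (median) within-block standard error across the band --
  # the peak block's own SE is inflated when the peak is narrow
  excess <- p[i_peak] - chord[which(in_band == i_peak)]
  se_band <- stats::median(spectrum$se[in_band])
  if (length(excess) == 0 || excess < peak_z * se_band)
    return(no_peak)
  phi_p <- .trapz(fb, pmax(pb - chord, 0))
  phi_u <- .trapz(fb, chord)
  phi <- phi_p / (phi_p + phi_u)
  structure(list(phi = phi, f_minus = f_minus, f_peak = f_peak,
                 f_plus = f_plus, phi_p = phi_p, phi_u = phi_u,
                 peak_found = TRUE),
            class = "cros_orderparam")
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' @exportS3Method base::print
print.cros_orderparam <- function(x, ...) {
  if (x$peak_found) {
    cat(sprintf("Order parameter phi = %.4f (f- = %.2f, fp = %.2f, f+ = %.2f Hz)\n",
                x$phi, x$f_minus, x$f_peak, x$f_plus))
  } else {
    cat("Order parameter phi = 0 (no qualifying spectral peak)\n")
  }
  invisible(x)
}
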