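#' Bounded power-law distribution functions
#'
#' Density, cumulative distribution and inverse-CDF sampling for the
#' continuous power law `P(x) = C * x^-mu` restricted to `[x_min, x_max]`,
#' with `C = (mu - 1) / (x_min^(1 - mu) - x_max^(1 - mu))` and cumulative
#' `F(h) = (h^(1 - mu) - x_min^(1 - mu)) / (x_max^(1 - mu) - x_min^(1 - mu))`.
#' These closed forms are the reference distributions of the
#' [kappa_index()].
#'
#' @param x,q Evaluation points.
#' @param mu Exponent, `> 1`.
#' @param x_min,x_max Support bounds, `x_max > x_min > 0`.
#' @return Density / probability values.
#' @name bounded_powerlaw
NULL

#' @rdname bounded_powerlaw
#' @export
dbounded_powerlaw <- function(x, mu, x_min, x_max) {
  .check_bpl(mu, x_min, x_max)
  C <- (mu - 1) / (x_min^(1 - mu) - x_max^(1 - mu))
  ifelse(x >= x_min & x <= x_max, C * x^(-mu), 0)
}

#' @rdname bounded_powerlaw
#' @export
pbounded_powerlaw <- function(q, mu, x_min, x_max) {
  .check_bpl(mu, x_min, x_max)
  denom <- x_max^(1 - mu) - x_min^(1 - mu)
  p <- (pmin(pmax(q, x_min), x_max)^(1 - mu) - x_min^(1 - mu)) / denom
  pmin(pmax(p, 0), 1)
}

.check_bpl <- function(mu, x_min, x_max) {
  if (mu <= 1) stop("'mu' must be > 1")
  if (!(x_max > x_min && x_min > 0)) stop("need x_max > x_min > 0")
  invisible(TRUE)
}

#' Sample a bounded power law by inverse-CDF
#'
#' @inheritParams bounded_powerlaw
#' @param n Sample size.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param plotting_positions If `TRUE`, return the deterministic
#'   inverse-CDF quantiles at positions `(i - 0.5) / n` instead of random
#'   draws (a sample whose empirical CDF matches the theoretical one up to
#'   the `1/n` staircase; used for exact kappa identities).
#' @return Numeric vector of length `n` in `[x_min, x_max]`.
#' @export
sample_bounded_powerlaw <- function(mu, x_min, x_max, n, seed = NULL,
                                    plotting_positions = FALSE) {
  .check_bpl(mu, x_min, x_max)
  u <- if (plotting_positions) {
    (seq_len(n) - 0.5) / n
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats::runif(n)
  }
  a <- x_min^(1 - mu)
  bb <- x_max^(1 - mu)
  (a + u * (bb - a))^(1 / (1 - mu))
}

#' Sample an exponentially truncated power law
#'
#' Draws from `P(x) ~ x^-mu * exp(-x / x0)` on `x >= x_min` by rejection
#' sampling with a pure power-law proposal (acceptance probability
#' `exp(-(x - x_min) / x0)`, so the acceptance rate is tracked and
#' pathological settings abort). Requires `mu > 1` (the proposal must be
#' normalizable); `x0 = Inf` reduces to the pure power law.
#'
#' @param mu Power-law exponent, `> 1`.
#' @param x0 Exponential cutoff scale, `> 0` (may be `Inf`).
#' @param x_min Lower support bound, `> 0`.
#' @param n Sample size.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of length `n`, with attribute `acceptance_rate`.
#' @export
sample_truncated_powerlaw <- function(mu, x0, x_min, n, seed = NULL) {
  if (mu <= 1) stop("'mu' must be > 1 for the power-law proposal")
  if (x0 <= 0) stop("'x0' must be > 0")
  if (x_min <= 0) stop("'x_min' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(0)
  proposed <- 0
  accepted <- 0
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 1000L)
    x <- x_min * stats::runif(m)^(1 / (1 - mu))   # pure power-law proposal
    keep <- if (is.finite(x0)) {
      stats::runif(m) < exp(-(x - x_min) / x0)
    } else rep(TRUE, m)
    out <- c(out, x[keep])
    proposed <- proposed + m
    accepted <- accepted + sum(keep)
    if (proposed > 1000 && accepted / proposed < 1e-3)
      stop("rejection acceptance rate below 1e-3; x0 too small relative to x_min")
  }
  out <- out[seq_len(n)]
  attr(out, "acceptance_rate") <- accepted / proposed
  out
}

#' Colored noise by spectral synthesis
#'
#' Generates a Gaussian series whose power spectrum decays as
#' `S(f) ~ 1/f^v`: unit-variance complex Gaussian spectrum shaped by
#' `f^(-v/2)` with random phases, Hermitian-symmetrized, inverse
#' transformed and standardized to zero mean and unit variance. The DFA
#' exponent of the result obeys `v = 2*alpha - 1`.
#'
#' @param v Spectral exponent in `[0, 2]` (`0` = white noise, `1` = 1/f).
#' @param n Series length.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Standardized numeric series of length `n`.
#' @export
colored_noise <- function(v, n, seed = NULL) {
  if (v < 0 || v > 2) stop("'v' must lie in [0, 2]")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  n_pos <- n %/% 2
  f <- seq_len(n_pos) / n                 # positive frequencies (cycles/sample)
  amp <- f^(-v / 2)
  z <- (stats::rnorm(n_pos) + 1i * stats::rnorm(n_pos)) / sqrt(2) * amp
  spec <- complex(length.out = n)
  spec[2:(n_pos + 1)] <- z
  if (n %% 2 == 0) {
    spec[n_pos + 1] <- sqrt(2) * Re(z[n_pos]) # Nyquist bin must be real
    if (n_pos > 1) spec[n:(n_pos + 2)] <- Conj(z[seq_len(n_pos - 1)])
  } else {
    spec[n:(n_pos + 2)] <- Conj(z)
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Oscillatory test signal
#'
#' Sinusoid of frequency `f0` (Hz) and amplitude `amp` plus white Gaussian
#' noise; fixture for the spectral-peak and order-parameter analyses.
#'
#' @param f0 Carrier frequency, Hz.
#' @param amp Sinusoid amplitude (0 gives a peakless noise fixture).
#' @param noise_sd White-noise standard deviation.
#' @param n Series length (samples at `fs` Hz).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param fs Sampling rate, Hz.
#' @return Numeric series of length `n`.
#' @export
oscillatory_signal <- function(f0, amp, noise_sd, n, seed = NULL, fs = 1000) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  amp * sin(2 * pi * f0 * t) + stats::rnorm(n, sd = noise_sd)
}

#' Synthetic avalanche-profile family with known collapse exponent
#'
#' Builds mean-profile families obeying the shape-collapse scaling
#' `s(t, T) = T^(gamma0 - 1) * F(t / T)` with the parabolic scaling
#' function `F(u) = 4 u (1 - u)`, optionally corrupted by multiplicative
#' lognormal noise. Returns a catalog-like object usable by
#' [shape_collapse()] and [mean_size_vs_duration()]; the ground truth
#' `gamma0` equals the `1/(sigma nu z)` exponent the analyses should
#' recover.
#'
#' @param gamma0 Collapse exponent (`> 1`).
#' @param durations Integer event durations (steps).
#' @param noise_sd Standard deviation of multiplicative lognormal noise on
#'   profile values (0 = noiseless).
#' @param samples_per_T Events generated per duration.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `cros_catalog` with `events`, `profiles` and `theta = 0`.
#' @export
profile_family <- function(gamma0, durations, noise_sd = 0,
                           samples_per_T = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  durations <- as.integer(durations)
  profiles <- list()
  rows <- list()
  k <- 0L
  t_cursor <- 1L
  for (T_i in durations) {
    u <- (seq_len(T_i) - 0.5) / T_i
    base <- T_i^(gamma0 - 1) * 4 * u * (1 - u)
    for (s in seq_len(samples_per_T)) {
      prof <- base
      if (noise_sd > 0)
        prof <- prof * stats::rlnorm(T_i, meanlog = -noise_sd^2 / 2,
                                     sdlog = noise_sd)
      k <- k + 1L
      profiles[[k]] <- prof
      rows[[k]] <- data.frame(t_i = t_cursor, t_f = t_cursor + T_i,
                              T = T_i, s_g = sum(prof), s_theta = sum(prof))
      t_cursor <- t_cursor + T_i + 1L
    }
  }
  structure(list(events = do.call(rbind, rows), profiles = profiles,
                 theta = 0, n_censored = 0L),
            class = "cros_catalog")
}
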