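#' Avalanche detection threshold
#'
#' The threshold is a fraction `Gamma` of the median population activity,
#' `theta = Gamma * median(A)`, computed over the full trace with zeros
#' included (per realization, not pooled). The original model convention is
#' `Gamma = 0.5`. A zero median (deeply subcritical regime) yields
#' `theta = 0` with a warning, since every positive-activity step then
#' counts as supra-threshold.
#'
#' @param trace A `cros_trace` or a numeric activity series.
#' @param gamma Positive threshold fraction `Gamma`.
#' @return Scalar threshold in activity units.
#' @examples
#' compute_threshold(c(0, 2, 4, 2, 0), gamma = 0.5) # 1
#' @export
compute_threshold <- function(trace, gamma = 0.5) {
  A <- if (inherits(trace, "cros_trace")) trace$A else as.numeric(trace)
  if (length(A) == 0) stop("empty trace")
  if (gamma <= 0) stop("'gamma' must be > 0")
  med <- stats::median(A)
  if (med == 0) {
    warning("median activity is zero: threshold degenerates to 0 (subcritical regime)")
    return(0)
  }
  gamma * med
}

#' Extract neuronal avalanches from an activity trace
#'
#' An avalanche is a maximal run of consecutive steps with `A(t) > theta`
#' (strict). For an event starting at the first supra-threshold step `t_i`
#' and ending at `t_f`, the first subsequent step with `A <= theta`:
#' duration `T = t_f - t_i` (ms at 1 ms steps), size `s_g = sum(A)` over
#' `[t_i, t_f)` (total spikes) and `s_theta = sum(A - theta)` (area above
#' the threshold). Events still open at either trace boundary are censored
#' and discarded (counted in `n_censored`).
#'
#' @param trace A `cros_trace` or numeric activity series.
#' @param theta Threshold, `>= 0` (see [compute_threshold()]).
#' @param keep_profiles If `TRUE` (default) keep each event's per-step
#'   activity profile, required for shape collapse.
#' @return Object of class `cros_catalog`: list with `events` (data frame
#'   with columns `t_i`, `t_f`, `T`, `s_g`, `s_theta`), `profiles` (list of
#'   numeric vectors, or `NULL`), `theta`, `n_censored`.
#' @examples
#' cat <- extract_avalanches(c(0, 0, 3, 5, 2, 0, 0), theta = 1.5)
#' cat$events # one event: T = 3, s_g = 10, s_theta = 5.5
#' @export
extract_avalanches <- function(trace, theta, keep_profiles = TRUE) {
  A <- if (inherits(trace, "cros_trace")) trace$A else as.numeric(trace)
  if (theta < 0) stop("'theta' must be >= 0")
  above <- A > theta
  n <- length(A)
  empty <- data.frame(t_i = integer(0), t_f = integer(0), T = integer(0),
                      s_g = numeric(0), s_theta = numeric(0))
  if (!any(above)) {
    return(structure(list(events = empty,
                          profiles = if (keep_profiles) list() else NULL,
                          theta = theta, n_censored = 0L),
                     class = "cros_catalog"))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sup <- which(r$values)
  t_i <- starts[sup]
  t_f <- ends[sup] + 1L                 # first step back at or below theta
  # censored: event touching either boundary of the trace
  cens <- t_i == 1L | ends[sup] == n
  n_censored <- sum(cens)
  t_i <- t_i[!cens]; t_f <- t_f[!cens]
  if (length(t_i) == 0) {
    return(structure(list(events = empty,
                          profiles = if (keep_profiles) list() else NULL,
                          theta = theta, n_censored = n_censored),
                     class = "cros_catalog"))
  }
  cs <- c(0, cumsum(as.numeric(A)))
  s_g <- cs[t_f] - cs[t_i]
  dur <- t_f - t_i
  events <- data.frame(t_i = t_i, t_f = t_f, T = dur,
                       s_g = s_g, s_theta = s_g - dur * theta)
  profiles <- NULL
  if (keep_profiles)
    profiles <- lapply(seq_along(t_i),
                       function(k) A[t_i[k]:(t_f[k] - 1L)])
  structure(list(events = events, profiles = profiles, theta = theta,
                 n_censored = n_censored),
            class = "cros_catalog")
}

#' @exportS3Method base::print
print.cros_catalog <- function(x, ...) {
  cat(sprintf("Avalanche catalog: %d events (theta = %.4g, %d censored)\n",
              nrow(x$events), x$theta, x$n_censored))
  if (nrow(x$events) > 0)
    cat(sprintf("  T: %d-%d ms; s_theta: %.3g-%.3g\n",
                min(x$events$T), max(x$events$T),
                min(x$events$s_theta), max(x$events$s_theta)))
  invisible(x)
}

#' Kappa scale-invariance index
#'
#' Compares the empirical cumulative distribution of a sample restricted to
#' `[x_min, x_max]` with the cumulative of the bounded power law
#' `P(x) ~ x^-mu` on the same interval, at `b` logarithmically spaced
#' points `h_j`:
#' `kappa = 1 + (1/b) * sum_j (F_th(h_j) - F_obs(h_j))`.
#' `kappa ~ 1` indicates agreement with the power law, `kappa < 1` a
#' subcritical (e.g. exponential-like) distribution and `kappa > 1` a
#' supercritical distribution with excess mass at large `x`.
#'
#' @param sample Positive values (avalanche sizes or durations).
#' @param mu Reference power-law exponent, `> 1` (e.g. directed-percolation
#'   values: mean-field `tau = 1.5`, `tau_t = 2`; two-dimensional
#'   `tau = 1.268`, `tau_t = 1.450`).
#' @param x_min,x_max Restriction interval, `x_max > x_min > 0`.
#' @param b Number of log-spaced evaluation points (default 10).
#' @return Scalar `kappa`.
#' @examples
#' x <- sample_bounded_powerlaw(1.5, 1, 1000, n = 1e4, seed = 1)
#' kappa_index(x, mu = 1.5, x_min = 1, x_max = 1000) # close to 1
#' @export
kappa_index <- function(sample, mu, x_min, x_max, b = 10L) {
  if (mu <= 1) stop("'mu' must be > 1")
  if (!(x_max > x_min && x_min > 0)) stop("need x_max > x_min > 0")
  x <- sample[sample >= x_min & sample <= x_max]
  if (length(x) == 0) stop("no sample values inside [x_min, x_max]")
  h <- exp(seq(log(x_min), log(x_max), length.out = b))
  F_th <- pbounded_powerlaw(h, mu, x_min, x_max)
  F_obs <- vapply(h, function(hh) mean(x < hh), numeric(1))
  1 + mean(F_th - F_obs)
}
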