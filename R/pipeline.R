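#' Full criticality-analysis battery for one trace
#'
#' Runs the complete per-trace analysis: spectral order parameter, DFA of
#' the raw and band-filtered activity, avalanche extraction at each
#' threshold fraction in `gamma_list`, kappa indices against the mean-field
#' and two-dimensional directed-percolation exponents, truncated power-law
#' MLE fits with loglikelihood-ratio comparisons for sizes and durations,
#' and the size-duration scaling / shape-collapse / crackling-relation
#' tests.
#'
#' @param trace A `cros_trace`.
#' @param gamma_list Threshold fractions `Gamma` to analyse (default 0.5).
#' @param s_min,T_min Fixed MLE lower bounds for sizes and durations.
#' @param run_dfa,run_spectrum,run_scaling Toggles for the costlier stages.
#' @return A list with elements `summary` (one-row data frame per `Gamma`)
#'   and `details` (per-`Gamma` list of the underlying fit objects).
#' @export
analyze_trace <- function(trace, gamma_list = 0.5, s_min = 10, T_min = 4,
                          run_dfa = TRUE, run_spectrum = TRUE,
                          run_scaling = TRUE) {
  stopifnot(inherits(trace, "cros_trace"))
  phi <- f_peak <- alpha_raw <- alpha_band <- NA_real_
  if (run_spectrum) {
    sp <- power_spectrum(trace)
    op <- order_parameter(sp)
    phi <- op$phi
    f_peak <- op$f_peak
  }
  if (run_dfa) {
    alpha_raw <- dfa(trace$A)$alpha
    alpha_band <- dfa_band(trace$A)$alpha
  }
  base <- data.frame(mean_A = mean(trace$A), firing_rate = firing_rate(trace),
                     phi = phi, f_peak = f_peak,
                     alpha_raw = alpha_raw, alpha_band = alpha_band)
  rows <- list()
  details <- list()
  for (g in gamma_list) {
    row <- base
    row$gamma <- g
    det <- list()
    theta <- suppressWarnings(compute_threshold(trace, g))
    catal <- extract_avalanches(trace, theta)
    ev <- catal$events
    row$theta <- theta
    row$n_events <- nrow(ev)
    row$tau <- row$tau_t <- row$x0_size <- row$x0_dur <- NA_real_
    row$llr_wins <- NA
    row$kappa_theta_2d <- row$kappa_theta_mf <- NA_real_
    row$kappa_T_2d <- row$kappa_T_mf <- NA_real_
    row$snz_fit <- row$snz_collapse <- NA_real_
    if (nrow(ev) >= 50) {
      kx_max <- stats::quantile(ev$s_theta, 0.99, names = FALSE)
      kt_max <- stats::quantile(ev$T, 0.99, names = FALSE)
      if (kx_max > s_min) {
        row$kappa_theta_2d <- kappa_index(ev$s_theta, 1.268, s_min, kx_max)
        row$kappa_theta_mf <- kappa_index(ev$s_theta, 1.5, s_min, kx_max)
      }
      if (kt_max > T_min) {
        row$kappa_T_2d <- kappa_index(ev$T, 1.450, T_min, kt_max)
        row$kappa_T_mf <- kappa_index(ev$T, 2, T_min, kt_max)
      }
      fit_s <- tryCatch(fit_truncated_powerlaw(ev$s_theta, s_min),
                        error = function(e) NULL)
      fit_T <- tryCatch(fit_truncated_powerlaw(ev$T, T_min),
                        error = function(e) NULL)
      det$fit_size <- fit_s
      det$fit_duration <- fit_T
      if (!is.null(fit_s)) {
        row$tau <- fit_s$mu
        row$x0_size <- fit_s$x0
        row$llr_wins <- all(fit_s$comparisons$R > 0)
      }
      if (!is.null(fit_T)) {
        row$tau_t <- fit_T$mu
        row$x0_dur <- fit_T$x0
      }
      if (run_scaling) {
        szt <- tryCatch(mean_size_vs_duration(catal), error = function(e) NULL)
        col <- tryCatch(shape_collapse(catal), error = function(e) NULL)
        det$size_vs_duration <- szt
        det$collapse <- col
        if (!is.null(szt)) row$snz_fit <- szt$exponent
        if (!is.null(col)) row$snz_collapse <- col$gamma
        if (!is.null(szt) && !is.null(fit_s) && !is.null(fit_T) &&
            fit_s$mu > 1) {
          det$crackling <- crackling_check(fit_s$mu, fit_T$mu, szt$exponent)
        }
      }
    }
    rows[[as.character(g)]] <- row
    details[[as.character(g)]] <- det
  }
  list(summary = do.call(rbind, rows), details = details)
}

#' Parameter sweep over connectivity space
#'
#' Builds and simulates `n_realizations` disordered networks for every
#' `(r_E, r_I)` cell of the grid and runs the full analysis battery on
#' each, producing one tidy row per (cell, `Gamma`, realization). Disorder
#' and dynamics seeds are derived deterministically from `seed_base` so a
#' sweep is fully reproducible from its configuration. Individual cell
#' failures are caught and recorded (`error` column), and the sweep
#' continues.
#'
#' @param grid Data frame with columns `r_E` and `r_I` (one row per cell).
#' @param L,ell Lattice and neighbourhood sides.
#' @param gamma_list Threshold fractions analysed per trace.
#' @param n_realizations Disorder realizations per cell (the reference
#'   protocol averages 5).
#' @param n_steps Steps per simulation (reference protocol: `2^20`).
#' @param seed_base Base seed from which per-cell seeds are derived.
#' @param ... Passed to [analyze_trace()].
#' @return Data frame of class `cros_sweep`; one row per
#'   (cell, realization, `Gamma`), with the analysis summary columns plus
#'   `r_E`, `r_I`, `L`, `ell`, `realization`, `disorder_seed`, `dyn_seed`.
#' @export
run_sweep <- function(grid, L = 50, ell = 7, gamma_list = 0.5,
                      n_realizations = 5, n_steps = 2^20,
                      seed_base = 1L, ...) {
  stopifnot(is.data.frame(grid))
  if (nrow(grid) == 0) {
    out <- data.frame()
    class(out) <- c("cros_sweep", class(out))
    return(out)
  }
  stopifnot(all(c("r_E", "r_I") %in% names(grid)))
  rows <- list()
  for (cell in seq_len(nrow(grid))) {
    for (real in seq_len(n_realizations)) {
      ds <- .derive_seed(seed_base, cell, real, 1L)
      ys <- .derive_seed(seed_base, cell, real, 2L)
      res <- tryCatch({
        net <- build_network(L = L, ell = ell, r_E = grid$r_E[cell],
                             r_I = grid$r_I[cell], seed = ds)
        tr <- simulate_cros(net, n_steps = n_steps, seed = ys)
        analyze_trace(tr, gamma_list = gamma_list, ...)$summary
      }, error = function(e) data.frame(error = conditionMessage(e)))
      res$r_E <- grid$r_E[cell]
      res$r_I <- grid$r_I[cell]
      res$L <- L
      res$ell <- ell
      res$realization <- real
      res$disorder_seed <- ds
      res$dyn_seed <- ys
      rows[[length(rows) + 1L]] <- res
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cros_sweep", class(out))
  out
}

# deterministic, collision-poor seed stream below 2^31
.derive_seed <- function(base, cell, realization, stream) {
  (as.numeric(base) * 2654435761 + cell * 97561 +
     realization * 1299721 + stream * 15485863) %% 2147483629 + 1
}

#' Transition scan along the excitatory-connectivity axis
#'
#' Sweeps `r_E` at fixed `r_I` and summarizes the continuously varying
#' exponents: per-`Gamma` realization-averaged `tau(r_E)` and
#' `tau_t(r_E)` curves, the parametric `(tau, tau_t)` spread with a linear
#' fit, and the Pearson correlation between single-run band-filtered DFA
#' exponents and `tau`. Transition-region membership of a cell is decided
#' by the majority (over realizations) of the loglikelihood-ratio
#' triple-win rule: the truncated power law beats the pure power law,
#' lognormal and exponential alternatives.
#'
#' @param r_E_values Scanned excitatory connectivities.
#' @param r_I Fixed inhibitory connectivity.
#' @inheritParams run_sweep
#' @return List with `sweep` (the underlying [run_sweep()] table), `curves`
#'   (per `Gamma` and `r_E`: mean and sd of `tau`, `tau_t`, `alpha_band`,
#'   `phi`, plus `in_transition`), `spread_fit` (linear fit of `tau_t` on
#'   `tau` over transition cells) and `alpha_tau_correlation` (Pearson `r`
#'   over single runs in the transition region).
#' @export
transition_scan <- function(r_E_values, r_I = 0.6, L = 50, ell = 7,
                            gamma_list = 0.5, n_realizations = 5,
                            n_steps = 2^20, seed_base = 1L, ...) {
  grid <- data.frame(r_E = r_E_values, r_I = r_I)
  sw <- run_sweep(grid, L = L, ell = ell, gamma_list = gamma_list,
                  n_realizations = n_realizations, n_steps = n_steps,
                  seed_base = seed_base, ...)
  ok <- if ("error" %in% names(sw)) is.na(sw$error) else rep(TRUE, nrow(sw))
  swo <- sw[ok & !is.na(sw$gamma), , drop = FALSE]
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  curves <- do.call(rbind, lapply(split(swo, list(swo$gamma, swo$r_E),
                                        drop = TRUE), function(d) {
    data.frame(gamma = d$gamma[1], r_E = d$r_E[1],
               tau_mean = mean(d$tau, na.rm = TRUE),
               tau_sd = stats::sd(d$tau, na.rm = TRUE),
               tau_t_mean = mean(d$tau_t, na.rm = TRUE),
               tau_t_sd = stats::sd(d$tau_t, na.rm = TRUE),
               alpha_band_mean = mean(d$alpha_band, na.rm = TRUE),
               phi_mean = mean(d$phi, na.rm = TRUE),
               in_transition = mean(d$llr_wins, na.rm = TRUE) > 0.5)
  }))
  rownames(curves) <- NULL
  trans_cells <- curves[curves$in_transition %in% TRUE,
                        c("gamma", "r_E")]
  in_trans <- interaction(swo$gamma, swo$r_E) %in%
    interaction(trans_cells$gamma, trans_cells$r_E)
  st <- swo[in_trans, , drop = FALSE]
  spread_fit <- NULL
  alpha_tau_cor <- NA_real_
  if (nrow(st) >= 3 && sum(stats::complete.cases(st[c("tau", "tau_t")])) >= 3)
    spread_fit <- stats::lm(tau_t ~ tau, data = st)
  cc <- stats::complete.cases(st[c("alpha_band", "tau")])
  if (length(unique(st$r_E[cc])) >= 2 && sum(cc) >= 3) {
    alpha_tau_cor <- stats::cor(st$alpha_band[cc], st$tau[cc],
                                method = "pearson")
  }
  list(sweep = sw, curves = curves, spread_fit = spread_fit,
       alpha_tau_correlation = alpha_tau_cor)
}
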