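test_that("threshold is the stated fraction of the median activity", {
  expect_equal(compute_threshold(c(0, 2, 4, 2, 0), gamma = 0.5), 1.0)
  expect_equal(compute_threshold(c(5, 1, 3), gamma = 1), 3)
  expect_equal(compute_threshold(rep(7, 10), gamma = 0.8), 5.6)
  expect_warning(th <- compute_threshold(c(0, 0, 0, 1), gamma = 0.5),
                 "zero")
  expect_equal(th, 0)
  expect_error(compute_threshold(numeric(0), 0.5), "empty")
  expect_error(compute_threshold(c(1, 2), gamma = 0), "gamma")
})

test_that("avalanche extraction matches an independent run-length scan", {
  cat <- extract_avalanches(c(0, 0, 3, 5, 2, 0, 0), theta = 1.5)
  expect_equal(nrow(cat$events), 1)
  expect_equal(cat$events$t_i, 3)        # 1-based step indices
  expect_equal(cat$events$t_f, 6)
  expect_equal(cat$events$T, 3)
  expect_equal(cat$events$s_g, 10)
  expect_equal(cat$events$s_theta, 5.5)
  expect_equal(cat$profiles[[1]], c(3, 5, 2))

  cat2 <- extract_avalanches(c(0, 3, 0, 4, 0), theta = 1)
  expect_equal(cat2$events$T, c(1, 1))
  expect_equal(cat2$events$s_g, c(3, 4))

  # everything at or below theta: empty catalog
  expect_equal(nrow(extract_avalanches(c(1, 1, 1), theta = 1)$events), 0)

  # brute-force oracle on a random trace
  set.seed(99)
  A <- rpois(5000, 2)
  theta <- 1.5
  cat3 <- extract_avalanches(A, theta)
  # independent scan
  ev <- list(); open <- FALSE; start <- 0
  for (t in seq_along(A)) {
    if (!open && A[t] > theta) { open <- TRUE; start <- t }
    if (open && A[t] <= theta) {
      ev[[length(ev) + 1]] <- c(start, t); open <- FALSE
    }
  }
  ev <- do.call(rbind, ev)
  ev <- ev[ev[, 1] > 1, , drop = FALSE]  # censoring at the left edge
  expect_equal(cat3$events$t_i, ev[, 1])
  expect_equal(cat3$events$t_f, ev[, 2])
  expect_equal(cat3$events$s_g,
               vapply(seq_len(nrow(ev)),
                      function(k) sum(A[ev[k, 1]:(ev[k, 2] - 1)]),
                      numeric(1)))
})

test_that("events touching the trace boundary are censored", {
  cat <- extract_avalanches(c(3, 2, 0, 4, 0, 0, 5, 5), theta = 1)
  expect_equal(cat$n_censored, 2)
  expect_equal(cat$events$t_i, 4)
})

test_that("size identities and threshold monotonicity hold", {
  set.seed(7)
  A <- rpois(20000, 3)
  for (th in c(0, 1.5, 2.5)) {
    cat <- extract_avalanches(A, th)
    expect_true(all(cat$events$s_theta <= cat$events$s_g + 1e-12))
    expect_true(all(cat$events$s_theta >= 0))
    expect_equal(cat$events$s_theta, cat$events$s_g - cat$events$T * th)
    if (th == 0) expect_equal(cat$events$s_theta, cat$events$s_g)
  }
  # total supra-threshold time is non-increasing in theta
  tot <- vapply(c(0.5, 1.5, 2.5, 3.5),
                function(th) sum(extract_avalanches(A, th)$events$T),
                numeric(1))
  expect_true(all(diff(tot) <= 0))
})

test_that("kappa equals 1 on plotting-position samples and behaves directionally", {
  mu <- 1.5; x_min <- 1; x_max <- 1000
  # deterministic inverse-CDF sample: empirical CDF matches F_th up to the
  # 1/n staircase, so kappa = 1 to that resolution
  n <- 20000
  x <- sample_bounded_powerlaw(mu, x_min, x_max, n, plotting_positions = TRUE)
  expect_equal(kappa_index(x, mu, x_min, x_max), 1, tolerance = 2 / n)

  # large random sample: kappa close to 1
  x2 <- sample_bounded_powerlaw(mu, 1, 1000, 1e5, seed = 4)
  expect_equal(kappa_index(x2, mu, 1, 1000), 1, tolerance = 0.02)

  # exponential-like sample: subcritical, kappa < 1
  set.seed(5)
  xe <- 1 + rexp(1e5, rate = 1 / 5)
  xe <- xe[xe <= 1000]
  expect_lt(kappa_index(xe, mu, 1, 1000), 0.98)

  # excess mass near x_max: supercritical, kappa > 1
  xb <- c(x2, runif(2e4, 600, 1000))
  expect_gt(kappa_index(xb, mu, 1, 1000), 1.02)
})

test_that("kappa is invariant under reordering and common rescaling", {
  x <- sample_bounded_powerlaw(1.4, 2, 500, 5000, seed = 11)
  k1 <- kappa_index(x, 1.4, 2, 500)
  expect_identical(kappa_index(rev(x), 1.4, 2, 500), k1)
  expect_identical(kappa_index(sample(x), 1.4, 2, 500), k1)
  expect_equal(kappa_index(10 * x, 1.4, 20, 5000), k1, tolerance = 1e-12)
})

test_that("kappa rejects invalid inputs", {
  expect_error(kappa_index(c(1, 2), mu = 1, x_min = 1, x_max = 10), "mu")
  expect_error(kappa_index(c(1, 2), mu = 1.5, x_min = 5, x_max = 2))
  expect_error(kappa_index(c(100, 200), mu = 1.5, x_min = 1, x_max = 10),
               "no sample")
})

test_that("catalog export writes the documented TSV columns", {
  cat <- extract_avalanches(c(0, 3, 4, 0, 5, 0), theta = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat, path)
  back <- read.delim(path)
  expect_identical(names(back), c("t_i", "t_f", "T_ms", "s_g", "s_theta"))
  expect_equal(back$s_g, cat$events$s_g)
})
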