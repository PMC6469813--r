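test_that("neuron types, neighbourhood bounds and weight structure hold", {
  net <- build_network(L = 20, ell = 7, r_E = 1, r_I = 1, seed = 5)
  n <- 20^2
  expect_equal(sum(net$is_excitatory), round(0.75 * n))

  # with full connectivity every in-range target is connected: interior
  # neurons reach exactly the 48 candidates of the 7x7 square, never self
  W <- net$weights
  outdeg <- Matrix::rowSums(W != 0)
  interior <- rep(FALSE, n)
  rows <- (seq_len(n) - 1) %/% 20
  cols <- (seq_len(n) - 1) %% 20
  interior[rows >= 3 & rows <= 16 & cols >= 3 & cols <= 16] <- TRUE
  expect_true(all(outdeg[interior] == 48))
  expect_true(all(outdeg[!interior] < 48))
  expect_true(all(Matrix::diag(W) == 0))

  # every connection within Chebyshev distance 3
  Wt <- methods::as(W, "TsparseMatrix")
  pre_r <- Wt@i %/% 20; pre_c <- Wt@i %% 20
  post_r <- Wt@j %/% 20; post_c <- Wt@j %% 20
  cheb <- pmax(abs(pre_r - post_r), abs(pre_c - post_c))
  expect_true(all(cheb >= 1 & cheb <= 3))

  # weights determined solely by the (pre, post) type pair
  w <- Wt@x
  pre_exc <- net$is_excitatory[Wt@i + 1L]
  post_exc <- net$is_excitatory[Wt@j + 1L]
  expect_true(all(w[pre_exc & post_exc] == 0.02))
  expect_true(all(w[pre_exc & !post_exc] == 0.011))
  expect_true(all(w[!pre_exc] == -2))
})

test_that("construction is reproducible and seed-sensitive", {
  a <- build_network(L = 15, r_E = 0.3, r_I = 0.6, seed = 42)
  b <- build_network(L = 15, r_E = 0.3, r_I = 0.6, seed = 42)
  c <- build_network(L = 15, r_E = 0.3, r_I = 0.6, seed = 43)
  expect_identical(a$weights, b$weights)
  expect_identical(a$is_excitatory, b$is_excitatory)
  expect_false(identical(a$weights, c$weights))
})

test_that("realized out-degree matches the connectivity fraction in expectation", {
  # oracle: realized out-degree of interior excitatory neurons over many
  # disorder seeds, compared with the Bernoulli sampling target r_E * 48
  r_E <- 0.5
  n_seeds <- 60
  fracs <- vapply(seq_len(n_seeds), function(s) {
    net <- build_network(L = 20, ell = 7, r_E = r_E, r_I = 0.6, seed = s,
                         degree = "bernoulli")
    outdeg <- Matrix::rowSums(net$weights != 0)
    rows <- (seq_len(400) - 1) %/% 20
    cols <- (seq_len(400) - 1) %% 20
    interior <- rows >= 3 & rows <= 16 & cols >= 3 & cols <= 16
    mean(outdeg[interior & net$is_excitatory] / 48)
  }, numeric(1))
  # ~150 interior excitatory neurons x 60 seeds: binomial SE well under 0.01
  expect_lt(abs(mean(fracs) - r_E), 0.01)

  # exact-degree variant: interior out-degree is exactly round(r * 48)
  net <- build_network(L = 20, ell = 7, r_E = 0.5, r_I = 0.6, seed = 1,
                       degree = "exact")
  outdeg <- Matrix::rowSums(net$weights != 0)
  rows <- (seq_len(400) - 1) %/% 20
  cols <- (seq_len(400) - 1) %% 20
  interior <- rows >= 3 & rows <= 16 & cols >= 3 & cols <= 16
  expect_true(all(outdeg[interior & net$is_excitatory] == 24))
})

test_that("zero-connectivity limit empties excitatory rows", {
  net <- build_network(L = 15, r_E = 1e-9, r_I = 0.6, seed = 7)
  outdeg <- Matrix::rowSums(net$weights != 0)
  expect_true(all(outdeg[net$is_excitatory] == 0))
  expect_gt(sum(outdeg[!net$is_excitatory]), 0)
})

test_that("connection frequency decays exponentially with distance", {
  # small r_E so no probabilities are capped; pooled over seeds, the
  # log-frequency at each distance regresses on distance with slope -1/a0
  counts <- NULL
  for (s in 1:40) {
    net <- build_network(L = 20, ell = 7, r_E = 0.08, r_I = 0.6, seed = s,
                         degree = "bernoulli")
    Wt <- methods::as(net$weights, "TsparseMatrix")
    pre_exc <- net$is_excitatory[Wt@i + 1L]
    pre_r <- Wt@i %/% 20; pre_c <- Wt@i %% 20
    post_r <- Wt@j %/% 20; post_c <- Wt@j %% 20
    d <- sqrt((pre_r - post_r)^2 + (pre_c - post_c)^2)[pre_exc]
    counts <- c(counts, d)
  }
  tab <- table(round(counts, 3))
  d_vals <- as.numeric(names(tab))
  # normalize counts by each distance's multiplicity in the full stencil
  # before the regression
  off <- expand.grid(dx = -3:3, dy = -3:3)
  off <- off[!(off$dx == 0 & off$dy == 0), ]
  off_d <- round(sqrt(off$dx^2 + off$dy^2), 3)
  mult <- vapply(d_vals, function(dd) sum(abs(off_d - dd) < 1e-6),
                 numeric(1))
  keep <- mult > 0 & as.numeric(tab) > 0
  d_vals <- d_vals[keep]; tab <- tab[keep]; mult <- mult[keep]
  y <- log(as.numeric(tab) / mult)
  fit <- stats::lm(y ~ d_vals)
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.08)
})

test_that("invalid arguments are rejected", {
  expect_error(build_network(L = 20, ell = 6, r_E = 0.3, r_I = 0.6), "odd")
  expect_error(build_network(L = 20, r_E = 0, r_I = 0.6), "r_E")
  expect_error(build_network(L = 20, r_E = 0.3, r_I = 1.2), "r_I")
  expect_error(build_network(L = 5, ell = 7, r_E = 0.3, r_I = 0.6))
})

test_that("capped probabilities still deliver the target mean out-degree", {
  # r_I = 0.9 forces p = 1 on near targets; renormalization must keep the
  # realized mean out-degree within 1% of 0.9 * 48 for interior neurons
  degs <- vapply(1:30, function(s) {
    net <- build_network(L = 20, ell = 7, r_E = 0.1, r_I = 0.9, seed = s,
                         degree = "bernoulli")
    outdeg <- Matrix::rowSums(net$weights != 0)
    rows <- (seq_len(400) - 1) %/% 20
    cols <- (seq_len(400) - 1) %% 20
    interior <- rows >= 3 & rows <= 16 & cols >= 3 & cols <= 16
    mean(outdeg[interior & !net$is_excitatory])
  }, numeric(1))
  expect_lt(abs(mean(degs) / 48 - 0.9), 0.01)
})

test_that("topology round-trips through the plain-text serialization", {
  net <- build_network(L = 12, r_E = 0.25, r_I = 0.55, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_topology(net, path)
  back <- read_topology(path)
  expect_identical(back$is_excitatory, net$is_excitatory)
  expect_equal(back$weights, net$weights)
  expect_equal(back$r_E, net$r_E)
})
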