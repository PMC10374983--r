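test_that("Whittle's recursion solves the block Yule-Walker equations", {
  set.seed(1)
  for (i in 1:5) {
    m <- sample(2:4, 1); q <- sample(2:6, 1)
    A_list <- lapply(seq_len(q), function(p) {
      matrix(rnorm(m * m, sd = 0.25 / p), m, m)
    })
    Sig <- crossprod(matrix(rnorm(m * m), m)) / m + diag(m) * 0.5
    G <- var_autocov(A_list, Sig, q)
    fit <- whittle_var(G)
    oracle <- yule_walker_direct(G)
    expect_equal(fit$A, oracle$A, tolerance = 1e-8)
    expect_equal(fit$Sigma, (oracle$Sigma + t(oracle$Sigma)) / 2,
                 tolerance = 1e-8)
    ## exact recovery of the generating model from its own autocovariance
    for (p in seq_len(q)) {
      expect_equal(fit$A[, , p], A_list[[p]], tolerance = 1e-6)
    }
  }
})

test_that("autocovariance from a cross-spectrum inverts the DFT correctly", {
  ## build the exact spectrum of a known VAR and recover its autocovariance
  A_list <- list(matrix(c(0.5, 0, 0.4, 0.3), 2, 2))
  Sig <- diag(2)
  nf <- 101; n <- 200
  S <- array(0i, c(2, 2, nf))
  for (k in seq_len(nf)) {
    z <- exp(-1i * 2 * pi * (k - 1) / n)
    Aw <- diag(2) - A_list[[1]] * z
    H <- solve(Aw)
    S[, , k] <- H %*% Sig %*% Conj(t(H))
  }
  attr(S, "freqs") <- (seq_len(nf) - 1) * 0.5
  class(S) <- "fc_cross_spectrum"
  G <- cross_spectrum_to_autocov(S, 5)
  G_true <- var_autocov(A_list, Sig, 5)
  expect_equal(G, G_true, tolerance = 1e-6)
})

test_that("spectral GC recovers the directionality of a known VAR(2)", {
  A_list <- list(matrix(c(0.55, 0.5, 0, 0.35), 2, 2),
                 matrix(c(-0.8, 0, 0, -0.5), 2, 2))
  ## column-major: x(t) drives y(t) via A1[2,1] = 0.5; no y -> x path
  x <- simulate_var(A_list, diag(2), 40000, seed = 8)
  S <- cross_spectrum(as_epochs(x[1, , drop = FALSE], 200),
                      as_epochs(x[2, , drop = FALSE], 200), 100)
  res <- spectral_gc(S, order = 20)
  expect_gt(max(res$Fxy), 0.5)
  expect_lt(max(res$Fyx), 0.01)

  ## oracle: analytic GC of the generating model, evaluated from its true
  ## parameters (no fitting)
  G_true <- var_autocov(A_list, diag(2), 20)
  fit_true <- list(A = array(unlist(A_list), c(2, 2, 2)), Sigma = diag(2))
  ana <- fcpipe:::.var_gc_spectrum(array(c(A_list[[1]], A_list[[2]]),
                                         c(2, 2, 2)),
                                   diag(2), 1, 2, 101)
  expect_gt(cor(res$Fxy, ana$Fxy), 0.99)
  expect_lt(max(abs(res$Fyx - ana$Fyx)), 0.01)
})

test_that("the fitted VAR factorization reconstructs the cross-spectrum", {
  A_list <- list(matrix(c(0.4, 0.3, 0.1, 0.5), 2, 2),
                 matrix(c(-0.3, 0, 0.2, -0.2), 2, 2))
  x <- simulate_var(A_list, diag(c(1, 0.7)), 200000, seed = 9)
  S <- cross_spectrum(as_epochs(x[1, , drop = FALSE], 200),
                      as_epochs(x[2, , drop = FALSE], 200), 100)
  G <- cross_spectrum_to_autocov(S, 20)
  fit <- whittle_var(G)
  n <- 200
  rel <- vapply(seq_len(dim(S)[3]), function(k) {
    z <- exp(-1i * 2 * pi * (k - 1) / n)
    Aw <- diag(2) + 0i
    for (p in 1:20) Aw <- Aw - fit$A[, , p] * z^p
    H <- solve(Aw)
    Sm <- H %*% fit$Sigma %*% Conj(t(H))
    sqrt(sum(Mod(Sm - S[, , k])^2)) / sqrt(sum(Mod(S[, , k])^2))
  }, 0)
  expect_lt(median(rel), 0.05)
})

test_that("independent series give near-zero GC in both directions", {
  set.seed(10)
  S <- cross_spectrum(as_epochs(rnorm(18000), 200),
                      as_epochs(rnorm(18000), 200), 100)
  res <- spectral_gc(S, order = 20)
  expect_lt(mean(res$Fxy), 0.02)
  expect_lt(mean(res$Fyx), 0.02)
})

test_that("TRGC is antisymmetric and positive for a delayed copy", {
  set.seed(11)
  pr <- make_interacting_pair(18000, delay = 10, seed = 5)
  xs <- pr$sender + 0.3 * pink_noise(18000, seed = 6)
  ys <- pr$receiver + 0.3 * pink_noise(18000, seed = 7)
  Sxy <- cross_spectrum(as_epochs(xs, 200), as_epochs(ys, 200), 100)
  Syx <- cross_spectrum(as_epochs(ys, 200), as_epochs(xs, 200), 100)
  txy <- trgc(Sxy, 20); tyx <- trgc(Syx, 20)
  expect_equal(txy, -tyx, tolerance = 1e-8)
  band <- attr(Sxy, "freqs") >= 8 & attr(Sxy, "freqs") <= 12
  expect_gt(mean(txy[band]), 0)
})

test_that("time reversal of white noise swaps GC directions", {
  set.seed(12)
  x <- matrix(rnorm(2 * 18000), 2)
  x[2, ] <- x[2, ] + 0.5 * fcpipe:::delay_series(x[1, ], 3)
  S <- cross_spectrum(as_epochs(x[1, , drop = FALSE], 200),
                      as_epochs(x[2, , drop = FALSE], 200), 100)
  G <- cross_spectrum_to_autocov(S, 15)
  Gt <- G
  for (p in seq_len(dim(G)[3])) Gt[, , p] <- t(G[, , p])
  f_fwd <- whittle_var(G); f_rev <- whittle_var(Gt)
  a <- fcpipe:::.var_gc_spectrum(f_fwd$A, f_fwd$Sigma, 1, 2, 101)
  b <- fcpipe:::.var_gc_spectrum(f_rev$A, f_rev$Sigma, 1, 2, 101)
  ## reversed-time x -> y behaves like forward y -> x
  expect_equal(mean(a$Fxy), mean(b$Fyx), tolerance = 0.05)
  expect_equal(mean(a$Fyx), mean(b$Fxy), tolerance = 0.05)
})

test_that("the batched C++ GC path matches the per-pair R implementation", {
  set.seed(13)
  nt <- 8000
  x <- matrix(rnorm(4 * nt), 4)
  x[3, ] <- x[3, ] + 0.6 * fcpipe:::delay_series(x[1, ], 4)
  ep <- as_epochs(x, 200)
  S <- fcpipe:::.csd_multichannel(ep, 100)
  membership <- c(1L, 1L, 2L, 2L)
  pairs_mat <- matrix(c(1L, 2L), 1)
  res <- fcpipe:::cpp_gc_pairs(S, dim(S), membership, pairs_mat, 12L,
                               seq_len(dim(S)[3]), TRUE)
  Sp <- cross_spectrum(as_epochs(x[1:2, ], 200), as_epochs(x[3:4, ], 200),
                       100)
  rr <- spectral_gc(Sp, order = 12)
  expect_equal(drop(res$Fxy), rr$Fxy, tolerance = 1e-6)
  expect_equal(drop(res$Fyx), rr$Fyx, tolerance = 1e-6)
  tr <- trgc(Sp, order = 12)
  expect_equal(drop(res$Fxy - res$Fyx - (res$Fxy_r - res$Fyx_r)), tr,
               tolerance = 1e-6)
})

test_that("the batched C++ undirected metrics match the R implementations", {
  set.seed(14)
  x <- matrix(rnorm(4 * 8000), 4)
  x[3, ] <- x[3, ] + 0.6 * fcpipe:::delay_series(x[1, ], 4)
  ep <- as_epochs(x, 200)
  S <- fcpipe:::.csd_multichannel(ep, 100)
  membership <- c(1L, 1L, 2L, 2L)
  pairs_mat <- matrix(c(1L, 2L), 1)
  res <- fcpipe:::cpp_undirected_pairs(S, dim(S), membership, pairs_mat)
  Sp <- cross_spectrum(as_epochs(x[1:2, ], 200), as_epochs(x[3:4, ], 200),
                       100)
  expect_equal(drop(res$coh), coh_icoh_score(Sp, "coh"), tolerance = 1e-10)
  expect_equal(drop(res$icoh), coh_icoh_score(Sp, "icoh"), tolerance = 1e-10)
  expect_equal(drop(res$mim), mim(Sp), tolerance = 1e-10)
  expect_equal(drop(res$mic), mic(Sp), tolerance = 1e-10)
})

test_that("unstable or degenerate spectra raise errors", {
  S <- array(0i, c(2, 2, 5))
  for (k in 1:5) S[, , k] <- diag(2)
  attr(S, "freqs") <- seq(0, 2, by = 0.5)
  attr(S, "K") <- 1L; attr(S, "L") <- 1L
  class(S) <- "fc_cross_spectrum"
  ## flat unit spectrum is fine (white noise)
  expect_silent(spectral_gc(S, order = 2))
  S0 <- S; S0[1, 1, ] <- 0; S0[2, 2, ] <- 0
  expect_error(spectral_gc(S0, order = 2))
})
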