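test_that("LCMV satisfies the unit-gain constraint on every voxel", {
  model <- tiny_model()
  set.seed(1)
  rec <- simulate_recording(fast_config(seed = 2), model)
  filt <- fit_lcmv(sensor_covariance(rec), model)
  L <- model$gain_vector
  worst <- 0
  for (v in seq_len(model$space$n_sources)) {
    idx <- 3 * v - (2:0)
    G <- crossprod(filt$weights[, idx], L[, idx]) - diag(3)
    worst <- max(worst, max(abs(G)))
  }
  expect_lt(worst, 1e-8)
})

test_that("LCMV with identity covariance and orthonormal blocks is the leadfield", {
  set.seed(2)
  ns <- 12; nv <- 3
  L <- matrix(0, ns, 3 * nv)
  for (v in seq_len(nv)) L[, 3 * v - (2:0)] <- qr.Q(qr(matrix(rnorm(ns * 3), ns)))
  lf <- list(gain_vector = L)
  P <- fcpipe:::cpp_lcmv_filter(L, diag(ns))
  expect_equal(P, L, tolerance = 1e-10)
})

test_that("LCMV power map localizes a strong simulated source", {
  model <- small_model()
  set.seed(3)
  nt <- 6000
  v_true <- 37
  J <- matrix(0, 3 * model$space$n_sources, nt)
  J[3 * v_true - 1, ] <- band_filter(rnorm(nt), c(8, 12), 100)
  Q <- model$gain_vector %*% J
  Q <- Q + 0.02 * sd(Q) * matrix(rnorm(length(Q)), nrow(Q))
  filt <- fit_lcmv(sensor_covariance(Q), model)
  Jh <- crossprod(filt$weights, Q)
  pow <- vapply(seq_len(model$space$n_sources), function(v) {
    sum(Jh[3 * v - (2:0), ]^2)
  }, 0)
  expect_equal(which.max(pow), v_true)
})

test_that("eLORETA converges to SPD weights and spreads a point source", {
  model <- tiny_model()
  filt <- fit_eloreta(NULL, model, reg = 0.1)
  expect_true(filt$converged)
  expect_lt(filt$delta, 1e-6)
  evs <- apply(filt$W, 3, function(w) min(eigen((w + t(w)) / 2,
                                                symmetric = TRUE,
                                                only.values = TRUE)$values))
  expect_true(all(evs > 0))

  ## point source: power map peaks at (or adjacent to) the true location but
  ## is spatially spread
  set.seed(4)
  nt <- 4000
  v_true <- 20
  J <- matrix(0, 3 * model$space$n_sources, nt)
  J[3 * v_true, ] <- band_filter(rnorm(nt), c(8, 12), 100)
  Q <- model$gain_vector %*% J
  Jh <- crossprod(filt$weights, Q)
  pow <- vapply(seq_len(model$space$n_sources), function(v) {
    sum(Jh[3 * v - (2:0), ]^2)
  }, 0)
  top <- order(-pow)[1:5]
  d_top <- sqrt(sum((model$space$positions[which.max(pow), ] -
                       model$space$positions[v_true, ])^2))
  expect_lt(d_top, 0.03)              # peak near the truth
  expect_gt(sum(pow > 0.25 * max(pow)), 3)  # but spread out
})

test_that("DICS at one real frequency equals LCMV on that matrix", {
  model <- tiny_model()
  set.seed(5)
  rec <- simulate_recording(fast_config(seed = 6), model)
  ep <- epoch_data(rec)
  S <- fcpipe:::.csd_multichannel(ep, 100)
  filt <- fit_dics(S, model, ridge = 0.05)
  f <- 21
  Cf <- Re(S[, , f]); Cf <- (Cf + t(Cf)) / 2
  Cf <- Cf + diag(0.05 * mean(diag(Cf)), nrow(Cf))
  P_ref <- fcpipe:::cpp_lcmv_filter(model$gain_vector, solve(Cf))
  expect_equal(dics_filter(filt, f), P_ref, tolerance = 1e-10)

  ## unit gain per frequency
  Pf <- dics_filter(filt, f)
  v <- 4; idx <- 3 * v - (2:0)
  expect_equal(crossprod(Pf[, idx], model$gain_vector[, idx]), diag(3),
               tolerance = 1e-8)

  ## filters differ across frequencies for colored data
  expect_gt(max(abs(dics_filter(filt, 10) - dics_filter(filt, 30))), 1e-8)
})

test_that("Champagne decreases its objective, sparsifies, and vanishes on zero data", {
  set.seed(6)
  space <- build_source_space(50, 5, seed = 2)
  sens <- build_sensor_array(20)
  lf <- build_leadfield(space, sens)
  nt <- 2000
  J <- matrix(0, 150, nt)
  J[3 * 7 - 1, ] <- band_filter(rnorm(nt), c(8, 12), 100)
  J[3 * 31 - 2, ] <- band_filter(rnorm(nt), c(8, 12), 100)
  Q <- lf$gain_vector %*% J
  Q <- Q + 0.05 * sd(Q) * matrix(rnorm(length(Q)), nrow(Q))
  ch <- fit_champagne(Q, lf, noise_var = 0.1 * mean(Q^2))
  expect_true(all(diff(ch$objective) <= 1e-8))
  tr <- apply(ch$gamma, 3, function(g) sum(diag(g)))
  expect_gte(mean(tr < 1e-6 * max(tr)), 0.8)
  expect_true(all(order(-tr)[1:2] %in% c(7, 31)))

  ch0 <- fit_champagne(matrix(0, 20, 50), lf, noise_var = 1, max_iter = 10)
  expect_equal(max(abs(ch0$gamma)), 0)
  expect_error(fit_champagne(Q, lf, noise_var = 0), "positive")
})

test_that("spatial cross-validation uses the documented grid and limits", {
  model <- tiny_model()
  set.seed(7)
  rec <- simulate_recording(fast_config(seed = 8), model)
  Q <- rec$continuous
  tr <- sum(diag(sensor_covariance(Q)))
  sel <- spatial_crossval_select(Q, model, "eloreta", n_candidates = 15,
                                 candidates = NULL, n_folds = 4)
  expect_length(sel$candidates, 15)
  expect_equal(min(sel$candidates), 0.01 * tr, tolerance = 1e-9)
  expect_equal(max(sel$candidates), tr, tolerance = 1e-9)
  expect_true(sel$selected %in% sel$candidates)

  expect_equal(spatial_crossval_select(Q, model, "eloreta",
                                       candidates = 0.5)$selected, 0.5)
  expect_error(spatial_crossval_select(Q, model, "eloreta", n_folds = 1),
               "parameter error")
  expect_error(spatial_crossval_select(Q[, 1:500], model, "eloreta",
                                       n_folds = 12), "parameter error")
})

test_that("cross-validation selects the brute-force argmin of held-out error", {
  model <- tiny_model()
  set.seed(8)
  nt <- 1500
  J <- matrix(0, 3 * model$space$n_sources, nt)
  for (v in c(5, 20, 44)) J[3 * v - 1, ] <- rnorm(nt)
  Q <- model$gain_vector %*% J
  tr <- sum(diag(sensor_covariance(Q)))
  cands <- exp(seq(log(0.01 * tr), log(tr), length.out = 5))
  sel <- spatial_crossval_select(Q, model, "eloreta", candidates = cands,
                                 n_folds = 4, seed = 3)
  ## brute-force oracle: refit every candidate on every fold directly from
  ## the data matrices and measure the held-out squared error
  C <- sensor_covariance(Q)
  set.seed(3)
  fold <- sample(rep(1:4, length.out = nrow(Q)))
  errs <- vapply(cands, function(a) {
    tot <- 0
    for (k in 1:4) {
      te <- which(fold == k); trn <- which(fold != k)
      lf2 <- model; lf2$gain_vector <- model$gain_vector[trn, ]
      P <- fit_eloreta(NULL, lf2, reg = a)$weights
      Qc <- Q - rowMeans(Q)
      pred <- model$gain_vector[te, ] %*% (t(P) %*% Qc[trn, ])
      tot <- tot + sum((Qc[te, ] - pred)^2) / sum(Qc[te, ]^2)
    }
    tot / 4
  }, 0)
  expect_equal(sel$selected, cands[which.min(errs)])
  expect_equal(order(sel$cv_error), order(errs))
})

test_that("inverse filters are linear operators", {
  model <- tiny_model()
  set.seed(9)
  recA <- simulate_recording(fast_config(seed = 10), model)
  filt <- fit_lcmv(sensor_covariance(recA), model)
  a <- recA$continuous
  b <- matrix(rnorm(length(a)), nrow(a))
  Ja <- apply_inverse(filt, a)$time_courses
  Jb <- apply_inverse(filt, b)$time_courses
  Jab <- apply_inverse(filt, a + b)$time_courses
  expect_equal(Jab, Ja + Jb, tolerance = 1e-9)
})
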