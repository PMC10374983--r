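## Shared small fixtures, built once per test run.

.fix <- new.env()

tiny_model <- function() {
  if (is.null(.fix$tiny)) {
    space <- build_source_space(60, 6, seed = 11)
    sens <- build_sensor_array(24)
    .fix$tiny <- build_leadfield(space, sens)
  }
  .fix$tiny
}

small_model <- function() {
  if (is.null(.fix$small)) {
    space <- build_source_space(120, 12, seed = 7)
    sens <- build_sensor_array(32)
    .fix$small <- build_leadfield(space, sens)
  }
  .fix$small
}

## short-duration default-style simulation config for fast end-to-end tests
fast_config <- function(seed = 1, ...) {
  sim_config(duration_s = 40, seed = seed, ...)
}

## hand-built source space (bypasses clustering) for geometric leadfield
## tests; positions is an n x 3 matrix inside the inner shell
manual_space <- function(positions, normals = NULL, n_regions = 1) {
  n <- nrow(positions)
  if (is.null(normals)) {
    normals <- positions / sqrt(rowSums(positions^2))
    normals[!is.finite(normals)] <- 0
    zero <- rowSums(normals^2) == 0
    normals[zero, ] <- matrix(rep(c(0, 0, 1), sum(zero)), ncol = 3,
                              byrow = TRUE)
  }
  structure(list(positions = positions, normals = normals,
                 region_label = rep_len(seq_len(n_regions), n),
                 n_regions = as.integer(n_regions),
                 n_sources = as.integer(n), inner_radius = 0.087),
            class = "fc_source_space")
}

## Horner evaluation of a polynomial with highest-order coefficient first
polyval <- function(p, x) {
  out <- 0
  for (c_ in p) out <- out * x + c_
  out
}

## epoch array (Ne x T x K) from a channels-in-rows matrix
as_epochs <- function(x, epoch_len) {
  if (is.vector(x)) x <- matrix(x, 1)
  epoch_data(x, epoch_len)
}

## independent direct solver of the block Yule-Walker equations
## [A_1 .. A_q] T = [G(1) .. G(q)], T_{jk} = G(k - j) (block-Toeplitz),
## used as the oracle for Whittle's recursion
yule_walker_direct <- function(G) {
  m <- dim(G)[1]; q <- dim(G)[3] - 1
  Tm <- matrix(0, m * q, m * q)
  for (j in seq_len(q)) {
    for (k in seq_len(q)) {
      lag <- k - j
      blk <- if (lag >= 0) G[, , lag + 1] else t(G[, , -lag + 1])
      Tm[(j - 1) * m + 1:m, (k - 1) * m + 1:m] <- blk
    }
  }
  RHS <- matrix(0, m, m * q)
  for (k in seq_len(q)) RHS[, (k - 1) * m + 1:m] <- G[, , k + 1]
  Acat <- RHS %*% solve(Tm)
  A <- array(0, c(m, m, q))
  Sigma <- G[, , 1]
  for (p in seq_len(q)) {
    A[, , p] <- Acat[, (p - 1) * m + 1:m]
    Sigma <- Sigma - A[, , p] %*% t(G[, , p + 1])
  }
  list(A = A, Sigma = Sigma)
}

## analytic autocovariance of a stable VAR via the companion-form
## discrete Lyapunov equation (iterated to convergence)
var_autocov <- function(A_list, Sigma, n_lags) {
  m <- nrow(Sigma); q <- length(A_list)
  comp <- matrix(0, m * q, m * q)
  for (p in seq_len(q)) comp[1:m, (p - 1) * m + 1:m] <- A_list[[p]]
  if (q > 1) comp[(m + 1):(m * q), 1:(m * (q - 1))] <- diag(m * (q - 1))
  Sig_big <- matrix(0, m * q, m * q)
  Sig_big[1:m, 1:m] <- Sigma
  P <- Sig_big
  for (i in 1:3000) {
    P_new <- comp %*% P %*% t(comp) + Sig_big
    if (max(abs(P_new - P)) < 1e-14) { P <- P_new; break }
    P <- P_new
  }
  G <- array(0, c(m, m, n_lags + 1))
  G[, , 1] <- P[1:m, 1:m]
  state <- P
  for (lag in seq_len(n_lags)) {
    state <- comp %*% state
    G[, , lag + 1] <- state[1:m, 1:m]
  }
  G
}

## simulate a VAR process
simulate_var <- function(A_list, Sigma, n, seed = 1, burn = 500) {
  set.seed(seed)
  m <- nrow(Sigma); q <- length(A_list)
  ch <- chol(Sigma)
  x <- matrix(0, m, n + burn)
  eps <- t(matrix(rnorm((n + burn) * m), n + burn, m) %*% ch)
  for (t in (q + 1):(n + burn)) {
    acc <- eps[, t]
    for (p in seq_len(q)) acc <- acc + A_list[[p]] %*% x[, t - p]
    x[, t] <- acc
  }
  x[, burn + seq_len(n), drop = FALSE]
}
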