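#' Autocovariance sequence from a cross-spectrum
#'
#' Extends the one-sided cross-spectrum (0..Nyquist) to the full circle by
#' Hermitian symmetry and applies the inverse DFT, yielding the
#' autocovariance `G(p) = E[z(t) z(t-p)']` at lags `0..n_lags`.
#'
#' @param S an `fc_cross_spectrum` (full frequency grid, DC and Nyquist
#'   included).
#' @param n_lags maximum lag.
#' @return real array `m x m x (n_lags + 1)`.
#' @export
cross_spectrum_to_autocov <- function(S, n_lags = 20) {
  m <- dim(S)[1]; nf <- dim(S)[3]
  n <- 2L * (nf - 1L)
  S2 <- array(0i, c(m, m, n))
  S2[, , seq_len(nf)] <- S[, , seq_len(nf)]
  if (nf > 2) {
    for (j in seq_len(nf - 2)) S2[, , nf + j] <- Conj(S[, , nf - j])
  }
  G <- array(0, c(m, m, n_lags + 1))
  k <- 0:(n - 1)
  for (p in 0:n_lags) {
    w <- exp(2i * pi * k * p / n)
    Gp <- matrix(0i, m, m)
    for (ki in seq_len(n)) Gp <- Gp + S2[, , ki] * w[ki]
    G[, , p + 1] <- Re(Gp) / n
  }
  G
}

#' Fit a VAR model from an autocovariance sequence (Whittle's algorithm)
#'
#' Multichannel Levinson-Durbin recursion solving the block Yule-Walker
#' equations `G(k) = sum_j A_j G(k - j)` for the autoregressive coefficients
#' and the innovation covariance.
#'
#' @param G real array `m x m x (p + 1)` of autocovariances at lags `0..p`.
#' @return list with `A` (array `m x m x p`) and `Sigma` (`m x m`).
#' @export
whittle_var <- function(G) {
  m <- dim(G)[1]; q <- dim(G)[3] - 1L
  AF <- array(0, c(m, m, q)); AB <- array(0, c(m, m, q))
  Vf <- G[, , 1]; Vb <- G[, , 1]
  for (k in seq_len(q)) {
    D <- G[, , k + 1]
    if (k > 1) {
      for (j in seq_len(k - 1)) D <- D - AF[, , j] %*% G[, , k - j + 1]
    }
    Akk <- D %*% solve(Vb)
    Bkk <- t(D) %*% solve(Vf)
    if (k > 1) {
      AFold <- AF; ABold <- AB
      for (j in seq_len(k - 1)) {
        AF[, , j] <- AFold[, , j] - Akk %*% ABold[, , k - j]
        AB[, , j] <- ABold[, , j] - Bkk %*% AFold[, , k - j]
      }
    }
    AF[, , k] <- Akk; AB[, , k] <- Bkk
    Vf <- Vf - Akk %*% t(D)
    Vb <- Vb - Bkk %*% D
  }
  list(A = AF, Sigma = (Vf + t(Vf)) / 2)
}

## determinant of a Hermitian matrix via its (real) eigenvalues
.hdet <- function(M) {
  prod(eigen((M + Conj(t(M))) / 2, symmetric = TRUE,
             only.values = TRUE)$values)
}

## Spectral GC scores from fitted VAR parameters on the grid of S.
.var_gc_spectrum <- function(A, Sigma, bx, by, nf) {
  m <- nrow(Sigma); q <- dim(A)[3]
  n <- 2L * (nf - 1L)
  Sxx_g <- Sigma[bx, bx, drop = FALSE]
  Syy_g <- Sigma[by, by, drop = FALSE]
  Sxy_g <- Sigma[bx, by, drop = FALSE]
  Sig_xx_y <- Sxx_g - Sxy_g %*% solve(Syy_g) %*% t(Sxy_g)
  Sig_yy_x <- Syy_g - t(Sxy_g) %*% solve(Sxx_g) %*% Sxy_g
  Fxy <- numeric(nf); Fyx <- numeric(nf)
  for (f in seq_len(nf)) {
    w <- 2 * pi * (f - 1) / n
    Aw <- diag(1 + 0i, m)
    for (p in seq_len(q)) Aw <- Aw - A[, , p] * exp(-1i * w * p)
    H <- solve(Aw)
    Sm <- H %*% Sigma %*% Conj(t(H))
    Syy <- Sm[by, by, drop = FALSE]
    Sxx <- Sm[bx, bx, drop = FALSE]
    Hyx <- H[by, bx, drop = FALSE]
    Hxy <- H[bx, by, drop = FALSE]
    dyy <- Re(.hdet(Syy))
    dxx <- Re(.hdet(Sxx))
    ryy <- Re(.hdet(Syy - Hyx %*% Sig_xx_y %*% Conj(t(Hyx))))
    rxx <- Re(.hdet(Sxx - Hxy %*% Sig_yy_x %*% Conj(t(Hxy))))
    Fxy[f] <- log(dyy) - log(max(ryy, .Machine$double.xmin))
    Fyx[f] <- log(dxx) - log(max(rxx, .Machine$double.xmin))
  }
  list(Fxy = Fxy, Fyx = Fyx)
}

#' Frequency-resolved multivariate Granger causality
#'
#' Transforms the joint cross-spectrum into an autocovariance sequence,
#' fits a VAR model of order `order` by Whittle's algorithm, derives the
#' spectral transfer function of the corresponding innovations-form model
#' (for a VAR this equals the inverse of the VAR polynomial
#' `A(z) = I - sum_p A_p z^p`) and evaluates the Geweke-style conditional
#' log-determinant ratio at every frequency, in both directions.
#'
#' @param S an `fc_cross_spectrum` of two component sets on the full grid.
#' @param order VAR model order (default 20).
#' @return list with `Fxy` (x -> y), `Fyx`, and `freqs`.
#' @export
spectral_gc <- function(S, order = 20) {
  b <- .blocks(S)
  G <- cross_spectrum_to_autocov(S, order)
  fit <- whittle_var(G)
  .check_var_stable(fit)
  res <- .var_gc_spectrum(fit$A, fit$Sigma, b$x, b$y, dim(S)[3])
  res$freqs <- attr(S, "freqs")
  res
}

.check_var_stable <- function(fit) {
  m <- nrow(fit$Sigma); q <- dim(fit$A)[3]
  comp <- matrix(0, m * q, m * q)
  comp[seq_len(m), ] <- matrix(fit$A, m, m * q)
  if (q > 1) comp[(m + 1):(m * q), seq_len(m * (q - 1))] <- diag(m * (q - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1) {
    stop(sprintf("unstable VAR fit (spectral radius %.4f >= 1)", rho))
  }
  ev <- eigen((fit$Sigma + t(fit$Sigma)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0) stop("non-positive-definite innovation covariance")
  invisible(rho)
}

#' Net and time-reversed spectral Granger causality
#'
#' `gc_net` returns `Fxy - Fyx` on the forward data. `trgc` additionally
#' fits the model on the transposed autocovariance sequence (equivalent to
#' reversing time) and subtracts the reversed net score; the result is
#' antisymmetric in the direction slot and robust to instantaneous mixing.
#'
#' @inheritParams spectral_gc
#' @return numeric vector of signed scores (x -> y) per frequency.
#' @export
trgc <- function(S, order = 20) {
  b <- .blocks(S)
  G <- cross_spectrum_to_autocov(S, order)
  Gt <- G
  for (p in seq_len(dim(G)[3])) Gt[, , p] <- t(G[, , p])
  nf <- dim(S)[3]
  fw <- whittle_var(G); .check_var_stable(fw)
  rv <- whittle_var(Gt); .check_var_stable(rv)
  f1 <- .var_gc_spectrum(fw$A, fw$Sigma, b$x, b$y, nf)
  f2 <- .var_gc_spectrum(rv$A, rv$Sigma, b$x, b$y, nf)
  (f1$Fxy - f1$Fyx) - (f2$Fxy - f2$Fyx)
}

#' @rdname trgc
#' @export
gc_net <- function(S, order = 20) {
  r <- spectral_gc(S, order)
  r$Fxy - r$Fyx
}
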