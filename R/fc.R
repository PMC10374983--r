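#' Epoch-averaged joint cross-spectrum of two component sets
#'
#' Each epoch is multiplied with a Hanning window and Fourier transformed;
#' the joint cross-spectrum is the epoch average of the outer products of
#' the transformed data. Frequencies run from 0 to the Nyquist frequency in
#' steps of `fs / T`.
#'
#' @param x_epochs array `Ne x T x K` (epochs, samples, components).
#' @param y_epochs array `Ne x T x L`; omit (or pass `NULL`) for the
#'   cross-spectrum of `x_epochs` with itself.
#' @param fs sampling rate in Hz.
#' @return `fc_cross_spectrum`: complex array `(K+L) x (K+L) x Nfreq` with
#'   attributes `freqs`, `K`, `L`, `n_epochs`.
#' @export
cross_spectrum <- function(x_epochs, y_epochs = NULL, fs = 100) {
  if (is.null(y_epochs)) {
    K <- dim(x_epochs)[3]
    S <- .csd_multichannel(x_epochs, fs)
    attr(S, "K") <- K; attr(S, "L") <- 0L
    return(S)
  }
  stopifnot(dim(x_epochs)[1] == dim(y_epochs)[1],
            dim(x_epochs)[2] == dim(y_epochs)[2])
  if (dim(x_epochs)[1] < 2) stop("estimation error: need at least 2 epochs")
  K <- dim(x_epochs)[3]; L <- dim(y_epochs)[3]
  z <- array(0, c(dim(x_epochs)[1], dim(x_epochs)[2], K + L))
  z[, , seq_len(K)] <- x_epochs
  z[, , K + seq_len(L)] <- y_epochs
  S <- .csd_multichannel(z, fs)
  attr(S, "K") <- K; attr(S, "L") <- L
  S
}

## Cross-spectral density of a multichannel epoch array (Ne x T x M).
.csd_multichannel <- function(z, fs) {
  ne <- dim(z)[1]; tt <- dim(z)[2]; m <- dim(z)[3]
  if (ne < 2) stop("estimation error: need at least 2 epochs")
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, tt - 1) / (tt - 1))  # Hanning
  nf <- tt %/% 2 + 1
  ## Fourier coefficients per epoch: nf x m x ne
  Fc <- array(0i, c(nf, m, ne))
  for (e in seq_len(ne)) {
    Fc[, , e] <- mvfft(win * matrix(z[e, , ], tt, m))[seq_len(nf), ,
                                                      drop = FALSE]
  }
  S <- array(0i, c(m, m, nf))
  for (f in seq_len(nf)) {
    Mf <- matrix(Fc[f, , ], m, ne)
    S[, , f] <- (Mf %*% Conj(t(Mf))) / ne
  }
  attr(S, "freqs") <- (seq_len(nf) - 1) * fs / tt
  attr(S, "n_epochs") <- ne
  class(S) <- "fc_cross_spectrum"
  S
}

.blocks <- function(S) {
  K <- attr(S, "K"); L <- attr(S, "L")
  list(x = seq_len(K), y = K + seq_len(L))
}

#' Complex coherency
#'
#' Normalizes the cross-spectrum element-wise by the geometric mean of the
#' corresponding auto-spectra.
#'
#' @param S an `fc_cross_spectrum`.
#' @return complex array, same shape as `S`.
#' @export
coherency <- function(S) {
  nf <- dim(S)[3]
  C <- S
  for (f in seq_len(nf)) {
    d <- Re(diag(S[, , f]))
    if (any(d <= 0)) stop("degenerate error: zero-power component")
    sc <- 1 / sqrt(d)
    C[, , f] <- S[, , f] * outer(sc, sc)
  }
  C
}

#' Coherence / imaginary-coherency score of a component-set pair
#'
#' Element-wise absolute coherency (`"coh"`) or absolute imaginary part of
#' coherency (`"icoh"`) over the off-diagonal (x, y) block, averaged across
#' all K x L component pairs.
#'
#' @param S an `fc_cross_spectrum` of two component sets.
#' @param variant `"coh"` or `"icoh"`.
#' @return numeric vector, one score per frequency.
#' @export
coh_icoh_score <- function(S, variant = c("coh", "icoh")) {
  variant <- match.arg(variant)
  C <- coherency(S)
  b <- .blocks(S)
  vapply(seq_len(dim(S)[3]), function(f) {
    blk <- C[b$x, b$y, f]
    if (variant == "coh") mean(Mod(blk)) else mean(abs(Im(blk)))
  }, 0)
}

## Ridge-stabilized inverse of a symmetric real matrix.
.ridge_solve <- function(M, cond_limit = 1e10, ridge_frac = 1e-10) {
  if (!is.matrix(M)) M <- as.matrix(M)
  if (rcond(M) < 1 / cond_limit) {
    M <- M + diag(ridge_frac * sum(diag(M)), nrow(M))
  }
  solve(M)
}

## Inverse symmetric square root of a real SPD matrix.
.inv_sqrtm <- function(M, ridge_frac = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, ridge_frac * max(e$values))
  e$vectors %*% diag(1 / sqrt(v), length(v)) %*% t(e$vectors)
}

#' Multivariate interaction measure (MIM)
#'
#' Trace-form multivariate generalization of the squared imaginary part of
#' coherency between two component sets, evaluated per frequency on the
#' coherency partitions.
#'
#' @param S an `fc_cross_spectrum` of two component sets.
#' @return numeric vector, one nonnegative score per frequency.
#' @export
mim <- function(S) {
  C <- coherency(S)
  b <- .blocks(S)
  vapply(seq_len(dim(S)[3]), function(f) {
    Cxx <- Re(C[b$x, b$x, f, drop = FALSE][, , 1])
    Cyy <- Re(C[b$y, b$y, f, drop = FALSE][, , 1])
    Cxyi <- Im(C[b$x, b$y, f, drop = FALSE][, , 1])
    Cxx <- matrix(Cxx, length(b$x)); Cyy <- matrix(Cyy, length(b$y))
    Cxyi <- matrix(Cxyi, length(b$x), length(b$y))
    sum(diag(.ridge_solve(Cxx) %*% Cxyi %*% .ridge_solve(Cyy) %*% t(Cxyi)))
  }, 0)
}

#' Maximized imaginary coherency (MIC)
#'
#' Maximizes the imaginary part of coherency over one-dimensional
#' projections of the two component sets. After whitening the cross-spectrum
#' by the inverse symmetric square roots of the real within-set coherency
#' blocks, the maximum is attained at the leading singular pair of the
#' imaginary whitened off-diagonal block.
#'
#' @param S an `fc_cross_spectrum` of two component sets.
#' @return numeric vector in `[0, 1]`, one score per frequency.
#' @export
mic <- function(S) {
  C <- coherency(S)
  b <- .blocks(S)
  vapply(seq_len(dim(S)[3]), function(f) {
    Cxx <- matrix(Re(C[b$x, b$x, f]), length(b$x))
    Cyy <- matrix(Re(C[b$y, b$y, f]), length(b$y))
    Cxyi <- matrix(Im(C[b$x, b$y, f]), length(b$x), length(b$y))
    W <- .inv_sqrtm(Cxx) %*% Cxyi %*% .inv_sqrtm(Cyy)
    max(svd(W)$d)
  }, 0)
}

#' Average scores over an inclusive frequency band
#'
#' @param values numeric vector (or matrix with frequencies in columns).
#' @param freqs frequency grid in Hz.
#' @param band length-2 band edges in Hz (inclusive).
#' @export
band_average <- function(values, freqs, band = c(8, 12)) {
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("no frequency bins inside the band")
  if (is.matrix(values)) rowMeans(values[, sel, drop = FALSE])
  else mean(values[sel])
}
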