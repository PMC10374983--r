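#' Sample covariance of sensor data
#'
#' @param x `fc_recording` or numeric matrix (sensors x time).
#' @return Ns x Ns covariance matrix.
#' @export
sensor_covariance <- function(x) {
  if (inherits(x, "fc_recording")) x <- x$continuous
  xc <- x - rowMeans(x)
  tcrossprod(xc) / (ncol(x) - 1)
}

.ridge_load <- function(C, cond_limit = 1e10, ridge_frac = 1e-8) {
  if (rcond(C) < 1 / cond_limit) {
    C <- C + diag(ridge_frac * sum(diag(C)), nrow(C))
  }
  C
}

#' LCMV beamformer filter
#'
#' Minimum-variance spatial filter with a per-voxel unit-gain constraint:
#' `P_v = C^-1 L_v (L_v' C^-1 L_v)^-1`, so that `P_v' L_v = I`.
#' The covariance is ridge-loaded by `1e-8 * trace` when its condition
#' number exceeds `1e10`.
#'
#' @param sensor_cov Ns x Ns sensor covariance.
#' @param leadfield an `fc_leadfield`.
#' @return `fc_inverse_filter` with `weights` (Ns x 3Nv; source estimate is
#'   `t(weights) %*% Q`).
#' @export
fit_lcmv <- function(sensor_cov, leadfield) {
  C <- .ridge_load((sensor_cov + t(sensor_cov)) / 2)
  P <- cpp_lcmv_filter(leadfield$gain_vector, solve(C))
  structure(list(weights = P, method = "lcmv", reg = NA_real_,
                 per_frequency = FALSE, leadfield = leadfield),
            class = "fc_inverse_filter")
}

#' eLORETA inverse filter
#'
#' Weighted minimum-norm filter with iteratively refined block-diagonal
#' depth weights `W_v = [L_v' M L_v]^(1/2)`,
#' `M = (L W^-1 L' + a K)^+` (K the common-average centering matrix),
#' iterated to a fixed point. The filter itself does not depend on the
#' data; `sensor_cov` is accepted for interface consistency and used only
#' when `reg` is `NULL` to place the default regularization on the scale of
#' the measured data (`0.05 * trace`).
#'
#' @param sensor_cov Ns x Ns sensor covariance (may be `NULL` when `reg`
#'   is given).
#' @param leadfield an `fc_leadfield`.
#' @param reg nonnegative regularization parameter `a`.
#' @param max_iter,tol iteration controls (relative Frobenius change of
#'   the weights).
#' @param weights_init optional 3 x 3 x Nv warm-start weights.
#' @return `fc_inverse_filter` (with convergence metadata).
#' @export
fit_eloreta <- function(sensor_cov = NULL, leadfield, reg = NULL,
                        max_iter = 200, tol = 1e-6, weights_init = NULL) {
  if (is.null(reg)) {
    if (is.null(sensor_cov)) stop("provide either reg or sensor_cov")
    reg <- 0.05 * sum(diag(sensor_cov))
  }
  if (reg < 0) stop("reg must be nonnegative")
  res <- cpp_eloreta(leadfield$gain_vector, reg, as.integer(max_iter), tol,
                     weights_init)
  if (!res$converged) {
    warning(sprintf("eLORETA weights not converged after %d iterations (relative change %.2e)",
                    res$iterations, res$delta))
  }
  structure(list(weights = res$P, method = "eloreta", reg = reg,
                 per_frequency = FALSE, W = res$W,
                 iterations = res$iterations, delta = res$delta,
                 converged = res$converged,
                 leadfield = leadfield),
            class = "fc_inverse_filter")
}

#' DICS beamformer
#'
#' Frequency-domain LCMV variant: a separate unit-gain beamformer is built
#' at each frequency from the real part of the sensor cross-spectral
#' density. Filters are materialized on demand with [dics_filter()].
#'
#' @param sensor_cross_spectrum `fc_cross_spectrum` of the sensor data
#'   (Ns channels, full frequency grid).
#' @param leadfield an `fc_leadfield`.
#' @param ridge diagonal loading applied to every frequency's real CSD, as
#'   a fraction of its mean diagonal. The per-frequency CSD is estimated
#'   from `Ne` epochs and is rank-deficient whenever `Ne < Ns`, so unlike
#'   LCMV the DICS beamformer always needs explicit loading; 0.05 is the
#'   conventional beamformer default.
#' @return `fc_inverse_filter` with `per_frequency = TRUE`.
#' @export
fit_dics <- function(sensor_cross_spectrum, leadfield, ridge = 0.05) {
  nf <- dim(sensor_cross_spectrum)[3]
  ns <- dim(sensor_cross_spectrum)[1]
  Cinv <- array(0, c(ns, ns, nf))
  for (f in seq_len(nf)) {
    Cf <- Re(sensor_cross_spectrum[, , f])
    Cf <- (Cf + t(Cf)) / 2 + diag(ridge * mean(diag(Cf)), ns)
    Cinv[, , f] <- solve(Cf)
  }
  structure(list(Cinv = Cinv, method = "dics", reg = NA_real_,
                 per_frequency = TRUE,
                 freqs = attr(sensor_cross_spectrum, "freqs"),
                 leadfield = leadfield),
            class = "fc_inverse_filter")
}

#' @rdname fit_dics
#' @param filter a DICS `fc_inverse_filter`.
#' @param f_index frequency bin index.
#' @return Ns x 3Nv filter matrix for that frequency.
#' @export
dics_filter <- function(filter, f_index) {
  stopifnot(filter$method == "dics")
  cpp_lcmv_filter(filter$leadfield$gain_vector, filter$Cinv[, , f_index])
}

## Symmetric matrix square root (SPD input).
.sqrtm_spd <- function(M, ridge = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, max(e$values, 0) * ridge, 0)
  e$vectors %*% diag(sqrt(v), length(v)) %*% t(e$vectors)
}

#' Champagne sparse Bayesian inverse
#'
#' Hierarchical sparse Bayesian learning with a full 3 x 3 positive
#' semi-definite prior covariance per voxel and homoscedastic sensor noise.
#' Hyperparameters are optimized by convex-bounding fixed-point updates of
#' the Type-II (negative log evidence) objective
#' `L = Tr(C Sigma_q^-1) + log det Sigma_q`; most voxel priors shrink to
#' zero, producing a sparse source distribution.
#'
#' @param sensor_data Ns x Nt matrix (or `fc_recording`).
#' @param leadfield an `fc_leadfield`.
#' @param noise_var positive sensor noise variance `sigma^2`.
#' @param max_iter,tol iteration controls (relative change of the
#'   objective).
#' @param cov optional precomputed sensor covariance (overrides
#'   `sensor_data`).
#' @return `fc_inverse_filter` with `weights = Sigma_q^-1 L Gamma`
#'   (posterior-mean filter), per-voxel `gamma` (3 x 3 x Nv) and the
#'   objective trace `objective`.
#' @export
fit_champagne <- function(sensor_data, leadfield, noise_var,
                          max_iter = 200, tol = 1e-6, cov = NULL) {
  if (noise_var <= 0) stop("noise_var must be positive")
  if (is.null(cov)) {
    if (inherits(sensor_data, "fc_recording")) {
      sensor_data <- sensor_data$continuous
    }
    cov <- tcrossprod(sensor_data) / ncol(sensor_data)
  }
  L <- leadfield$gain_vector
  ns <- nrow(L); nv <- ncol(L) / 3
  gam <- array(0, c(3, 3, nv))
  g0 <- sum(diag(cov)) / max(sum(L^2), .Machine$double.eps)
  for (v in seq_len(nv)) gam[, , v] <- diag(g0, 3)

  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    ## Sigma_q = sigma^2 I + L Gamma L'
    LG <- L
    for (v in seq_len(nv)) {
      idx <- 3 * v - (2:0)
      LG[, idx] <- L[, idx, drop = FALSE] %*% gam[, , v]
    }
    Sq <- diag(noise_var, ns) + tcrossprod(LG, L)
    Sq <- (Sq + t(Sq)) / 2
    Sqi <- solve(Sq)
    ld <- determinant(Sq, logarithm = TRUE)$modulus[1]
    obj <- c(obj, sum(Sqi * cov) + ld)
    if (it > 1) {
      if (!is.finite(obj[it])) stop("Champagne objective diverged")
      rel <- abs(obj[it] - obj[it - 1]) / max(abs(obj[it - 1]), 1e-300)
      if (rel < tol) break
    }
    SqiC <- Sqi %*% cov %*% Sqi
    for (v in seq_len(nv)) {
      idx <- 3 * v - (2:0)
      Lv <- L[, idx, drop = FALSE]
      Zv <- crossprod(Lv, Sqi %*% Lv)
      Gv <- gam[, , v]
      Mv <- Gv %*% crossprod(Lv, SqiC %*% Lv) %*% Gv
      Zh <- .sqrtm_spd(Zv)
      Zhi <- .inv_sqrtm(Zv)
      gam[, , v] <- Zhi %*% .sqrtm_spd(Zh %*% Mv %*% Zh) %*% Zhi
    }
  }
  ## posterior mean filter P = Sigma_q^-1 L Gamma
  LG <- L
  for (v in seq_len(nv)) {
    idx <- 3 * v - (2:0)
    LG[, idx] <- L[, idx, drop = FALSE] %*% gam[, , v]
  }
  Sq <- diag(noise_var, ns) + tcrossprod(LG, L)
  P <- solve((Sq + t(Sq)) / 2, LG)
  structure(list(weights = P, method = "champagne", reg = noise_var,
                 per_frequency = FALSE, gamma = gam, objective = obj,
                 leadfield = leadfield),
            class = "fc_inverse_filter")
}

#' Apply a (time-domain) inverse filter to a recording
#'
#' @param filter an `fc_inverse_filter` (lcmv, eloreta or champagne).
#' @param x `fc_recording` or sensors x time matrix.
#' @return `fc_source_estimate` with `time_courses` (3Nv x Nt).
#' @export
apply_inverse <- function(filter, x) {
  if (filter$per_frequency) {
    stop("per-frequency (DICS) filters project cross-spectra, not time series")
  }
  if (inherits(x, "fc_recording")) x <- x$continuous
  structure(list(time_courses = crossprod(filter$weights, x),
                 method = filter$method),
            class = "fc_source_estimate")
}

#' Select a regularization parameter by spatial cross-validation
#'
#' Sensors are split into folds; the inverse model is fitted on the
#' training sensors only, sources are reconstructed from the training
#' sensors, and the held-out sensors are predicted through their leadfield
#' rows. The candidate minimizing the mean normalized held-out squared
#' error is returned. The default candidate grid is 15 logarithmically
#' spaced values between `0.01 * Tr(Cov)` and `Tr(Cov)`.
#'
#' @param sensor_data Ns x Nt matrix or `fc_recording`.
#' @param leadfield an `fc_leadfield`.
#' @param method `"eloreta"` (regularization `a`) or `"champagne"` (noise
#'   variance `sigma^2`).
#' @param n_folds number of sensor folds (>= 2).
#' @param candidates optional candidate values; default grid as above.
#' @param n_candidates grid size when `candidates` is `NULL`.
#' @param seed seed for the fold assignment.
#' @param ... passed to the fitting routine.
#' @return list with `selected`, `candidates`, `cv_error`.
#' @export
spatial_crossval_select <- function(sensor_data, leadfield,
                                    method = c("eloreta", "champagne"),
                                    n_folds = 5, candidates = NULL,
                                    n_candidates = 15, seed = 1, ...) {
  method <- match.arg(method)
  if (inherits(sensor_data, "fc_recording")) {
    sensor_data <- sensor_data$continuous
  }
  if (n_folds < 2) stop("parameter error: n_folds must be >= 2")
  C <- sensor_covariance(sensor_data)
  ns <- nrow(C)
  tr <- sum(diag(C))
  if (is.null(candidates)) {
    candidates <- exp(seq(log(0.01 * tr), log(tr), length.out = n_candidates))
  }
  if (length(candidates) == 0) stop("parameter error: no candidates")
  if (length(candidates) == 1) {
    return(list(selected = candidates, candidates = candidates,
                cv_error = NA_real_))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(n_folds), length.out = ns))
  if (min(tabulate(fold, n_folds)) < 3) {
    stop("parameter error: every fold needs at least 3 sensors")
  }

  L <- leadfield$gain_vector
  errs <- matrix(NA_real_, length(candidates), n_folds)
  for (k in seq_len(n_folds)) {
    te <- which(fold == k); trn <- which(fold != k)
    L_tr <- L[trn, , drop = FALSE]; L_te <- L[te, , drop = FALSE]
    C_trtr <- C[trn, trn]; C_trte <- C[trn, te]; C_tete <- C[te, te]
    lf_tr <- leadfield; lf_tr$gain_vector <- L_tr
    W_warm <- NULL
    for (ci in seq_along(candidates)) {
      P <- switch(method,
        eloreta = {
          fit <- fit_eloreta(NULL, lf_tr, reg = candidates[ci],
                             weights_init = W_warm, ...)
          W_warm <- fit$W
          fit$weights
        },
        champagne = fit_champagne(NULL, lf_tr, noise_var = candidates[ci],
                                  cov = C_trtr, ...)$weights)
      O <- L_te %*% t(P)   # held-out prediction operator
      err <- sum(diag(C_tete)) - 2 * sum(O * t(C_trte)) +
        sum((O %*% C_trtr) * O)
      errs[ci, k] <- err / sum(diag(C_tete))
    }
  }
  mean_err <- rowMeans(errs)
  list(selected = candidates[which.min(mean_err)], candidates = candidates,
       cv_error = mean_err)
}

#' @export
print.fc_inverse_filter <- function(x, ...) {
  cat("<fc_inverse_filter> method=", x$method,
      if (!is.na(x$reg)) sprintf(", reg=%.3g", x$reg) else "", "\n", sep = "")
  invisible(x)
}
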