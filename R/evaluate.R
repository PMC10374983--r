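#' Normalized percentile rank of ground-truth scores
#'
#' Scores are sorted in descending order and the ranks `r_i` of the
#' ground-truth entries are retrieved (ties receive the mean of the tied
#' ranks). The raw percentile rank
#' `PR' = mean_i (1 - r_i / F)` is normalized to the perfect-skill
#' (ranks 1..NI) and no-skill (ranks F-NI+1..F) cases, so that 1 means the
#' ground truth occupies the top ranks, 0 the bottom ranks, and random
#' scores average 0.5.
#'
#' @param scores numeric vector of candidate scores (one per candidate
#'   pair).
#' @param truth_idx indices of the ground-truth entries in `scores`; the
#'   special value `NA` marks a ground-truth entry absent from the
#'   candidate list (e.g. a wrongly signed directed score), which receives
#'   the worst rank `F`.
#' @return `fc_pr` list with `pr`, `raw_pr`, `ranks`, `F`, `NI`.
#' @export
percentile_rank <- function(scores, truth_idx) {
  F_ <- length(scores)
  NI <- length(truth_idx)
  if (NI < 1 || F_ < NI) stop("parameter error: need F >= NI >= 1")
  if (any(!is.na(truth_idx) & (truth_idx < 1 | truth_idx > F_))) {
    stop("truth indices out of range")
  }
  rk <- rank(-scores, ties.method = "average")
  r <- numeric(NI)
  r[!is.na(truth_idx)] <- rk[truth_idx[!is.na(truth_idx)]]
  ## absent ground-truth entries (e.g. wrongly signed directed scores) fill
  ## the bottom ranks F, F-1, ... so that PR stays within [0, 1]
  n_missing <- sum(is.na(truth_idx))
  if (n_missing > 0) r[is.na(truth_idx)] <- F_ - seq_len(n_missing) + 1
  raw <- sum(1 - r / F_) / NI
  i <- seq_len(NI)
  pr_ps <- sum(1 - i / F_) / NI
  pr_ns <- sum(1 - (F_ - i + 1) / F_) / NI
  pr <- (raw - pr_ns) / (pr_ps - pr_ns)
  structure(list(pr = pr, raw_pr = raw, ranks = r, F = F_, NI = NI),
            class = "fc_pr")
}

## Upper-triangle (i < j) candidate list of an R x R score matrix, plus the
## index of a given unordered region pair in that list.
.upper_pairs <- function(R) {
  which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
}

.pair_index <- function(pairs_mat, a, b) {
  i <- pmin(a, b); j <- pmax(a, b)
  match(paste(i, j), paste(pairs_mat[, 1], pairs_mat[, 2]))
}

#' Percentile rank of a region-pair score matrix
#'
#' Candidates are the upper-triangle (off-diagonal, unordered) region
#' pairs. For undirected metrics the scores are used as-is. For directed
#' (antisymmetric) metrics, `task = "detection"` ranks absolute values
#' while `task = "direction"` ranks the positively signed scores: a
#' ground-truth pair whose score has the wrong sign is absent from the
#' candidate list and receives the worst rank.
#'
#' @param score_mat R x R score matrix (symmetric, or antisymmetric for
#'   directed metrics).
#' @param truth data.frame with columns `seed_region`, `target_region`.
#' @param directed whether `score_mat` is a signed directed
#'   (seed -> target, antisymmetric) score matrix.
#' @param task `"detection"` or `"direction"` (directed metrics only).
#' @return `fc_pr`.
#' @export
pr_matrix <- function(score_mat, truth, directed = FALSE,
                      task = c("detection", "direction")) {
  task <- match.arg(task)
  R <- nrow(score_mat)
  up <- .upper_pairs(R)
  vals <- score_mat[up]
  ti <- .pair_index(up, truth$seed_region, truth$target_region)
  if (any(is.na(ti))) stop("truth pair outside candidate set")
  if (!directed) {
    return(percentile_rank(vals, ti))
  }
  if (task == "detection") {
    return(percentile_rank(abs(vals), ti))
  }
  ## direction: candidate list = positive directed scores (= |vals|, one
  ## orientation per pair); the truth entry exists only when the score of
  ## seed -> target is positive.
  signed_truth <- score_mat[cbind(truth$seed_region, truth$target_region)]
  ti[signed_truth <= 0] <- NA
  percentile_rank(abs(vals), ti)
}

#' Epoch-shuffling surrogate test for MIM between two component sets
#'
#' Builds a null distribution by permuting the epoch pairing between the
#' two sets when forming the off-diagonal cross-spectral blocks (the
#' spectral powers on the diagonal are kept unshuffled), recomputes the
#' band-averaged MIM for each permutation, and returns
#' `p = (1 + #(null >= observed)) / (1 + n_shuffles)` (kept strictly
#' positive so FDR correction is well-defined).
#'
#' @param x_epochs,y_epochs arrays `Ne x T x K` / `Ne x T x L`.
#' @param n_shuffles number of surrogates (default 10000; a warning is
#'   issued below 100).
#' @param band frequency band averaged over (Hz, inclusive).
#' @param fs sampling rate (Hz).
#' @param seed optional seed for the permutations.
#' @return list with `p`, `observed`, `null` (the surrogate values).
#' @export
surrogate_mim_test <- function(x_epochs, y_epochs, n_shuffles = 10000,
                               band = c(8, 12), fs = 100, seed = NULL) {
  if (n_shuffles < 100) warning("fewer than 100 surrogate samples")
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  K <- dim(x_epochs)[3]; L <- dim(y_epochs)[3]
  ne <- dim(x_epochs)[1]; tt <- dim(x_epochs)[2]
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, tt - 1) / (tt - 1))
  nf <- tt %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / tt
  bsel <- which(freqs >= band[1] & freqs <= band[2])

  Fx <- array(0i, c(length(bsel), K, ne))
  Fy <- array(0i, c(length(bsel), L, ne))
  for (e in seq_len(ne)) {
    Fx[, , e] <- mvfft(win * matrix(x_epochs[e, , ], tt, K))[bsel, , drop = FALSE]
    Fy[, , e] <- mvfft(win * matrix(y_epochs[e, , ], tt, L))[bsel, , drop = FALSE]
  }

  mim_band <- function(perm) {
    val <- 0
    for (bi in seq_along(bsel)) {
      X <- matrix(Fx[bi, , ], K, ne)
      Y <- matrix(Fy[bi, , ], L, ne)
      Sxx <- (X %*% Conj(t(X))) / ne
      Syy <- (Y %*% Conj(t(Y))) / ne
      Sxy <- (X %*% Conj(t(Y[, perm, drop = FALSE]))) / ne
      dx <- 1 / sqrt(Re(diag(Sxx))); dy <- 1 / sqrt(Re(diag(Syy)))
      Cxx <- Re(Sxx) * outer(dx, dx)
      Cyy <- Re(Syy) * outer(dy, dy)
      Cxyi <- Im(Sxy) * outer(dx, dy)
      val <- val + sum(diag(.ridge_solve(Cxx) %*% Cxyi %*%
                              .ridge_solve(Cyy) %*% t(Cxyi)))
    }
    val / length(bsel)
  }

  observed <- mim_band(seq_len(ne))
  null <- vapply(seq_len(n_shuffles), function(s) mim_band(sample(ne)), 0)
  list(p = (1 + sum(null >= observed)) / (1 + n_shuffles),
       observed = observed, null = null)
}

#' FDR significance mask for an upper-triangle p-value set
#'
#' Benjamini-Hochberg correction at the given alpha over the upper
#' triangle of a region x region p-value matrix.
#'
#' @param p_mat R x R matrix of p-values (upper triangle used).
#' @param alpha FDR level.
#' @return logical R x R matrix (upper triangle), TRUE where significant.
#' @export
fdr_mask <- function(p_mat, alpha = 0.05) {
  R <- nrow(p_mat)
  up <- .upper_pairs(R)
  padj <- p.adjust(p_mat[up], method = "BH")
  mask <- matrix(FALSE, R, R)
  mask[up] <- padj <= alpha
  mask
}

#' Paired one-sided comparison of two pipelines' PR samples
#'
#' One-sided Wilcoxon signed-rank test of `b > a` on paired per-iteration
#' performance values.
#'
#' @param pr_a,pr_b equal-length paired numeric vectors.
#' @return one-sided p-value for `b > a`.
#' @export
compare_conditions <- function(pr_a, pr_b) {
  stopifnot(length(pr_a) == length(pr_b))
  d <- pr_b - pr_a
  if (all(d == 0)) stop("degenerate test: all paired differences are zero")
  wilcox.test(pr_b, pr_a, paired = TRUE, alternative = "greater",
              exact = length(d) <= 50 && !any(d == 0) &&
                !any(duplicated(abs(d[d != 0]))))$p.value
}

#' @export
print.fc_pr <- function(x, ...) {
  cat(sprintf("<fc_pr> PR=%.4f (raw %.4f; NI=%d of F=%d; ranks %s)\n",
              x$pr, x$raw_pr, x$NI, x$F,
              paste(round(x$ranks, 1), collapse = ", ")))
  invisible(x)
}
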