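.metric_names <- c("coh", "icoh", "mim", "mic", "gc", "trgc")
.directed_metrics <- c("gc", "trgc")

## region-pair candidate matrix (upper triangle, i < j)
.region_pairs <- function(R) {
  up <- .upper_pairs(R)
  up[order(up[, 1], up[, 2]), , drop = FALSE]
}

## Assemble an R x R matrix from per-pair values (symmetric or, for
## directed scores, antisymmetric with the value oriented first -> second).
.pairs_to_matrix <- function(vals, pairs_mat, R, antisym = FALSE) {
  M <- matrix(0, R, R)
  M[pairs_mat] <- vals
  M[pairs_mat[, c(2, 1), drop = FALSE]] <- if (antisym) -vals else vals
  M
}

#' Region-pair functional connectivity scores
#'
#' Builds the joint cross-spectrum of all region components and evaluates
#' the requested metrics for every region pair at every frequency;
#' frequency bins inside the band (inclusive) are averaged into a
#' region x region score matrix. Univariate metrics (coherence, iCOH) are
#' averaged over all component pairs; multivariate metrics (MIM, MIC, GC,
#' TRGC) act on the stacked component sets. In `fcmean` mode (MIM/MIC
#' only) the metric is computed per voxel pair and averaged.
#'
#' @param components an `fc_region_components`.
#' @param metrics subset of `coh, icoh, mim, mic, gc, trgc`.
#' @param epoch_len epoch length in samples.
#' @param fs sampling rate (Hz).
#' @param band scoring band (Hz, inclusive).
#' @param gc_order VAR model order for GC/TRGC.
#' @param keep_tensor also return the full per-frequency tensors.
#' @return list per metric: `band_matrix` (R x R; signed antisymmetric,
#'   seed -> target positive, for GC/TRGC), `directed` flag, and
#'   optionally `tensor` (R x R x Nfreq) and `freqs`.
#' @export
region_pair_scores <- function(components, metrics = "mim",
                               epoch_len = 200, fs = 100, band = c(8, 12),
                               gc_order = 20, keep_tensor = FALSE) {
  metrics <- match.arg(metrics, .metric_names, several.ok = TRUE)
  R <- components$n_regions
  pairs_mat <- .region_pairs(R)

  if (components$scheme == "fcmean") {
    if (!all(metrics %in% c("mim", "mic"))) {
      stop("parameter error: fcmean is supported for MIM and MIC only")
    }
    return(.fcmean_scores(components, metrics, epoch_len, fs, band,
                          pairs_mat))
  }

  st <- stack_components(components)
  ep <- epoch_data(st$data, epoch_len)
  S <- .csd_multichannel(ep, fs)
  freqs <- attr(S, "freqs")
  bsel <- freqs >= band[1] & freqs <= band[2]
  out <- list()

  und <- intersect(metrics, c("coh", "icoh", "mim", "mic"))
  if (length(und) > 0) {
    ## unless the full tensor is requested, only the band bins are needed
    if (keep_tensor) {
      res <- cpp_undirected_pairs(S, dim(S), st$membership, pairs_mat)
      band_cols <- which(bsel)
    } else {
      Sb <- S[, , bsel, drop = FALSE]
      res <- cpp_undirected_pairs(Sb, dim(Sb), st$membership, pairs_mat)
      band_cols <- seq_len(sum(bsel))
    }
    for (m in und) {
      vals <- rowMeans(res[[m]][, band_cols, drop = FALSE])
      out[[m]] <- list(metric = m, directed = FALSE,
                       band_matrix = .pairs_to_matrix(vals, pairs_mat, R))
      if (keep_tensor) {
        tens <- array(0, c(R, R, length(freqs)))
        for (f in seq_along(freqs)) {
          tens[, , f] <- .pairs_to_matrix(res[[m]][, f], pairs_mat, R)
        }
        out[[m]]$tensor <- tens; out[[m]]$freqs <- freqs
      }
    }
  }

  dir_m <- intersect(metrics, .directed_metrics)
  if (length(dir_m) > 0) {
    res <- cpp_gc_pairs(S, dim(S), st$membership, pairs_mat,
                        as.integer(gc_order), which(bsel),
                        time_reversed = "trgc" %in% dir_m)
    net <- res$Fxy - res$Fyx
    if ("gc" %in% dir_m) {
      out$gc <- list(metric = "gc", directed = TRUE,
                     band_matrix = .pairs_to_matrix(rowMeans(net), pairs_mat,
                                                    R, antisym = TRUE))
    }
    if ("trgc" %in% dir_m) {
      tr <- net - (res$Fxy_r - res$Fyx_r)
      out$trgc <- list(metric = "trgc", directed = TRUE,
                       band_matrix = .pairs_to_matrix(rowMeans(tr), pairs_mat,
                                                      R, antisym = TRUE))
    }
  }
  out[metrics]
}

## FC-first-mean-second: metric per voxel pair (3 x 3 component blocks),
## averaged over all voxel combinations of the two regions.
.fcmean_scores <- function(components, metrics, epoch_len, fs, band,
                           pairs_mat) {
  R <- components$n_regions
  vox_data <- list(); vox_region <- integer(0)
  for (r in seq_len(R)) {
    for (vx in components$components[[r]]) {
      vox_data <- c(vox_data, list(vx))
      vox_region <- c(vox_region, r)
    }
  }
  nvx <- length(vox_data)
  data <- t(do.call(cbind, vox_data))
  membership <- rep(seq_len(nvx), each = 3)
  ep <- epoch_data(data, epoch_len)
  S <- .csd_multichannel(ep, fs)
  freqs <- attr(S, "freqs")
  bsel <- which(freqs >= band[1] & freqs <= band[2])
  Sb <- S[, , bsel, drop = FALSE]
  vox_pairs <- .region_pairs(nvx)
  keep <- vox_region[vox_pairs[, 1]] != vox_region[vox_pairs[, 2]]
  vox_pairs <- vox_pairs[keep, , drop = FALSE]
  res <- cpp_undirected_pairs(Sb, dim(Sb), membership, vox_pairs)
  out <- list()
  for (m in metrics) {
    vals_vox <- rowMeans(res[[m]])
    key <- paste(pmin(vox_region[vox_pairs[, 1]], vox_region[vox_pairs[, 2]]),
                 pmax(vox_region[vox_pairs[, 1]], vox_region[vox_pairs[, 2]]))
    agg <- tapply(vals_vox, key, mean)
    vals <- as.numeric(agg[paste(pairs_mat[, 1], pairs_mat[, 2])])
    out[[m]] <- list(metric = m, directed = FALSE,
                     band_matrix = .pairs_to_matrix(vals, pairs_mat, R))
  }
  out
}

#' Run a full sensor-to-connectome pipeline on one recording
#'
#' Sensor data are standardized to unit mean per-channel variance (all
#' metrics are scale-invariant; this only places regularization grids on a
#' consistent scale), projected to source space with the chosen inverse
#' solution, aggregated within regions, and scored with the requested FC
#' metrics.
#'
#' @param recording an `fc_recording`.
#' @param leadfield the `fc_leadfield` used for inversion.
#' @param inverse one of `"lcmv"`, `"eloreta"`, `"dics"`, `"champagne"`.
#' @param scheme region-aggregation scheme (see [reduce_regions()]); DICS
#'   supports the `fixpc` schemes only.
#' @param metrics FC metrics to compute.
#' @param reg fixed regularization (eLORETA `a` / Champagne `sigma^2`);
#'   when `NULL` it is selected by five-fold spatial cross-validation.
#' @param cv_n_candidates size of the cross-validation candidate grid.
#' @param gc_order VAR order for GC/TRGC.
#' @param band scoring band in Hz.
#' @param keep_tensor keep per-frequency tensors (undirected metrics).
#' @return list per metric as in [region_pair_scores()], with the selected
#'   regularization attached as attribute `"reg"`.
#' @export
run_pipeline <- function(recording, leadfield, inverse = "lcmv",
                         scheme = "fixpc3", metrics = "mim", reg = NULL,
                         cv_n_candidates = 15, gc_order = 20,
                         band = c(8, 12), keep_tensor = FALSE) {
  inverse <- match.arg(inverse, c("lcmv", "eloreta", "dics", "champagne"))
  cfg <- recording$config
  Q <- recording$continuous
  Q <- Q / sqrt(mean(Q^2))

  if (inverse == "dics") {
    return(.run_pipeline_dics(Q, recording, leadfield, scheme, metrics,
                              gc_order, band))
  }

  filt <- switch(inverse,
    lcmv = fit_lcmv(sensor_covariance(Q), leadfield),
    eloreta = {
      if (is.null(reg)) {
        reg <- spatial_crossval_select(Q, leadfield, "eloreta",
                                       n_candidates = cv_n_candidates)$selected
      }
      fit_eloreta(NULL, leadfield, reg = reg)
    },
    champagne = {
      if (is.null(reg)) {
        reg <- spatial_crossval_select(Q, leadfield, "champagne",
                                       n_candidates = cv_n_candidates)$selected
      }
      fit_champagne(Q, leadfield, noise_var = reg)
    })
  est <- structure(list(time_courses = crossprod(filt$weights, Q),
                        method = inverse),
                   class = "fc_source_estimate")
  comps <- reduce_regions(est, leadfield$space, scheme,
                          ground_truth = recording$ground_truth)
  out <- region_pair_scores(comps, metrics, epoch_len = cfg$epoch_len,
                            fs = cfg$fs, band = band, gc_order = gc_order,
                            keep_tensor = keep_tensor)
  attr(out, "reg") <- filt$reg
  out
}

## DICS path: per-frequency beamforming of the sensor cross-spectrum,
## region PCA on the frequency-summed real source cross-spectrum, reduced
## per-frequency cross-spectra of the projected components.
.run_pipeline_dics <- function(Q, recording, leadfield, scheme, metrics,
                               gc_order, band) {
  fixc <- .scheme_fixpc_c(scheme)
  if (is.na(fixc)) {
    stop("parameter error: DICS supports fixpc schemes only")
  }
  cfg <- recording$config
  ep <- epoch_data(Q, cfg$epoch_len)
  Ssens <- .csd_multichannel(ep, cfg$fs)
  freqs <- attr(Ssens, "freqs")
  nf <- length(freqs)
  filt <- fit_dics(Ssens, leadfield)
  space <- leadfield$space
  R <- space$n_regions

  region_rows <- lapply(seq_len(R), function(r) {
    vox <- which(space$region_label == r)
    as.vector(t(outer(vox, c(2, 1, 0), function(v, o) 3 * v - o)))
  })

  ## accumulate per-region frequency-summed real source CSD and keep the
  ## per-frequency filters' region blocks
  csd_sum <- lapply(seq_len(R), function(r) {
    matrix(0, length(region_rows[[r]]), length(region_rows[[r]]))
  })
  Pf <- vector("list", nf)
  for (f in seq_len(nf)) {
    P <- dics_filter(filt, f)
    Pf[[f]] <- P
    Sf <- Ssens[, , f]
    for (r in seq_len(R)) {
      Pr <- P[, region_rows[[r]], drop = FALSE]
      SJr <- Re(Conj(t(Pr)) %*% Sf %*% Pr)
      csd_sum[[r]] <- csd_sum[[r]] + SJr
    }
  }
  proj <- dics_region_reduce(csd_sum, n_components = fixc)

  m <- R * fixc
  membership <- rep(seq_len(R), each = fixc)
  S <- array(0i, c(m, m, nf))
  for (f in seq_len(nf)) {
    B <- matrix(0, nrow(Pf[[f]]), m)
    for (r in seq_len(R)) {
      B[, (r - 1) * fixc + seq_len(fixc)] <-
        Pf[[f]][, region_rows[[r]], drop = FALSE] %*% proj[[r]]
    }
    S[, , f] <- Conj(t(B)) %*% Ssens[, , f] %*% B
  }
  attr(S, "freqs") <- freqs
  attr(S, "n_epochs") <- attr(Ssens, "n_epochs")
  class(S) <- "fc_cross_spectrum"

  pairs_mat <- .region_pairs(R)
  bsel <- freqs >= band[1] & freqs <= band[2]
  out <- list()
  und <- intersect(metrics, c("coh", "icoh", "mim", "mic"))
  if (length(und) > 0) {
    Sb <- S[, , bsel, drop = FALSE]
    res <- cpp_undirected_pairs(Sb, dim(Sb), membership, pairs_mat)
    for (mm in und) {
      vals <- rowMeans(res[[mm]])
      out[[mm]] <- list(metric = mm, directed = FALSE,
                        band_matrix = .pairs_to_matrix(vals, pairs_mat, R))
    }
  }
  dir_m <- intersect(metrics, .directed_metrics)
  if (length(dir_m) > 0) {
    res <- cpp_gc_pairs(S, dim(S), membership, pairs_mat,
                        as.integer(gc_order), which(bsel),
                        time_reversed = "trgc" %in% dir_m)
    net <- res$Fxy - res$Fyx
    if ("gc" %in% dir_m) {
      out$gc <- list(metric = "gc", directed = TRUE,
                     band_matrix = .pairs_to_matrix(rowMeans(net), pairs_mat,
                                                    R, antisym = TRUE))
    }
    if ("trgc" %in% dir_m) {
      tr <- net - (res$Fxy_r - res$Fyx_r)
      out$trgc <- list(metric = "trgc", directed = TRUE,
                       band_matrix = .pairs_to_matrix(rowMeans(tr), pairs_mat,
                                                      R, antisym = TRUE))
    }
  }
  out <- out[metrics]
  attr(out, "reg") <- NA_real_
  out
}
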