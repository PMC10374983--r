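#' SVD-based principal components of one region's source time courses
#'
#' Columns are mean-centered, an economy SVD `X = U D V'` is computed, and
#' the principal component time courses `U D` are returned together with
#' the explained-variance fractions `d_j^2 / sum(d^2)`. Component signs are
#' fixed by making the largest-magnitude loading of each component
#' positive.
#'
#' @param region_courses `Nt x (3 Rr)` matrix of the region's source time
#'   courses.
#' @return list with `components` (`Nt x r`, variance-ordered), `d`
#'   (singular values) and `explained`.
#' @export
region_svd <- function(region_courses) {
  X <- sweep(region_courses, 2, colMeans(region_courses))
  ## economy decomposition via the (small) column Gram matrix: X = U D V',
  ## X'X = V D^2 V', so the PC time courses U D equal X V
  e <- eigen(crossprod(X), symmetric = TRUE)
  d2 <- pmax(e$values, 0)
  d <- sqrt(d2)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(components = X %*% V, d = d,
       explained = if (sum(d2) > 0) d2 / sum(d2) else d2)
}

.known_schemes <- c(paste0("fixpc", 1:6), "varpc90", "varpc99", "meanfc",
                    "central", "fcmean", "truevox")

.scheme_fixpc_c <- function(scheme) {
  if (grepl("^fixpc[1-6]$", scheme)) as.integer(sub("fixpc", "", scheme))
  else NA_integer_
}

#' Aggregate voxel-level source time courses into region components
#'
#' Implements the region-aggregation schemes: a fixed number of strongest
#' PCs (`fixpc1` .. `fixpc6`), enough PCs to preserve 90% / 99% of the
#' region variance (`varpc90`, `varpc99`), orientation-wise voxel means
#' (`meanfc`), the most central voxel (`central`), all voxels retained for
#' later score averaging (`fcmean`), and the ground-truth voxel
#' (`truevox`).
#'
#' @param source_estimate `fc_source_estimate` (or `3Nv x Nt` matrix of
#'   source time courses).
#' @param space the `fc_source_space` the estimate lives in.
#' @param scheme one of the scheme tags above.
#' @param ground_truth ground-truth list (required for `truevox`): uses
#'   `$active` (data.frame with columns region, voxel).
#' @return `fc_region_components`: per-region component matrices
#'   (`Nt x C_r`), the per-region component counts and explained-variance
#'   fractions, and the scheme tag. For `fcmean` each region instead holds
#'   a list of per-voxel `Nt x 3` matrices.
#' @export
reduce_regions <- function(source_estimate, space, scheme = "fixpc3",
                           ground_truth = NULL) {
  scheme <- tolower(scheme)
  if (!scheme %in% .known_schemes) {
    stop("parameter error: unknown scheme '", scheme, "'")
  }
  J <- if (inherits(source_estimate, "fc_source_estimate")) {
    source_estimate$time_courses
  } else source_estimate
  stopifnot(nrow(J) == 3 * space$n_sources)
  if (scheme == "truevox" && is.null(ground_truth)) {
    stop("parameter error: truevox requires ground truth")
  }

  R <- space$n_regions
  comps <- vector("list", R)
  ncomp <- integer(R)
  explained <- vector("list", R)
  fixc <- .scheme_fixpc_c(scheme)

  for (r in seq_len(R)) {
    vox <- which(space$region_label == r)
    rows <- as.vector(t(outer(vox, c(2, 1, 0), function(v, o) 3 * v - o)))
    Xr <- t(J[rows, , drop = FALSE])   # Nt x 3Rr

    if (scheme == "meanfc") {
      M <- sapply(0:2, function(o) {
        rowMeans(Xr[, seq(1 + o, ncol(Xr), by = 3), drop = FALSE])
      })
      comps[[r]] <- sweep(M, 2, colMeans(M))
      ncomp[r] <- 3L
    } else if (scheme == "central") {
      pos <- space$positions[vox, , drop = FALSE]
      dm <- as.matrix(dist(pos))
      cv <- which.min(rowMeans(dm))
      sel <- (cv - 1) * 3 + 1:3
      M <- Xr[, sel, drop = FALSE]
      comps[[r]] <- sweep(M, 2, colMeans(M))
      ncomp[r] <- 3L
    } else if (scheme == "truevox") {
      act <- ground_truth$active
      tv <- act$voxel[act$region == r]
      if (length(tv) == 0) stop("parameter error: no ground-truth voxel for region ", r)
      pos_in_region <- match(tv, vox)
      sel <- as.vector(t(outer(pos_in_region, 0:2, function(p, o) (p - 1) * 3 + 1 + o)))
      M <- Xr[, sel, drop = FALSE]
      comps[[r]] <- sweep(M, 2, colMeans(M))
      ncomp[r] <- ncol(M)
    } else if (scheme == "fcmean") {
      comps[[r]] <- lapply(seq_along(vox), function(i) {
        M <- Xr[, (i - 1) * 3 + 1:3, drop = FALSE]
        sweep(M, 2, colMeans(M))
      })
      ncomp[r] <- 3L * length(vox)
    } else {
      sv <- region_svd(Xr)
      if (!is.na(fixc)) {
        if (ncol(sv$components) < fixc) {
          stop("parameter error: region ", r, " has fewer than ", fixc,
               " dimensions")
        }
        keep <- seq_len(fixc)
      } else {
        q <- if (scheme == "varpc90") 0.90 else 0.99
        keep <- seq_len(which(cumsum(sv$explained) >= q - 1e-12)[1])
      }
      comps[[r]] <- sv$components[, keep, drop = FALSE]
      ncomp[r] <- length(keep)
      explained[[r]] <- sv$explained[keep]
    }
  }

  structure(list(components = comps, n_components = ncomp,
                 explained = explained, scheme = scheme,
                 n_regions = R),
            class = "fc_region_components")
}

#' Region projection vectors from per-frequency source cross-spectra (DICS)
#'
#' For frequency-resolved (DICS) source reconstructions, region PCA is
#' performed on the real part of the region's source-level cross-spectrum
#' summed across frequencies; the top-C eigenvectors define the projection
#' applied to every frequency's block.
#'
#' @param region_csd_sum list (one entry per region) of real symmetric
#'   `3Rr x 3Rr` matrices (summed real source cross-spectra).
#' @param n_components number of components C (as in `fixpc-C`).
#' @return list per region of `3Rr x C` projection matrices, with
#'   eigenvalues attached as attribute `"values"`.
#' @export
dics_region_reduce <- function(region_csd_sum, n_components = 3) {
  lapply(region_csd_sum, function(M) {
    if (max(abs(M - t(M))) > 1e-6 * max(1e-300, max(abs(M)))) {
      stop("data error: region cross-spectrum not symmetric")
    }
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    if (ncol(e$vectors) < n_components) {
      stop("parameter error: region has fewer dimensions than components")
    }
    v <- e$vectors[, seq_len(n_components), drop = FALSE]
    for (j in seq_len(ncol(v))) {
      i <- which.max(abs(v[, j]))
      if (v[i, j] < 0) v[, j] <- -v[, j]
    }
    attr(v, "values") <- e$values[seq_len(n_components)]
    v
  })
}

#' Stack region components into a channel matrix with region membership
#'
#' @param components an `fc_region_components` (not `fcmean`).
#' @return list with `data` (channels x Nt) and `membership` (region id per
#'   channel).
#' @export
stack_components <- function(components) {
  stopifnot(inherits(components, "fc_region_components"))
  if (components$scheme == "fcmean") {
    stop("fcmean components are paired per voxel; use region_pair_scores")
  }
  data <- t(do.call(cbind, components$components))
  membership <- rep(seq_len(components$n_regions),
                    components$n_components)
  list(data = data, membership = as.integer(membership))
}

#' @export
print.fc_region_components <- function(x, ...) {
  cat("<fc_region_components> scheme=", x$scheme, ", ", x$n_regions,
      " regions, components per region ",
      paste(range(x$n_components), collapse = "-"), "\n", sep = "")
  invisible(x)
}
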