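#' @useDynLib fcpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans rnorm runif sd var quantile median p.adjust
#'   wilcox.test fft mvfft dist
NULL

golden_angle <- pi * (3 - sqrt(5))

## Quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- golden_angle * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

## Random 3D rotation matrix (uniform over SO(3) is not needed; a seeded
## QR-based orthogonal matrix with positive determinant suffices).
random_rotation <- function() {
  qr_m <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_m)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Build a synthetic cortical source space
#'
#' Places `n_sources` dipolar sources quasi-uniformly on a spherical cortical
#' shell, assigns each a radial (outward) orientation, and partitions them
#' into `n_regions` spatially contiguous regions by k-means clustering on the
#' source coordinates. Regions are relabelled by centroid angle so that the
#' labelling is a deterministic function of the geometry.
#'
#' @param n_sources number of dipolar sources (>= 2 * n_regions).
#' @param n_regions number of cortical regions.
#' @param seed integer seed controlling the (random) orientation of the
#'   source lattice and the clustering initialization.
#' @param inner_radius radius of the innermost (brain) shell in meters.
#' @param shell_frac fraction of `inner_radius` at which sources sit.
#' @return An object of class `fc_source_space` with fields `positions`
#'   (Nv x 3, meters), `normals` (Nv x 3 unit vectors), `region_label`
#'   (integer in 1..R), `n_regions`, `n_sources`.
#' @export
build_source_space <- function(n_sources, n_regions, seed = 0,
                               inner_radius = 0.087, shell_frac = 0.8) {
  stopifnot(n_sources >= 1, n_regions >= 1)
  if (n_sources < 2 * n_regions) {
    stop("invalid parcellation: need n_sources >= 2 * n_regions")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  pts <- fibonacci_sphere(n_sources) %*% random_rotation()
  positions <- pts * (shell_frac * inner_radius)
  normals <- pts  # radial, already unit length

  if (n_regions == 1) {
    labels <- rep(1L, n_sources)
  } else {
    km <- kmeans(positions, centers = n_regions, nstart = 5, iter.max = 100)
    labels <- km$cluster
    labels <- .enforce_min_region_size(positions, labels, n_regions, min_size = 2)
    labels <- .relabel_by_centroid_angle(positions, labels, n_regions)
  }

  structure(
    list(positions = positions, normals = normals,
         region_label = as.integer(labels),
         n_regions = as.integer(n_regions),
         n_sources = as.integer(n_sources),
         inner_radius = inner_radius),
    class = "fc_source_space")
}

## Move nearest points out of large clusters into clusters below min_size.
.enforce_min_region_size <- function(positions, labels, k, min_size = 2) {
  repeat {
    sizes <- tabulate(labels, nbins = k)
    small <- which(sizes < min_size)
    if (length(small) == 0) break
    r <- small[1]
    cen <- if (sizes[r] > 0) {
      colMeans(positions[labels == r, , drop = FALSE])
    } else {
      ## empty cluster: seed it at the point farthest from its own centroid
      positions[which.max(rowSums(positions^2)), ]
    }
    donor_ok <- labels %in% which(sizes > min_size)
    d2 <- rowSums(sweep(positions, 2, cen)^2)
    d2[!donor_ok] <- Inf
    labels[which.min(d2)] <- r
  }
  labels
}

.relabel_by_centroid_angle <- function(positions, labels, k) {
  cz <- vapply(seq_len(k), function(r) mean(positions[labels == r, 3]), 0)
  caz <- vapply(seq_len(k), function(r) {
    p <- colMeans(positions[labels == r, , drop = FALSE])
    atan2(p[2], p[1])
  }, 0)
  ord <- order(-round(cz, 10), caz)
  new <- integer(k)
  new[ord] <- seq_len(k)
  new[labels]
}

#' Build a sensor array on the scalp
#'
#' Sensors are placed on the upper part of the outer sphere along a Fibonacci
#' spiral, emulating a standard EEG cap layout.
#'
#' @param n_sensors number of sensors (default 97).
#' @param radius scalp radius in meters.
#' @param z_min lowest relative height (fraction of radius) of a sensor.
#' @return `fc_sensor_array` with `positions` (Ns x 3) and `n_sensors`.
#' @export
build_sensor_array <- function(n_sensors = 97, radius = 0.1, z_min = 0.02) {
  stopifnot(n_sensors >= 2)
  i <- seq_len(n_sensors)
  z <- 1 - (i - 0.5) / n_sensors * (1 - z_min)
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- golden_angle * (i - 1)
  pos <- cbind(r * cos(phi), r * sin(phi), z) * radius
  structure(list(positions = pos, n_sensors = as.integer(n_sensors),
                 radius = radius),
            class = "fc_sensor_array")
}

## Transfer coefficients t_n for a dipole in the innermost shell of a
## 3-concentric-spheres volume conductor (radii scaled so the scalp is 1).
## The primary (infinite-medium) potential contributes rho^-(n+1) inside the
## brain shell; boundary conditions (continuity of potential and of radial
## current, zero current through the scalp) determine the scalp-surface
## harmonic coefficient t_n = A3 + B3.
shell_transfer_coefficients <- function(n_terms, radii, cond) {
  r1 <- radii[1]; r2 <- radii[2]
  s1 <- cond[1]; s2 <- cond[2]; s3 <- cond[3]
  t_n <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    A <- matrix(0, 5, 5)
    b <- numeric(5)
    ## unknowns: A1, A2, B2, A3, B3
    A[1, ] <- c(r1^n, -r1^n, -r1^(-(n + 1)), 0, 0)
    b[1] <- -r1^(-(n + 1))
    A[2, ] <- c(s1 * n * r1^(n - 1), -s2 * n * r1^(n - 1),
                s2 * (n + 1) * r1^(-(n + 2)), 0, 0)
    b[2] <- s1 * (n + 1) * r1^(-(n + 2))
    A[3, ] <- c(0, r2^n, r2^(-(n + 1)), -r2^n, -r2^(-(n + 1)))
    A[4, ] <- c(0, s2 * n * r2^(n - 1), -s2 * (n + 1) * r2^(-(n + 2)),
                -s3 * n * r2^(n - 1), s3 * (n + 1) * r2^(-(n + 2)))
    A[5, ] <- c(0, 0, 0, n, -(n + 1))
    x <- solve(A, b)
    t_n[n] <- x[4] + x[5]
  }
  t_n
}

## Potential at scalp-surface sensors for one dipole (general multi-shell
## series). pos: dipole position (scaled by scalp radius), E: Ns x 3 unit
## sensor directions, t_n: transfer coefficients, k0: overall scale.
## Returns Ns x 3 gain (columns = unit dipole moments along x, y, z).
.dipole_gain <- function(pos, E, t_n, k0) {
  b <- sqrt(sum(pos^2))
  u <- if (b < 1e-12) c(0, 0, 1) else pos / b
  cosg <- drop(E %*% u)
  cosg <- pmin(1, pmax(-1, cosg))
  Tm <- E - outer(cosg, u)          # un-normalized tangential directions
  sing <- sqrt(pmax(0, 1 - cosg^2))
  ok <- sing > 1e-12
  Tm[ok, ] <- Tm[ok, , drop = FALSE] / sing[ok]
  Tm[!ok, ] <- 0

  n_terms <- length(t_n)
  ns <- length(cosg)
  cR <- numeric(ns); cT <- numeric(ns)
  Pnm1 <- rep(1, ns)        # P_0
  Pn <- cosg                # P_1
  Pdnm1 <- rep(0, ns)       # P_0'
  Pdn <- rep(1, ns)         # P_1'
  bet <- 1                  # b^(n-1)
  for (n in seq_len(n_terms)) {
    if (n > 1) {
      Pnew <- ((2 * n - 1) * cosg * Pn - (n - 1) * Pnm1) / n
      Pdnew <- Pdnm1 + (2 * n - 1) * Pn
      Pnm1 <- Pn; Pn <- Pnew
      Pdnm1 <- Pdn; Pdn <- Pdnew
      bet <- bet * b
    }
    w <- t_n[n] * bet
    cR <- cR + w * n * Pn
    cT <- cT + w * (sing * Pdn)
  }
  k0 * (outer(cR, u) + cT * Tm)
}

#' Build an analytic three-shell spherical leadfield
#'
#' Computes the sensor potentials of unit dipoles by the truncated Legendre
#' series solution for three concentric spheres (brain, skull, scalp),
#' re-references all columns to the common average, and projects each
#' three-column source block onto the source normal to obtain the scalar
#' (orientation-constrained) leadfield.
#'
#' @param space an `fc_source_space`.
#' @param sensors an `fc_sensor_array`.
#' @param conductivities length-3 positive conductivities (S/m) of brain,
#'   skull, scalp. Defaults to standard values 0.33 / 0.0042 / 0.33.
#' @param radii length-3 increasing shell radii in meters.
#' @param n_terms number of Legendre series terms.
#' @return `fc_leadfield` with `gain_vector` (Ns x 3Nv), `gain_scalar`
#'   (Ns x Nv), and geometry metadata. Columns are common-average referenced
#'   and globally rescaled to unit mean column norm.
#' @export
build_leadfield <- function(space, sensors,
                            conductivities = c(0.33, 0.0042, 0.33),
                            radii = c(0.087, 0.092, 0.100),
                            n_terms = 60) {
  stopifnot(inherits(space, "fc_source_space"),
            inherits(sensors, "fc_sensor_array"))
  if (any(diff(radii) <= 0) || any(radii <= 0)) {
    stop("geometry error: radii must be positive and strictly increasing")
  }
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  rad <- sqrt(rowSums(space$positions^2))
  if (any(rad >= radii[1])) {
    stop("geometry error: all sources must lie strictly inside the inner shell")
  }
  R <- radii[3]
  E <- sensors$positions / sqrt(rowSums(sensors$positions^2))
  t_n <- shell_transfer_coefficients(n_terms, radii / R, conductivities)
  k0 <- 1 / (4 * pi * conductivities[1] * R^2)

  nv <- space$n_sources
  ns <- sensors$n_sensors
  G <- matrix(0, ns, 3 * nv)
  for (v in seq_len(nv)) {
    G[, 3 * v - (2:0)] <- .dipole_gain(space$positions[v, ] / R, E, t_n, k0)
  }
  ## common-average reference
  G <- sweep(G, 2, colMeans(G))
  ## scalar leadfield: project 3-blocks on the source normal
  Gs <- matrix(0, ns, nv)
  for (v in seq_len(nv)) {
    Gs[, v] <- G[, 3 * v - (2:0)] %*% space$normals[v, ]
  }
  ## arbitrary physical scale: normalize to unit mean scalar column norm so
  ## regularization grids expressed relative to data traces are meaningful
  sc <- mean(sqrt(colSums(Gs^2)))
  if (sc > 0) { G <- G / sc; Gs <- Gs / sc }

  structure(
    list(gain_vector = G, gain_scalar = Gs, reference = "common_average",
         space = space, sensors = sensors,
         conductivities = conductivities, radii = radii,
         n_terms = n_terms),
    class = "fc_leadfield")
}

#' Build a complete head model (source space, sensors, leadfield)
#'
#' Convenience wrapper producing the default benchmarking forward model.
#'
#' @inheritParams build_source_space
#' @param n_sensors number of scalp sensors.
#' @param ... passed to [build_leadfield()].
#' @return `fc_leadfield` (which embeds the source space and sensor array).
#' @export
build_head_model <- function(n_sources = 500, n_regions = 68, seed = 0,
                             n_sensors = 97, ...) {
  space <- build_source_space(n_sources, n_regions, seed = seed)
  sensors <- build_sensor_array(n_sensors)
  build_leadfield(space, sensors, ...)
}

## Closed-form per-harmonic solution for a single homogeneous sphere with
## insulating exterior; used as an independent check of the shell solver.
single_sphere_potential <- function(pos, moment, E, radius, conductivity,
                                    n_terms = 100) {
  b <- sqrt(sum(pos^2)) / radius
  u <- if (b < 1e-12) moment / sqrt(sum(moment^2)) else pos / sqrt(sum(pos^2))
  cosg <- pmin(1, pmax(-1, drop(E %*% u)))
  Tm <- E - outer(cosg, u)
  sing <- sqrt(pmax(0, 1 - cosg^2))
  ok <- sing > 1e-12
  Tm[ok, ] <- Tm[ok, , drop = FALSE] / sing[ok]
  Tm[!ok, ] <- 0
  mr <- sum(moment * u)
  mt <- drop(Tm %*% moment)
  v <- numeric(length(cosg))
  Pnm1 <- rep(1, length(cosg)); Pn <- cosg
  Pdnm1 <- rep(0, length(cosg)); Pdn <- rep(1, length(cosg))
  bet <- 1
  for (n in seq_len(n_terms)) {
    if (n > 1) {
      Pnew <- ((2 * n - 1) * cosg * Pn - (n - 1) * Pnm1) / n
      Pdnew <- Pdnm1 + (2 * n - 1) * Pn
      Pnm1 <- Pn; Pn <- Pnew
      Pdnm1 <- Pdn; Pdn <- Pdnew
      bet <- bet * b
    }
    coef <- (2 * n + 1) / n * bet
    v <- v + coef * (n * mr * Pn + mt * (sing * Pdn))
  }
  v / (4 * pi * conductivity * radius^2)
}

#' @export
print.fc_source_space <- function(x, ...) {
  cat("<fc_source_space> ", x$n_sources, " sources, ", x$n_regions,
      " regions; region sizes ",
      paste(range(tabulate(x$region_label)), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' @export
print.fc_leadfield <- function(x, ...) {
  cat("<fc_leadfield> ", nrow(x$gain_scalar), " sensors x ",
      ncol(x$gain_scalar), " sources (", x$space$n_regions,
      " regions), common-average referenced\n", sep = "")
  invisible(x)
}

## Save/restore the RNG state so seeded builders do not disturb the caller's
## random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
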