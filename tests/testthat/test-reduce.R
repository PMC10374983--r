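test_that("region SVD matches the covariance eigen-decomposition route", {
  set.seed(1)
  X <- matrix(rnorm(200 * 9), 200, 9) %*% diag(c(5, 4, 3, 2, 1, 1, 0.5, 0.2, 0.1))
  sv <- region_svd(X)
  ## lambda_v = d_v^2 / (N - 1) equals the covariance eigenvalues
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sv$d^2 / (nrow(X) - 1), ev, tolerance = 1e-8)
  ## the PC time courses U D equal the classical svd route
  sv_ref <- svd(scale(X, scale = FALSE))
  expect_equal(abs(sv$components), abs(sv_ref$u %*% diag(sv_ref$d)),
               tolerance = 1e-6)
  expect_equal(sum(sv$explained), 1, tolerance = 1e-12)
  ## components are orthogonal with non-increasing variance
  G <- crossprod(sv$components)
  expect_lt(max(abs(G - diag(diag(G)))) / max(diag(G)), 1e-8)
  expect_true(all(diff(diag(G)) <= 1e-8))
})

test_that("duplicate columns collapse to a single component", {
  set.seed(2)
  x <- rnorm(500)
  X <- cbind(x, x)
  sv <- region_svd(X)
  expect_equal(sv$explained[1], 1, tolerance = 1e-12)
  expect_lt(sv$d[2] / sv$d[1], 1e-8)
})

test_that("fixed and variable PC schemes keep the documented counts", {
  model <- tiny_model()
  set.seed(3)
  rec <- simulate_recording(fast_config(seed = 4), model)
  filt <- fit_lcmv(sensor_covariance(rec), model)
  est <- apply_inverse(filt, rec)

  c3 <- reduce_regions(est, model$space, "fixpc3")
  expect_true(all(c3$n_components == 3))
  c1 <- reduce_regions(est, model$space, "fixpc1")
  expect_true(all(c1$n_components == 1))

  v90 <- reduce_regions(est, model$space, "varpc90")
  v99 <- reduce_regions(est, model$space, "varpc99")
  expect_true(all(v99$n_components >= v90$n_components))
  for (r in seq_len(model$space$n_regions)) {
    expect_gte(sum(v90$explained[[r]]), 0.90)
  }
  expect_error(reduce_regions(est, model$space, "nope"), "parameter error")
  expect_error(reduce_regions(est, model$space, "truevox"), "parameter error")
})

test_that("varpc uses an inclusive threshold", {
  ## construct a region with explained fractions exactly (0.9, 0.1)
  t <- seq_len(400)
  b1 <- sin(2 * pi * t / 40); b2 <- cos(2 * pi * t / 40)
  X <- cbind(sqrt(0.9) * b1, sqrt(0.1) * b2) %*%
    matrix(c(1, 1, 1, -1) / sqrt(2), 2, 2)
  sv <- region_svd(X)
  expect_equal(sv$explained[1], 0.9, tolerance = 1e-9)
  keep <- which(cumsum(sv$explained) >= 0.9 - 1e-12)[1]
  expect_equal(keep, 1L)
})

test_that("central voxel of a collinear region is the middle one", {
  positions <- rbind(c(0, 0, 0.05), c(0, 0.01, 0.05), c(0, 0.02, 0.05))
  space <- manual_space(positions, n_regions = 1)
  J <- matrix(rnorm(9 * 100), 9, 100)
  comps <- reduce_regions(J, space, "central")
  ## the middle voxel (index 2) has the smallest mean distance
  expect_equal(comps$n_components, 3L)
  mid <- sweep(t(J[4:6, , drop = FALSE]), 2,
               colMeans(t(J[4:6, , drop = FALSE])))
  expect_equal(comps$components[[1]], mid, tolerance = 1e-12)
})

test_that("meanfc averages orientations and equals PCA for identical voxels", {
  positions <- rbind(c(0, 0, 0.05), c(0, 0.01, 0.05))
  space <- manual_space(positions, n_regions = 1)
  base <- matrix(rnorm(3 * 300), 3, 300)
  J <- rbind(base, base)   # two identical voxels
  comps <- reduce_regions(J, space, "meanfc")
  expect_equal(comps$components[[1]],
               sweep(t(base), 2, rowMeans(base)), tolerance = 1e-12)
  ## PCA of two identical voxels spans the same 3-dim subspace
  pc <- reduce_regions(J, space, "fixpc3")
  cc <- stats::cancor(comps$components[[1]], pc$components[[1]])
  expect_equal(cc$cor, rep(1, 3), tolerance = 1e-8)
})

test_that("truevox picks the ground-truth voxels", {
  model <- tiny_model()
  rec <- simulate_recording(fast_config(seed = 5), model)
  filt <- fit_lcmv(sensor_covariance(rec), model)
  est <- apply_inverse(filt, rec)
  comps <- reduce_regions(est, model$space, "truevox",
                          ground_truth = rec$ground_truth)
  expect_true(all(comps$n_components == 3))
  r1 <- rec$ground_truth$pairs$seed_region[1]
  v1 <- rec$ground_truth$pairs$seed_voxel[1]
  ref <- t(est$time_courses[3 * v1 - (2:0), ])
  expect_equal(comps$components[[r1]], sweep(ref, 2, colMeans(ref)),
               tolerance = 1e-12)
})

test_that("reduction is idempotent for fixpc components", {
  set.seed(6)
  X <- matrix(rnorm(400 * 6), 400, 6)
  sv <- region_svd(X)
  top3 <- sv$components[, 1:3]
  sv2 <- region_svd(top3)
  ## already-orthogonal components are reproduced (up to sign)
  expect_equal(abs(sv2$components), abs(top3), tolerance = 1e-8)
})

test_that("DICS region reduction matches time-domain PCA on stationary data", {
  set.seed(7)
  nt <- 20000
  mix <- matrix(rnorm(36), 6, 6)
  src <- rbind(band_filter(rnorm(nt), c(5, 15), 100) * 3,
               band_filter(rnorm(nt), c(10, 30), 100) * 2,
               matrix(rnorm(4 * nt, sd = 0.3), 4))
  X <- mix %*% src   # 6 "source dimensions" in one region
  ## frequency-domain route: sum of real CSD across frequencies
  ep <- as_epochs(X, 200)
  S <- fcpipe:::.csd_multichannel(ep, 100)
  csd_sum <- Reduce(`+`, lapply(seq_len(dim(S)[3]), function(f) Re(S[, , f])))
  proj <- dics_region_reduce(list(csd_sum), n_components = 2)[[1]]
  ## time-domain route
  sv <- region_svd(t(X))
  evec <- eigen(stats::cov(t(X)), symmetric = TRUE)$vectors[, 1:2]
  cs <- abs(crossprod(proj, evec))
  expect_gt(min(svd(cs)$d), 0.95)  # same leading subspace

  ## frequency-flat diagonal cross-spectrum: projections are coordinate axes
  D <- diag(c(4, 3, 2, 1))
  proj2 <- dics_region_reduce(list(D), n_components = 2)[[1]]
  expect_equal(abs(proj2), cbind(c(1, 0, 0, 0), c(0, 1, 0, 0)),
               tolerance = 1e-12, ignore_attr = TRUE)

  ## rank-1 region
  u <- c(1, 2, -1) / sqrt(6)
  r1 <- dics_region_reduce(list(outer(u, u)), n_components = 2)[[1]]
  expect_equal(attr(r1, "values")[2], 0, tolerance = 1e-12)
  expect_error(dics_region_reduce(list(matrix(c(1, 2, 0, 1), 2))),
               "data error")
})
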