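test_that("band filter is zero-phase, selective, and validates the band", {
  fs <- 100
  t <- seq(1, 5000) / fs
  s10 <- sin(2 * pi * 10 * t)
  f10 <- band_filter(s10, c(8, 12), fs)
  mid <- 1000:4000
  expect_gt(max(abs(f10[mid])), 0.95)   # in-band amplitude within 5%
  ## zero phase: peak positions unchanged (cross-correlation peaks at lag 0)
  cc <- ccf(f10[mid], s10[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  ## 30 Hz attenuation matches the squared Butterworth magnitude response
  s30 <- sin(2 * pi * 30 * t)
  f30 <- band_filter(s30, c(8, 12), fs)
  bf <- signal::butter(2, c(8, 12) / 50, "pass")
  H30 <- abs(polyval(rev(bf$b), exp(-1i * 2 * pi * 30 / fs)) /
               polyval(rev(bf$a), exp(-1i * 2 * pi * 30 / fs)))^2
  att_db <- -20 * log10(max(abs(f30[mid])))
  expect_gte(att_db, 20)
  expect_equal(max(abs(f30[mid])), H30, tolerance = 0.15)

  ## white noise output spectrum peaks inside the band
  set.seed(4)
  w <- band_filter(rnorm(20000), c(8, 12), fs)
  sp <- stats::spec.pgram(ts(w, frequency = fs), plot = FALSE, span = 21)
  expect_true(sp$freq[which.max(sp$spec)] >= 8 && sp$freq[which.max(sp$spec)] <= 12)

  expect_error(band_filter(s10, c(8, 60), fs), "parameter error")
  expect_error(band_filter(s10, c(0, 12), fs), "parameter error")
})

test_that("interacting pairs are exact delayed copies", {
  pr <- make_interacting_pair(2000, delay = 5, seed = 3)
  ## circular alignment: shifting the receiver back by 5 recovers the sender
  expect_equal(fcpipe:::delay_series(pr$receiver, -5), pr$sender,
               tolerance = 1e-12)
  expect_equal(cor(pr$sender[6:2000], pr$receiver[6:2000]) < 1, TRUE)
  expect_equal(max(abs(pr$receiver - fcpipe:::delay_series(pr$sender, 5))), 0)
  expect_error(make_interacting_pair(2000, delay = 0), "parameter error")
  expect_error(make_interacting_pair(100, delay = 100), "parameter error")
  ## fractional delays preserve the l2 norm (spectral shift is unitary)
  pf <- make_interacting_pair(2000, delay = 2.5, seed = 3)
  expect_equal(sum(pf$sender^2), sum(pf$receiver^2), tolerance = 1e-9)
})

test_that("default delays span 50-200 ms, i.e. 5-20 samples at 100 Hz", {
  model <- tiny_model()
  d <- replicate(6, {
    rec <- simulate_recording(fast_config(seed = sample.int(1e6, 1)), model)
    rec$ground_truth$pairs$delay_samples
  })
  expect_true(all(d >= 5 & d <= 20))
})

test_that("source mixing sets the stated source-level SNR", {
  set.seed(5)
  g <- band_filter(rnorm(4000), c(8, 12), 100)
  p <- pink_noise(4000)
  expect_equal(assemble_source_signal(g, p, theta = 1), g / sqrt(sum(g^2)),
               tolerance = 1e-12)
  expect_equal(theta_to_db(0.6), 20 * log10(0.6 / 0.4))
  expect_equal(round(theta_to_db(0.6), 1), 3.5)
  expect_equal(theta_to_db(0.5), 0)
  expect_equal(db_to_theta(theta_to_db(0.73)), 0.73, tolerance = 1e-12)
  expect_error(assemble_source_signal(rep(0, 100), pink_noise(256)[1:100], 0.5),
               "degenerate")
})

test_that("pink noise has a 1/f spectrum and is seed-deterministic", {
  slopes <- vapply(1:25, function(i) {
    x <- pink_noise(18000, seed = i)
    sp <- stats::spec.pgram(ts(x, frequency = 100), plot = FALSE, span = 31)
    sel <- sp$freq >= 1 & sp$freq <= 40
    unname(coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
  }, 0)
  expect_gt(mean(slopes), -1.3)
  expect_lt(mean(slopes), -0.7)
  expect_identical(pink_noise(1024, seed = 1), pink_noise(1024, seed = 1))
  ## independence: raw correlations of 1/f series are dominated by the few
  ## low-frequency components, so whiten by differencing before comparing
  expect_lt(abs(cor(diff(pink_noise(18000, seed = 1)),
                    diff(pink_noise(18000, seed = 2)))), 0.05)
  expect_error(pink_noise(100))
})

test_that("sensor mixing hits the target band-limited SNR and is reproducible", {
  model <- tiny_model()
  cfg <- fast_config(seed = 9, highpass_hz = NA)
  rec <- simulate_recording(cfg, model, keep_components = TRUE)
  ratio <- fcpipe:::.band_frob(rec$signal_component, c(8, 12), 100) /
    fcpipe:::.band_frob(rec$noise_component, c(8, 12), 100)
  expect_equal(ratio, 0.6 / 0.4, tolerance = 0.01)
  ## norm bookkeeping: the mixed (pre-high-pass) data have unit band norm
  expect_equal(fcpipe:::.band_frob(rec$continuous, c(8, 12), 100), 1,
               tolerance = 1e-6)

  rec2 <- simulate_recording(cfg, model, keep_components = TRUE)
  expect_identical(rec$continuous, rec2$continuous)

  ## theta_snr = 1 boundary: data equal the normalized projected signal
  cfg1 <- fast_config(seed = 9, theta_snr = 1 - 1e-12, highpass_hz = NA)
  rec1 <- simulate_recording(cfg1, model, keep_components = TRUE)
  expect_equal(rec1$continuous,
               rec1$signal_component / (1 - 1e-12) /
                 fcpipe:::.band_frob(rec1$signal_component / (1 - 1e-12),
                                     c(8, 12), 100),
               tolerance = 1e-6)
})

test_that("sensor spectrum shows an alpha bump over the 1/f background", {
  model <- small_model()
  rec <- simulate_recording(sim_config(duration_s = 90, seed = 2), model)
  x <- rec$continuous[3, ]
  sp <- stats::spec.pgram(ts(x, frequency = 100), plot = FALSE, span = 31)
  alpha <- mean(sp$spec[sp$freq >= 8 & sp$freq <= 12])
  sides <- mean(sp$spec[(sp$freq >= 15 & sp$freq <= 25)])
  expect_gt(alpha / sides, 2)
})

test_that("sender and receiver ground-truth series share their spectrum", {
  pr <- make_interacting_pair(4096, delay = 7, seed = 12)
  ps <- Mod(fft(pr$sender))^2
  pr2 <- Mod(fft(pr$receiver))^2
  expect_equal(ps, pr2, tolerance = 1e-8)
})

test_that("correlated-pairs mode duplicates time courses and expands truth", {
  model <- small_model()
  cfg <- fast_config(seed = 21)
  rec <- simulate_correlated_pairs(cfg, model, keep_components = TRUE)
  expect_equal(nrow(rec$ground_truth$truth_regions), 4L)
  ## senders are rows 1:2, receivers rows 3:4 of the stored source signals
  js <- rec$source_signals
  expect_equal(cor(js[1, ], js[2, ]), 1, tolerance = 1e-12)
  expect_equal(cor(js[3, ], js[4, ]), 1, tolerance = 1e-12)
  expect_error(simulate_correlated_pairs(fast_config(n_interactions = 3),
                                         model), "parameter error")
  ## different seed: same duplication property, different regions possible
  rec2 <- simulate_correlated_pairs(fast_config(seed = 22), model,
                                    keep_components = TRUE)
  expect_equal(cor(rec2$source_signals[1, ], rec2$source_signals[2, ]), 1,
               tolerance = 1e-12)
})

test_that("two-sources-per-region mode yields one region pair, two links", {
  model <- small_model()
  rec <- simulate_two_sources_per_region(fast_config(seed = 31), model)
  gt <- rec$ground_truth
  expect_equal(nrow(gt$truth_regions), 1L)
  expect_equal(nrow(gt$pairs), 2L)
  expect_false(gt$pairs$seed_voxel[1] == gt$pairs$seed_voxel[2])
  expect_false(gt$pairs$target_voxel[1] == gt$pairs$target_voxel[2])
  ## every region hosts two active series
  expect_true(all(table(gt$active$region) == 2))
})
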