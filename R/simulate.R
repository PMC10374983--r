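#' Convert a mixing weight to a signal-to-noise ratio in dB
#'
#' The mixing model `s = theta * signal + (1 - theta) * noise` (with both
#' parts unit-normalized) corresponds to an SNR of
#' `20 * log10(theta / (1 - theta))` dB.
#'
#' @param theta mixing weight in (0, 1).
#' @return SNR in dB.
#' @export
theta_to_db <- function(theta) {
  stopifnot(all(theta > 0), all(theta < 1))
  20 * log10(theta / (1 - theta))
}

#' @rdname theta_to_db
#' @param db SNR in dB.
#' @export
db_to_theta <- function(db) {
  r <- 10^(db / 20)
  r / (1 + r)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a second-order digital Butterworth band-pass filter forward and
#' backward (zero phase distortion) along time.
#'
#' @param x numeric vector, or matrix with channels in rows and time in
#'   columns.
#' @param band length-2 band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 2).
#' @return filtered data, same shape as `x`.
#' @export
band_filter <- function(x, band = c(8, 12), fs = 100, order = 2) {
  if (!(band[1] > 0 && band[2] > band[1] && band[2] < fs / 2)) {
    stop("parameter error: band must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  .apply_filtfilt(x, bf)
}

#' Zero-phase Butterworth high-pass filter
#'
#' @inheritParams band_filter
#' @param cutoff cutoff frequency in Hz.
#' @export
highpass_filter <- function(x, cutoff = 1, fs = 100, order = 2) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  .apply_filtfilt(x, bf)
}

.apply_filtfilt <- function(x, bf) {
  if (is.matrix(x)) {
    cpp_filtfilt_rows(x, bf$b, bf$a)
  } else {
    drop(cpp_filtfilt_rows(matrix(x, 1), bf$b, bf$a))
  }
}

## Frobenius norm of the band-pass filtered version of X.
.band_frob <- function(x, band, fs) {
  sqrt(sum(band_filter(x, band, fs)^2))
}

#' Pink (1/f) noise
#'
#' Spectral-domain synthesis: the DFT of white Gaussian noise is shaped by a
#' 1/sqrt(f) amplitude profile (Hermitian symmetry is preserved because the
#' profile is real and even), then transformed back. The output is scaled to
#' unit standard deviation.
#'
#' @param n_samples series length (>= 256).
#' @param seed optional integer seed.
#' @return numeric vector with a 1/f power spectrum.
#' @export
pink_noise <- function(n_samples, seed = NULL) {
  if (n_samples < 256) stop("n_samples must be >= 256")
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  w <- rnorm(n_samples)
  X <- fft(w)
  k <- seq_len(n_samples) - 1
  fidx <- pmin(k, n_samples - k)     # symmetric frequency index
  amp <- c(0, 1 / sqrt(fidx[-1]))    # zero out DC
  x <- Re(fft(X * amp, inverse = TRUE)) / n_samples
  x / sd(x)
}

## Circular time shift by a (possibly fractional) number of samples,
## implemented as an exact frequency-domain phase ramp. For integer delays
## this is a circular shift; fractional delays interpolate spectrally.
delay_series <- function(x, delay_samples) {
  n <- length(x)
  if (delay_samples %% 1 == 0) {
    d <- as.integer(delay_samples) %% n
    if (d == 0) return(x)
    return(c(x[(n - d + 1):n], x[1:(n - d)]))
  }
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  ph <- exp(-2i * pi * k * delay_samples / n)
  Re(fft(fft(x) * ph, inverse = TRUE)) / n
}

#' Generate a unidirectionally interacting sender/receiver pair
#'
#' The sender is band-pass filtered white noise; the receiver is an exact
#' (circularly shifted) copy of the sender, delayed by `delay` samples.
#'
#' @param n_samples series length.
#' @param delay delay in samples (> 0; fractional delays are applied as
#'   exact spectral phase shifts).
#' @param band interaction band in Hz.
#' @param fs sampling rate in Hz.
#' @param seed optional integer seed.
#' @return list with `sender` and `receiver` numeric vectors.
#' @export
make_interacting_pair <- function(n_samples, delay, band = c(8, 12),
                                  fs = 100, seed = NULL) {
  if (delay <= 0) stop("parameter error: delay must be positive")
  if (delay >= n_samples) stop("parameter error: delay must be < n_samples")
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  g <- band_filter(rnorm(n_samples), band, fs)
  list(sender = g, receiver = delay_series(g, delay))
}

#' Mix a ground-truth series with pink background noise
#'
#' The ground-truth series is normalized by its own l2-norm; the noise by
#' the l2-norm of its band-pass filtered version. The source signal is the
#' weighted sum `theta * g_n + (1 - theta) * p_n`, which fixes the
#' source-level SNR at `20 log10(theta / (1 - theta))` dB inside the band.
#'
#' @param g ground-truth series.
#' @param p pink-noise series, same length.
#' @param theta mixing weight in (0, 1].
#' @param band interaction band in Hz.
#' @param fs sampling rate in Hz.
#' @return numeric vector, the source signal.
#' @export
assemble_source_signal <- function(g, p, theta, band = c(8, 12), fs = 100) {
  stopifnot(length(g) == length(p), theta > 0, theta <= 1)
  ng <- sqrt(sum(g^2))
  if (ng == 0) stop("degenerate signal: zero-norm ground truth")
  gn <- g / ng
  if (theta == 1) return(gn)
  np <- .band_frob(p, band, fs)
  if (np == 0) stop("degenerate signal: zero-norm noise")
  theta * gn + (1 - theta) * (p / np)
}

#' Simulation configuration
#'
#' Collects all parameters of the pseudo-EEG generator. Defaults reproduce
#' the benchmark's standard condition: 3 minutes at 100 Hz, 2-second epochs,
#' an 8-12 Hz interaction band, source-level SNR 3.5 dB (theta = 0.6),
#' brain-to-sensor-noise ratio 0 dB (theta_bsr = 0.5), sensor-level SNR
#' 3.5 dB (theta_snr = 0.6), two interacting region pairs with delays drawn
#' uniformly between 50 and 200 ms, and one active source per region.
#'
#' @param fs sampling rate (Hz).
#' @param duration_s recording length (s).
#' @param epoch_len epoch length in samples.
#' @param band interaction band (Hz).
#' @param theta source-level mixing weight.
#' @param theta_bsr brain-noise-to-sensor-noise mixing weight.
#' @param theta_snr sensor-level signal-to-noise mixing weight.
#' @param n_interactions number of interacting region pairs (NI).
#' @param delay_range_ms range the interaction delay is drawn from
#'   (uniformly), in ms. Ignored when `delay_ms` is given.
#' @param delay_ms optional fixed delay in ms (may map to a fractional
#'   number of samples; the delay is applied spectrally, so any positive
#'   value is valid).
#' @param n_active_per_region active sources per region (1 or 2).
#' @param correlated_pairs if TRUE (requires `n_interactions == 2`), the
#'   second source pair reuses the first pair's time courses and all four
#'   seed/target cross-pairs count as ground truth.
#' @param highpass_hz final sensor-data high-pass cutoff (Hz); NA disables.
#' @param seed master seed; expands into independent substreams for
#'   placement, signal, brain noise and sensor noise so that single
#'   components can be held fixed across conditions.
#' @return `fc_sim_config` list.
#' @export
sim_config <- function(fs = 100, duration_s = 180, epoch_len = 200,
                       band = c(8, 12), theta = 0.6, theta_bsr = 0.5,
                       theta_snr = 0.6, n_interactions = 2,
                       delay_range_ms = c(50, 200), delay_ms = NULL,
                       n_active_per_region = 1, correlated_pairs = FALSE,
                       highpass_hz = 1, seed = 1) {
  nt <- round(fs * duration_s)
  if (nt %% epoch_len != 0) stop("duration must be a whole number of epochs")
  stopifnot(theta > 0, theta < 1, theta_bsr > 0, theta_bsr < 1,
            theta_snr > 0, theta_snr <= 1, n_interactions >= 1,
            n_active_per_region %in% c(1L, 2L))
  if (!is.null(delay_ms) && delay_ms <= 0) {
    stop("parameter error: delay_ms must be positive")
  }
  structure(list(
    fs = fs, duration_s = duration_s, n_samples = nt,
    epoch_len = as.integer(epoch_len),
    n_epochs = as.integer(nt / epoch_len),
    band = band, theta = theta, theta_bsr = theta_bsr,
    theta_snr = theta_snr, n_interactions = as.integer(n_interactions),
    delay_range_ms = delay_range_ms, delay_ms = delay_ms,
    n_active_per_region = as.integer(n_active_per_region),
    correlated_pairs = isTRUE(correlated_pairs),
    highpass_hz = highpass_hz, seed = as.integer(seed)),
    class = "fc_sim_config")
}

## Derive named substream seeds from the master seed.
.substreams <- function(seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, 4)
  names(s) <- c("placement", "signal", "brain", "sensor")
  s
}

#' Simulate a sensor-space recording with ground-truth interactions
#'
#' Implements the full generative model: unidirectional band-limited
#' interactions placed at random voxels of randomly drawn region pairs,
#' independent pink brain noise in all remaining regions, projection through
#' the scalar leadfield, separate band-norm normalization of the interacting,
#' brain-noise and white sensor-noise components, mixing by `theta_bsr` and
#' `theta_snr` with renormalization after each stage, and a final 1 Hz
#' high-pass.
#'
#' @param config an `fc_sim_config`.
#' @param leadfield an `fc_leadfield`.
#' @return `fc_recording` with fields `continuous` (Ns x Nt, after
#'   high-pass), `ground_truth`, `config`, and (when
#'   `keep_components = TRUE`) the normalized pre-high-pass signal and noise
#'   components.
#' @param keep_components keep the normalized mixed components (for
#'   diagnostics).
#' @export
simulate_recording <- function(config, leadfield, keep_components = FALSE) {
  .simulate_core(config, leadfield, keep_components)
}

#' Simulate two perfectly correlated interacting source pairs
#'
#' The second source pair reuses the first pair's sender and receiver time
#' courses; all four seed/target cross-pairs are marked as ground-truth
#' interactions.
#'
#' @inheritParams simulate_recording
#' @export
simulate_correlated_pairs <- function(config, leadfield,
                                      keep_components = FALSE) {
  if (config$n_interactions != 2) {
    stop("parameter error: correlated pairs require n_interactions == 2")
  }
  config$correlated_pairs <- TRUE
  .simulate_core(config, leadfield, keep_components)
}

#' Simulate two interacting source pairs within one region pair
#'
#' Each chosen region hosts two active voxels; two independent bivariate
#' interactions run between the same (seed, target) region pair. All
#' non-interacting regions receive two brain-noise sources so that every
#' region carries the same number of time series.
#'
#' @inheritParams simulate_recording
#' @export
simulate_two_sources_per_region <- function(config, leadfield,
                                            keep_components = FALSE) {
  config$n_active_per_region <- 2L
  .simulate_core(config, leadfield, keep_components)
}

.simulate_core <- function(config, leadfield, keep_components = FALSE) {
  stopifnot(inherits(config, "fc_sim_config"),
            inherits(leadfield, "fc_leadfield"))
  space <- leadfield$space
  nt <- config$n_samples; fs <- config$fs; band <- config$band
  ni <- config$n_interactions
  napr <- config$n_active_per_region
  two_per_region <- napr == 2L
  n_pair_regions <- if (two_per_region) 1L else ni
  if (space$n_regions < 2 * n_pair_regions) {
    stop("dimension error: leadfield has too few regions for n_interactions")
  }
  seeds <- .substreams(config$seed)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)

  ## --- placement -----------------------------------------------------
  set.seed(seeds[["placement"]])
  regs <- sample(space$n_regions, 2 * n_pair_regions)
  seed_regions <- regs[seq_len(n_pair_regions)]
  target_regions <- regs[n_pair_regions + seq_len(n_pair_regions)]
  pick_voxels <- function(region, k) {
    vox <- which(space$region_label == region)
    if (length(vox) < k) stop("parcellation error: region too small")
    if (length(vox) == 1) vox else sample(vox, k)
  }
  if (two_per_region) {
    seed_vox <- pick_voxels(seed_regions, 2)
    target_vox <- pick_voxels(target_regions, 2)
    pairs <- data.frame(seed_region = rep(seed_regions, 2),
                        target_region = rep(target_regions, 2),
                        seed_voxel = seed_vox, target_voxel = target_vox)
    n_inter <- 2L
  } else {
    seed_vox <- vapply(seed_regions, pick_voxels, 0L, k = 1)
    target_vox <- vapply(target_regions, pick_voxels, 0L, k = 1)
    pairs <- data.frame(seed_region = seed_regions,
                        target_region = target_regions,
                        seed_voxel = seed_vox, target_voxel = target_vox)
    n_inter <- ni
  }
  noise_regions <- setdiff(seq_len(space$n_regions), regs)
  noise_vox <- unlist(lapply(noise_regions, pick_voxels, k = napr))

  ## --- interacting signals -------------------------------------------
  set.seed(seeds[["signal"]])
  if (is.null(config$delay_ms)) {
    delay_ms <- runif(n_inter, config$delay_range_ms[1],
                      config$delay_range_ms[2])
  } else {
    delay_ms <- rep(config$delay_ms, n_inter)
  }
  delay_smp <- delay_ms / 1000 * fs
  pairs$delay_ms <- delay_ms
  pairs$delay_samples <- delay_smp

  senders <- vector("list", n_inter); receivers <- vector("list", n_inter)
  for (i in seq_len(n_inter)) {
    if (config$correlated_pairs && i > 1) {
      senders[[i]] <- senders[[1]]; receivers[[i]] <- receivers[[1]]
      pairs$delay_ms[i] <- pairs$delay_ms[1]
      pairs$delay_samples[i] <- pairs$delay_samples[1]
      next
    }
    g <- band_filter(rnorm(nt), band, fs)
    gr <- delay_series(g, delay_smp[i])
    senders[[i]] <- assemble_source_signal(g, pink_noise(nt), config$theta,
                                           band, fs)
    receivers[[i]] <- assemble_source_signal(gr, pink_noise(nt),
                                             config$theta, band, fs)
  }
  JI <- do.call(rbind, c(senders, receivers))
  vox_I <- c(pairs$seed_voxel, pairs$target_voxel)

  ## --- brain noise ----------------------------------------------------
  set.seed(seeds[["brain"]])
  Jb <- t(vapply(seq_along(noise_vox), function(i) {
    p <- pink_noise(nt)
    p / .band_frob(p, band, fs)
  }, numeric(nt)))

  ## --- projection and sensor-level mixing -----------------------------
  Ls <- leadfield$gain_scalar
  QI <- Ls[, vox_I, drop = FALSE] %*% JI
  Qb <- Ls[, noise_vox, drop = FALSE] %*% Jb
  set.seed(seeds[["sensor"]])
  Qs <- matrix(rnorm(nrow(Ls) * nt), nrow(Ls), nt)

  QIn <- QI / .band_frob(QI, band, fs)
  Qbn <- Qb / .band_frob(Qb, band, fs)
  Qsn <- Qs / .band_frob(Qs, band, fs)
  Qn <- config$theta_bsr * Qbn + (1 - config$theta_bsr) * Qsn
  Qnn <- Qn / .band_frob(Qn, band, fs)
  Q <- config$theta_snr * QIn + (1 - config$theta_snr) * Qnn
  Q <- Q / .band_frob(Q, band, fs)

  continuous <- if (is.na(config$highpass_hz) || is.null(config$highpass_hz)) {
    Q
  } else {
    highpass_filter(Q, config$highpass_hz, fs)
  }

  active <- data.frame(
    region = c(pairs$seed_region, pairs$target_region,
               rep(noise_regions, each = napr)),
    voxel = c(pairs$seed_voxel, pairs$target_voxel, noise_vox))
  truth <- .ground_truth_pairs(pairs, config, space$n_regions)
  truth$active <- active
  rec <- structure(list(
    continuous = continuous, config = config,
    ground_truth = truth, n_sensors = nrow(Ls)), class = "fc_recording")
  if (keep_components) {
    rec$signal_component <- config$theta_snr * QIn
    rec$noise_component <- (1 - config$theta_snr) * Qnn
    rec$source_signals <- JI   # senders first, then receivers
  }
  rec
}

.ground_truth_pairs <- function(pairs, config, n_regions) {
  if (config$correlated_pairs) {
    truth <- expand.grid(seed_region = pairs$seed_region,
                         target_region = pairs$target_region)
    truth <- unique(truth)
  } else {
    truth <- unique(pairs[, c("seed_region", "target_region")])
  }
  list(pairs = pairs, truth_regions = truth,
       correlated_pairs = config$correlated_pairs,
       n_regions = n_regions)
}

#' Cut a recording (or any channels x time matrix) into epochs
#'
#' @param x `fc_recording` or numeric matrix (channels x time).
#' @param epoch_len epoch length in samples (taken from the recording's
#'   config when available).
#' @return array of dimension `n_epochs x epoch_len x n_channels`.
#' @export
epoch_data <- function(x, epoch_len = NULL) {
  if (inherits(x, "fc_recording")) {
    epoch_len <- x$config$epoch_len
    x <- x$continuous
  }
  stopifnot(is.matrix(x), !is.null(epoch_len))
  nt <- ncol(x); ne <- nt %/% epoch_len
  arr <- array(0, c(ne, epoch_len, nrow(x)))
  for (e in seq_len(ne)) {
    idx <- ((e - 1) * epoch_len + 1):(e * epoch_len)
    arr[e, , ] <- t(x[, idx, drop = FALSE])
  }
  arr
}

#' @export
print.fc_recording <- function(x, ...) {
  cat("<fc_recording> ", nrow(x$continuous), " sensors x ",
      ncol(x$continuous), " samples; ",
      nrow(x$ground_truth$pairs), " ground-truth interaction(s)\n", sep = "")
  invisible(x)
}
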