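---
title: "Benchmarking EEG source-connectivity pipelines with ground-truth simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking EEG source-connectivity pipelines with ground-truth simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcpipe)
```

## The problem

Estimating which cortical regions interact from scalp EEG requires a chain
of processing choices: an inverse solution to undo volume conduction, a rule
for collapsing the many reconstructed dipoles of an anatomical region into a
few time courses, and a functional-connectivity (FC) statistic. Each choice
can create or destroy sensitivity, and — because volume conduction mixes
every source into every sensor instantaneously — the wrong choice produces
spurious zero-lag connectivity that looks exactly like a finding.

`fcpipe` provides a closed experimental loop for evaluating such pipelines:
a generative model in which the true inter-regional interactions are known
exactly, the standard inverse/aggregation/FC building blocks, and a
rank-based score that measures how highly the true region pairs rank among
all candidate pairs. Because the ground truth is known, any pipeline can be
scored objectively, and competing pipelines can be compared on identical
data.

## The forward model

The package replaces anatomical head modelling with an analytic three-shell
spherical volume conductor (brain, skull, scalp; radii 0.087 / 0.092 /
0.100 m; conductivities 0.33 / 0.0042 / 0.33 S/m). Potentials of dipolar
sources are computed from the truncated Legendre-series solution of the
concentric-spheres boundary-value problem (60 terms; the equal-conductivity
limit is verified against the closed-form single-sphere solution in the test
suite). This keeps the package self-contained — no template MRI, BEM solver
or vendor electrode files — while preserving the physics that matters for
connectivity benchmarking: realistic field spread, depth-dependent gain
attenuation, and a strongly rank-limited skull-blurred mixing matrix.

Sources sit quasi-uniformly (Fibonacci lattice) on a cortical shell at 80%
of the brain radius with radial orientations; a seeded k-means clustering of
the source positions defines spatially contiguous regions (68 by default),
relabelled by centroid angle for determinism, with a repair step that
guarantees at least two sources per region. Sensors (97 by default) follow a
Fibonacci spiral over the upper scalp. All leadfield columns are re-referenced
to the common average. The physical scale of the leadfield is arbitrary
(all simulated signals are norm-controlled, below), so columns are rescaled
to unit mean norm; sensor data are likewise standardized before inverse
fitting so that regularization grids expressed as fractions of the data
covariance trace are on a consistent scale. Every FC metric used downstream
is invariant to these rescalings.

## The generative model

Ground-truth activity is band-limited (8–12 Hz, zero-phase second-order
Butterworth) white noise; each interaction is strictly unidirectional: the
receiving source is an exact copy of the sender, delayed by 50–200 ms
(drawn uniformly per interaction). The delay is applied as an exact
spectral phase shift (circular), which preserves the copy property and the
signal norm, and also supports sub-sample delays — the short-delay
experiment uses 2 ms = 0.2 samples at the 100 Hz sampling rate, which
cannot be represented by an integer shift.

At the source level, every interacting series is mixed with an independent
pink-noise background: `s = theta * g_n + (1 - theta) * p_n`, where `g_n`
is the ground-truth series normalized by its own l2-norm and `p_n` the pink
noise normalized by the l2-norm of its band-filtered version. The weight
`theta` fixes the source-level SNR at `20 log10(theta / (1 - theta))` dB;
the default `theta = 0.6` gives 3.5 dB. Non-interacting regions carry pure
pink noise. Pink noise is synthesized by 1/sqrt(f) amplitude shaping of the
DFT of white Gaussian noise.

Signal sources, brain-noise sources and white sensor noise are projected or
added at the sensor level and combined in two normalized stages: brain and
sensor noise are mixed with weight `theta_bsr` (default 0.5, i.e. a 0 dB
brain-to-sensor-noise ratio) and renormalized, then signal and total noise
are mixed with weight `theta_snr` (default 0.6, 3.5 dB) and renormalized.
All normalizations use the Frobenius norm of the 8–12 Hz-filtered data, so
the stated ratios hold exactly in the interaction band. A final 1 Hz
high-pass emulates standard acquisition filtering. The default recording is
3 minutes at 100 Hz, analysed in 90 epochs of 2 s.

One master seed expands into four named substreams (placement, signal,
brain noise, sensor noise). Experiments that vary a parameter therefore
reuse identical realizations of everything else within an iteration, which
removes between-condition Monte-Carlo variance from the comparisons.

Two special modes cover harder scenarios: `simulate_correlated_pairs`
duplicates the first pair's time courses into the second pair (all four
seed/target cross-pairs then count as ground truth), and
`simulate_two_sources_per_region` places two independent interactions
between two voxel pairs of the *same* region pair (all regions then carry
two active sources).

What the generator does *not* emulate: anatomical source geometry and
orientation variability, ocular/muscle artifacts, non-stationarity,
cross-frequency coupling, and inter-subject variability. Passing benchmarks
here demonstrates correct methodology under the stated generative model,
not performance on any particular clinical recording.

## Inverse solutions

Four inverse solutions are implemented against the same leadfield used for
simulation, reconstructing full 3D dipole moments (no orientation prior):

* **LCMV** — per-voxel minimum-variance beamformer with the unit-gain
  constraint `P_v' L_v = I`. The broadband sensor covariance is inverted
  directly, with diagonal loading of `1e-8 * trace` only if its condition
  number exceeds `1e10`.
* **eLORETA** — weighted minimum-norm filter whose block-diagonal weights
  `W_v = [L_v' M L_v]^(1/2)`, `M = (L W^-1 L' + a K)^+`, are iterated to a
  fixed point (initialization `W_v = I`, stop at relative Frobenius change
  `< 1e-6` or 200 iterations). `K` is the common-average centering matrix.
* **DICS** — the per-frequency beamformer analogue, built from the real
  part of the sensor cross-spectral density at each frequency. With 90
  epochs and 97 sensors every per-frequency CSD is rank-deficient, so a 5%
  diagonal loading (the conventional beamformer default) is always applied.
* **Champagne** — sparse Bayesian learning with a full 3x3 positive-definite
  prior covariance per voxel and homoscedastic sensor noise. Hyperparameters
  minimize the Type-II negative log evidence via convex-bounding fixed-point
  updates (`Gamma_v <- Z^-1/2 (Z^1/2 M Z^1/2)^1/2 Z^-1/2`); the objective is
  non-increasing and most voxel priors collapse to zero, giving sparse
  reconstructions.

The regularization parameter of eLORETA and the noise variance of Champagne
are selected by five-fold *spatial* cross-validation: sensors are split
into folds, the filter is fitted from the training sensors' leadfield rows,
and the held-out sensors are predicted through their leadfield rows from
the training-sensor reconstruction. The error metric is the normalized
held-out squared error (computable from the sensor covariance alone, which
makes the procedure cheap); the candidate grid is 15 (or, in the
scaled-down runs, 5) log-spaced values between `0.01 * Tr(Cov)` and
`Tr(Cov)`. A point worth documenting: on noiseless toy data the held-out
error is *not* monotone in the regularizer — the weighted-minimum-norm
estimator is biased, so a small interior regularization can predict held-out
sensors best. The cross-validation is therefore tested against a
brute-force reimplementation rather than against an assumed monotonicity.

## Region aggregation

After inversion, each region's `3 R_r`-dimensional source matrix (three
orientations of every voxel jointly, mean-centered) is reduced by SVD/PCA;
the principal-component time courses are the columns of `U D`, and
explained-variance fractions are squared singular values normalized by
their sum. Schemes: a fixed number of strongest PCs (`fixpc1`–`fixpc6`),
enough PCs for at least 90% or 99% of the region variance (inclusive
threshold; `varpc90`/`varpc99`), orientation-wise voxel means (`meanfc`),
the most central voxel (`central`), all voxels retained with FC computed
per voxel pair and averaged (`fcmean`, MIM/MIC only), and the ground-truth
voxel (`truevox`, baseline). Component signs are fixed by making the
largest-magnitude loading positive; all downstream metrics are
sign-invariant, this only stabilizes snapshots. For DICS, PCA operates on
the real part of the source-level cross-spectrum summed across all
frequencies, and the resulting projection is applied to every frequency's
block.

## Connectivity metrics

All metrics derive from the joint cross-spectrum of two component sets
(Hanning-windowed epoch DFTs, epoch-averaged outer products; 0–50 Hz in
0.5 Hz steps for the default epoch length). From complex coherency
`C = S_xy / sqrt(S_xx S_yy)`:

* **COH** — mean absolute coherency over component pairs (not robust to
  mixing);
* **iCOH** — mean absolute imaginary part (robust);
* **MIM** — `Tr[(C_xx^R)^-1 C_xy^I (C_yy^R)^-1 (C_xy^I)']`, the trace-form
  multivariate generalization (robust);
* **MIC** — the maximal imaginary coherency over one-dimensional
  projections of the two sets, computed in closed form as the largest
  singular value of the imaginary part of the whitened off-diagonal block,
  where whitening uses symmetric inverse square roots of the real
  within-set blocks (robust).

Real-part blocks are ridge-stabilized (`1e-10 * trace`) when their
condition number exceeds `1e10`.

Directed interactions use frequency-resolved multivariate Granger
causality: the cross-spectrum is inverse-DFT'd into an autocovariance
sequence (lags 0–20), a VAR(20) model is fitted by Whittle's multichannel
Levinson recursion, and Geweke-style conditional log-determinant ratios are
evaluated from the model's spectral factorization `S = H Sigma H*`. For a
VAR model the innovations-form state-space transfer function equals the
inverse of the VAR polynomial `A(z) = I - sum_p A_p z^p`, so `H` is
computed by polynomial inversion; the two routes are algebraically
identical, and the fitted factorization is verified against the input
spectrum in the tests. **TRGC** repeats the fit on the transposed
(time-reversed) autocovariance sequence and subtracts the reversed net
score, cancelling contributions that survive time reversal — i.e.
instantaneous mixing artifacts. TRGC is antisymmetric by construction.

For GC/TRGC two evaluation tasks are distinguished: *detection* ranks
absolute band-averaged net scores; *direction* ranks the positively signed
scores, and a ground-truth pair whose score has the wrong sign is treated
as absent from the candidate list and assigned the worst rank — this
package's documented completion of the "rank only the positive scores"
convention, chosen so that PR stays within [0, 1] even when every truth is
misdirected.

## Scoring and statistics

The percentile rank (PR) of a pipeline sorts all region-pair scores in
descending order, averages `1 - r_i/F` over the ground-truth ranks, and
normalizes between the perfect-skill and no-skill configurations, giving 1
when the truth occupies the top ranks, 0 at the bottom, and 0.5 on average
for random scores (any number of interactions). Ties receive mean ranks.
Candidates are the `R(R-1)/2` unordered off-diagonal region pairs.

Surrogate significance testing shuffles the epoch pairing between two
regions when forming the off-diagonal cross-spectral blocks (diagonal
powers stay unshuffled), recomputing band-averaged MIM per permutation.
The p-value uses the `(k+1)/(n+1)` convention — a deliberate deviation
from plain count ratios so that p stays positive for FDR correction, which
is Benjamini–Hochberg on the upper triangle at alpha 0.05. Pipelines are
compared with one-sided paired Wilcoxon signed-rank tests.

## Problem sizes and numerical choices

The package's benchmark presets mirror the six default conditions (LCMV,
FIXPC3, SNR 3.5 dB, BSR 0 dB, two interactions, 50–200 ms delays, one
source per region) and vary one factor each: FC metric (1A), aggregation
scheme (1B), surrogate statistics (1C), inverse solution (2A/2B),
correlated pairs (2C), SNR (3A), BSR (3B), number of interactions (4),
short delays (5) and two sources per region (6).

The reference configuration used by the package's own reproduction runs is
a 500-source / 68-region / 97-sensor spherical model with 30 Monte-Carlo
iterations per experiment — a size chosen so that a complete experiment
runs in minutes on a single core while leaving the per-iteration problem
(number of regions, sensors, epochs, frequency grid) identical to the
full-size setting. Published effect sizes at the full 1895-source BEM
setting transfer only approximately to this configuration; comparisons
should therefore emphasize the *ordering* of pipelines, which is stable,
over absolute PR values.

Other numerical choices: Legendre series truncated at 60 terms; k-means
with 5 restarts and a fixed seed; zero-phase filtering pads edges by odd
reflection; eLORETA warm-starts its weights across the CV candidate grid;
GC evaluates its spectral scores only at the band bins that are averaged;
degenerate inputs (zero-power components, singular real-part blocks,
unstable VAR fits) raise errors rather than returning silently.

## Storage and interfaces

Objects (head models, recordings, filters, result tables) are plain R
lists with S3 classes, serialized as RDS; experiment rows and summaries are
also written as tidy CSV by the `fcpipe` command-line tool (`exec/fcpipe`),
which wraps `build_head_model`, `simulate_recording` and `run_experiment`.

## Known limitations

* The spherical conductor has no anatomical asymmetry; inverse solutions
  that exploit anatomical priors are not representable.
* Radial-only source orientations interact with the spherical symmetry
  (tangential components of the reconstructed moments carry little
  signal); full 3D moments are nevertheless estimated everywhere.
* The delayed-copy interaction model makes sender and receiver spectra
  identical; metrics that exploit spectral asymmetries are not stressed.
* Surrogate tests inherit the spatial leakage of the inverse step: voxels
  near a true interaction can test significant (false positives by
  proximity), which is a property of the method under test, not of the
  testing machinery.
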