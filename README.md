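# fcpipe

Simulation and benchmarking of EEG source-connectivity pipelines.

## What problem this solves

Inferring *which cortical regions interact* from scalp EEG requires three
chained choices: an **inverse solution** (eLORETA, LCMV, DICS, Champagne), a
rule for **aggregating** the many reconstructed dipoles of a region into a
few time courses (PCA variants, voxel means, central voxel), and a
**functional-connectivity metric** (coherence, imaginary coherency, MIM,
MIC, spectral Granger causality, time-reversed GC). Volume conduction mixes
every source into every sensor instantaneously, so poor choices produce
spurious zero-lag "connectivity" that is indistinguishable from a finding.

`fcpipe` closes the loop: it simulates pseudo-EEG whose inter-regional
interactions are known exactly, runs any combination of the pipeline stages
above, and scores the result against the ground truth. It is aimed at
methods researchers and at practitioners who want to know, before analysing
real data, whether their pipeline can recover interactions under controlled
signal-to-noise conditions.

## The model in brief

Ground-truth activity is alpha-band (8–12 Hz) filtered white noise; each
interaction is unidirectional — the receiver is an exact copy of the sender
delayed by 50–200 ms. Sources are mixed with pink background noise at a
source-level SNR of `20·log10(θ/(1−θ))` dB (default θ = 0.6, i.e. 3.5 dB),
projected through an analytic three-shell spherical leadfield
(brain/skull/scalp), and combined with brain noise and white sensor noise
at controlled band-limited ratios (BSR 0 dB, sensor SNR 3.5 dB by default).

Pipelines are scored with the normalized **percentile rank** (PR): sort all
region-pair scores descending, take the ground-truth ranks `r_i` among the
`F` candidate pairs,

    PR′ = mean_i (1 − r_i/F),   PR = (PR′ − PR_ns) / (PR_ps − PR_ns),

normalized between the perfect-skill and no-skill configurations, so PR = 1
means the true pairs rank on top, PR = 0.5 is chance, PR = 0 is the bottom.
Directed metrics are additionally scored on their ability to get the
*direction* right (PR over positively signed scores).

## Worked example

```r
library(fcpipe)

## 1. Synthetic head model: 200 sources, 30 regions, 64 sensors
model <- build_head_model(n_sources = 200, n_regions = 30, seed = 42,
                          n_sensors = 64)
#> <fc_leadfield> 64 sensors x 200 sources (30 regions), common-average referenced

## 2. Simulate a recording with two ground-truth interactions
cfg <- sim_config(duration_s = 120, n_interactions = 2, seed = 7)
rec <- simulate_recording(cfg, model)
rec$ground_truth$truth_regions
#>   seed_region target_region
#> 1           5            18
#> 2          19            25

## 3. Sensor -> source -> regions -> connectivity
scores <- run_pipeline(rec, model, inverse = "lcmv", scheme = "fixpc3",
                       metrics = c("coh", "mim", "trgc"))

## 4. Score against the ground truth
truth <- rec$ground_truth$truth_regions
pr_matrix(scores$coh$band_matrix, truth)
#> <fc_pr> PR=0.6120 (raw 0.6103; NI=2 of F=435; ranks 314, 25)
pr_matrix(scores$mim$band_matrix, truth)
#> <fc_pr> PR=0.9573 (raw 0.9540; NI=2 of F=435; ranks 1, 39)
pr_matrix(scores$trgc$band_matrix, truth, directed = TRUE, task = "direction")
#> <fc_pr> PR=0.7529 (raw 0.7506; NI=2 of F=435; ranks 1, 216)
```

Reading the output: with plain coherence one true pair ranks 314th of 435
candidate pairs (volume conduction drowns it); with MIM — a multivariate
metric robust to instantaneous mixing — the true pairs rank 1st and 39th
(PR 0.96). Time-reversed GC additionally recovers the direction of the
first interaction (rank 1 among positively signed scores).

Complete benchmark experiments wrap this loop:

```r
spec <- experiment_spec("1A", n_iterations = 5, seed = 1,
                        levels = c("coh", "mim"),
                        sim_overrides = list(duration_s = 120))
run_experiment(spec, model)
#> <fc_result_table> experiment 1A, 5 iteration(s)
#>  condition metric      task n mean median p2.5 p97.5
#>    default    coh detection 5 0.64   0.68 0.33  0.87
#>    default    mim detection 5 0.84   0.91 0.58  0.99
```

Presets `1A`–`6` vary the FC metric, aggregation scheme, inverse solution,
SNR, brain/sensor-noise ratio, number of interactions, interaction delay,
and the number of active sources per region. A thin command-line wrapper is
installed as `exec/fcpipe` (`fcpipe forward|simulate|experiment ...`).

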