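# ecgStream

Online ECG biometrics for streaming heartbeat data.

ECG traces are a usable biometric: heartbeat morphology is stable within a
person and distinctive between people. In practice enrolment data arrive as
a *stream* — chunks of labeled heartbeats collected over time, with new
individuals appearing along the way — and retraining a batch model after
every chunk is wasteful. `ecgStream` implements an online learner that
absorbs each chunk once, never re-reads past raw data, and resists
catastrophic forgetting, together with the full pipeline around it:
Pan–Tompkins R-peak detection, heartbeat segmentation, 1-D multi-resolution
local-binary-pattern (1DMRLBP) features, synthetic data generators, and
identification / verification metrics.

## The model

At round *t*, features `X_t` (d × n_t) arrive with individual labels. The
learner maintains a projection `W` (d × r) and reconstruction `G` (d × r)
and fits latent representations `V_t` (n_t × r) by minimising

    α Σ_s ||V_s − X_sᵀW||² + β Σ_s ||X_s − G V_sᵀ||²        bidirectional regressions
    + γ ||A_t − H_t R_tᵀ||² + θ ||R_t − V_t||²              Hadamard-code prototype learning
    + η ||S_t − V_m V_tᵀ||²                                  memory enhancement
    + δ (||W||² + ||G||²)

where `A_t` marks same-individual pairs, `H_t` stacks fixed orthogonal ±1
Hadamard code rows per individual, `R_t` are learned prototypes, and `V_m`
holds one running-mean representation per enrolled individual. Each chunk
is absorbed by T = 6 alternating closed-form updates of `W`, `G`, `R_t`,
`V_t` — each the exact minimiser of its sub-problem, so the objective is
monotonically non-increasing. Past data enter only through the cumulative
statistics `C1 = Σ X Xᵀ`, `C2 = Σ X V`, `C3 = Σ VᵀV`, making storage
independent of stream length. Matching projects queries and registered
samples as `XᵀW` and assigns the nearest-neighbour label; verification
reports the equal error rate of the distance threshold sweep.

See `vignettes/online-ecg-biometrics.Rmd` for the derivations, the
numerical conventions, and the synthetic-data design.

## Worked example

```r
library(ecgStream)

## raw signal -> beats -> features
sim   <- simulateEcgRecord(fs = 360, nBeats = 120, noiseSd = 0.05, seed = 42)
peaks <- detectRPeaks(sim$record)           # 120 of 120 planted beats found
beats <- segmentHeartbeats(sim$record, peaks, windowLength = 260)
beats
#> HeartbeatMatrix: 120 beats x 260 samples (fs 360 Hz), 0 dropped at boundaries
extractLbpFeatures(beats, LbpConfig())
#> FeatureChunk round 1: d = 304 features x n = 120 samples, 1 individuals

## a labeled streaming protocol: 20 individuals, chunks of 70/70/70/70/49,
## 5 held-out query samples per individual
st  <- simulateFeatureStream(seed = 1)
fit <- trainStream(st$chunks, OnlineHyper(seed = 1), test = st$test)
fit$model
#> OnlineModel: d = 64 -> r = 128, 5 round(s) absorbed, 20 individuals enrolled
#>   modules: bidirectional-regressions + prototype-learning + memory-enhancement
fit$perRound
#>   round accuracy      eer
#> 1     1       99 7.471429
#> 2     2      100 4.207143
#> 3     3      100 3.393484
#> 4     4      100 2.714286
#> 5     5      100 2.310030
```

The per-round table shows the streaming behaviour: after round 1 the model
already identifies 99% of the held-out queries; as further chunks arrive
the accuracy holds at 100% and the verification EER drops from 7.5% to
2.3%, because the statistics, prototypes and memory keep sharpening the
latent space without ever revisiting earlier chunks.

A thin command-line wrapper (`inst/scripts/ecgstream`) exposes
`simulate | preprocess | train | evaluate | ablate` over the same
functions, e.g.

```sh
Rscript inst/scripts/ecgstream simulate --out stream/ --seed 3
Rscript inst/scripts/ecgstream train --stream stream/ --out ckpt/ --seed 3
Rscript inst/scripts/ecgstream evaluate --checkpoint ckpt/round_05 --stream stream/ --out metrics.json
```

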