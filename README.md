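# DaphniaTrack

Automatic high-throughput video tracking and ecotoxicological analysis of
*Daphnia magna* locomotion.

*Daphnia magna* is a standard bioindicator in acute aquatic toxicity
testing: its swimming activity degrades measurably under toxicant
exposure, and the immobility of exposed animals is the endpoint behind
the median effective concentration (EC50) reported by regulatory tests.
Scoring that endpoint by eye is slow; this package implements the full
computational side of an automated flow-cell tracking instrument, for
ecotoxicologists and bioimage analysts who want a transparent, scriptable
alternative to commercial trackers.

## What it does

The pipeline chains five stages, each exposed as ordinary R functions:

1. **Detection** — the background is the rolling per-pixel mean of the
   previous 20 s of frames; a frame's absolute difference from it is
   binarized at an automatic threshold chosen by 2-means clustering of
   the pixel values (the threshold is the midpoint `(mu1 + mu2)/2` of the
   two cluster means), and 8-connected components become candidate
   objects.
2. **Classification** — each candidate's bounding box is resized to
   8×8, converted to 64 Sobel gradient magnitudes, and labelled
   *daphnia*/noise by a random forest or SVM; noise (droplets, sediment)
   is discarded.
3. **Tracking** — SORT-style: each live track carries a Kalman state
   `x = [u, v, s, r, u̇, v̇, ṡ]` (centroid, box area, aspect ratio and
   rates) under a constant-velocity model; detections are assigned to
   predictions by the Hungarian algorithm on the mixed similarity

   `C_ij = (1 − λ) · max(0, (max_d − d_ij)/max_d) + λ · IOU_ij`

   combining normalised centroid distance and bounding-box IOU.
4. **Evaluation** — CLEAR MOT metrics (MOTA, MOTP, ID switches) and
   identity metrics (IDP, IDR, IDF1) against MOT-Challenge-format ground
   truth.
5. **Endpoints** — per-frame displacements, per-20-s average distances,
   the ≥ 20 s stationary (immobility) filter, mobile counts, radius of
   activity, and a two-parameter log-logistic EC50 fit
   `P(immobile | c) = 1/(1 + (EC50/c)^slope)` with binomial likelihood.

A seeded synthetic-scene generator (`generateVideo()`,
`generatePatchDB()`) renders dark elliptical swimmers with droplet and
sediment noise plus ground truth, so the whole chain is testable without
laboratory data.

## Worked example

```r
library(DaphniaTrack)

params <- sceneParams(seed = 7)          # 450 frames at 15 fps, 5 animals
scene  <- generateVideo(params)
scene
#> SyntheticScene: 450 frames (320x240 px), 2250 ground-truth records

db    <- generatePatchDB(params, nPerClass = 200)
model <- trainClassifier(db, method = "rf", seed = 7)
model
#> PatchClassifier: RF (magnitude features, seed 7)

res <- runPipeline(pipelineConfig(seed = 7), frames = scene,
                   classifier = model)

gt <- groundTruth(scene)
ev <- evaluateTracking(gt[gt$frame >= res$warmupFrames, ], res$trajectories)
round(ev[, c("IDF1", "IDP", "IDR", "IDs", "MOTA", "MOTP")], 2)
#>    IDF1 IDP  IDR IDs MOTA  MOTP
#> 1 98.37 100 96.8   0 96.8 99.95

summ <- res$summary
sprintf("mean displacement %.2f px/frame (SE %.3f), %d of %d mobile",
        summ$mean, summ$se, summ$mobile, summ$n)
#> [1] "mean displacement 1.28 px/frame (SE 0.077), 5 of 5 mobile"
```

The evaluation row reads: every emitted identity was correct (IDP 100),
96.8% of ground-truth boxes were recovered (IDR, MOTA), no identity was
ever swapped (IDs 0), and matched boxes overlapped the truth almost
perfectly (MOTP 99.95). The ~3% misses are the background warm-up
margin and track-confirmation delay. The displacement summary is the
video-level behavioural endpoint that downstream dose-response analysis
consumes.

A dose-response table yields the EC50:

```r
rec <- data.frame(concentration = c(0.375, 0.75, 1.5, 3, 6, 12),
                  n_total = 20,
                  n_immobile = c(0, 2, 9, 17, 20, 20))
fitEC50(rec)
#> Ec50Fit (logit link): EC50 = 1.606, slope = 3.21
#>   log-likelihood -5.048, converged: TRUE
```

A command-line front end with `simulate` / `train` / `track` /
`evaluate` / `behavior` / `ec50` subcommands is installed at
`inst/scripts/daphtrack.R`.

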