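---
title: "Methods: automated Daphnia magna tracking and toxicity endpoints"
author: "DaphniaTrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated Daphnia magna tracking and toxicity endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DaphniaTrack)
```

# Scope and model

DaphniaTrack implements the software half of an automated flow-cell
instrument for acute aquatic toxicity testing with *Daphnia magna*:
detection of swimming animals in backlit grayscale video, online
multi-object tracking, tracking-quality evaluation, and the behavioural
and dose-response endpoints built on the trajectories. This vignette
records the modelling assumptions, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does
and does not demonstrate.

# Detection

## Background model

The background estimate is the per-pixel arithmetic mean of the most
recent `fps * 20` frames (a rolling 20 s window). The first full window
is a warm-up period that yields no detections; all downstream statistics
start at warm-up completion. Two choices here were genuinely open:

* **Rolling vs. frozen.** A mean "over the previous 20 s" is a moving
  window, so the default keeps updating after warm-up; this adapts to
  slow illumination drift and to objects that settle (sediment is
  absorbed into the background within one window). A
  `freezeBackground` switch retains the first-window background instead,
  for recordings where animals rest so long that a rolling mean would
  absorb them.
* **Signed vs. absolute difference.** The difference image is the
  per-pixel *absolute* difference, so both darker and lighter objects
  are detectable. Under backlit (red/IR) illumination the animals are
  dark on a light field, but the absolute difference costs nothing and
  drops the polarity assumption.

The rolling mean is maintained as a running sum with eviction, and the
unit tests verify it equals a brute-force mean over the retained frames
at every step. An intrinsic artefact worth knowing: a pixel the animal
occupied during the window retains a "ghost" residue of magnitude
roughly `contrast * dwell / window` in the mean image. At the default
20 s window and ordinary swimming speeds the ghost is a few intensity
units and falls well below the automatic threshold; very short windows
(a few seconds) push ghosts toward the threshold and degrade detection —
that is a property of mean-background subtraction, not a tuning issue.

## Automatic threshold

The binarization threshold is chosen by 2-means (Lloyd) clustering of
the difference-image pixel values: pixels are alternately assigned to
the nearer of two means and the means recomputed, until assignments
stabilise, the means move less than `tol = 1e-6`, or 100 iterations; the
threshold is the midpoint `(mu1 + mu2) / 2`. Initialisation is at the
minimum and maximum pixel value — deterministic, and for the bimodal
histograms this stage sees it converges to the exhaustive-scan optimal
two-cluster split (property-tested against that oracle); a seeded random
initialisation is available for comparison. If all pixels are equal the
result is flagged degenerate and the foreground is empty, which is the
correct behaviour for an object-free video.

## Connected components

Foreground pixels are grouped with 8-connectivity (diagonal contact
joins) by a union-find pass, and components smaller than `min_area = 4`
pixels are discarded as single-pixel sensor noise. Neither the
connectivity nor a minimum size is forced by the method; 8-connectivity
was chosen because thin diagonal antenna/tail sections otherwise split
an animal in two, and 4 px is below any plausible animal size at the
intended magnification. Components are reported with tight bounding box,
mass-centre centroid and pixel area, ordered by box position for
determinism. Boxes use a 0-based, half-open `(x, y, w, h)` convention
everywhere in the package; only the MOT-Challenge file dialect, which is
1-based in the frame column, converts on I/O.

# Classification

Candidate boxes are cropped from the *frame* (not the difference
image), resized to 8×8 by exact area averaging, scaled to [0, 1], and
converted to features: the 64 per-pixel Sobel gradient magnitudes
(`sqrt(Gx^2 + Gy^2)`, 3×3 kernels, edge replication at borders),
flattened row-major. Gradient magnitude was preferred over signed
`Gx`/`Gy` concatenation for rotation robustness — swimming animals have
no canonical orientation; the 128-feature signed variant remains
available (`featureType = "gxgy"`).

The classifier is a random forest (100 trees, Gini splits, `sqrt(p)`
features per split) or a soft-margin SVM (RBF kernel, C = 1), via the
standard `randomForest` and `e1071` implementations, seeded so refits
reproduce predictions. These hyperparameters are conventional defaults,
not tuned values. The decision threshold on the animal-class score is
0.5 and configurable. Confusion-matrix metrics use the standard
definitions — accuracy `(TP+TN)/n`, recall `TP/(TP+FN)`, precision
`TP/(TP+FP)`, F1 the harmonic mean — with zero-denominator ratios
reported as `NA` rather than silently as 0.

# Tracking

Tracking is SORT-style online filtering. Each track carries the state
`x = [u, v, s, r, u̇, v̇, ṡ]` — centroid, box area ("scale"), aspect
ratio, and their per-frame rates, with no rate on the aspect ratio —
under a constant-velocity transition. Noise covariances follow the
public SORT reference convention: measurement noise `diag(1, 1, 10, 10)`
on `[u, v, s, r]`, initial covariance vague on the unobserved
velocities (`1e4`), small process noise (`diag(1, 1, 1, 1, .01, .01,
1e-4)`). The predicted area is floored at a small positive value so a
box can always be reconstructed.

Association between predicted tracks and detections maximises the mixed
similarity

```
C_ij = (1 - lambda) * max(0, (max_d - d_ij) / max_d) + lambda * IOU_ij
```

via the Hungarian algorithm (`clue::solve_LSAP`; verified against
permutation enumeration up to 6×6 in the tests). The distance term is
clamped at zero once the centroid distance exceeds `max_d`, keeping
`C_ij` in [0, 1] — the raw expression would go negative for distant
pairs and distort the assignment. With `lambda = 1` the tracker is
vanilla IOU-SORT; with `lambda = 0` it is a pure normalised-distance
tracker. Defaults, all exposed in the configuration and none dictated
by the method itself: `lambda = 0.5`, `max_d` = a tenth of the frame
diagonal, minimum match similarity `c_min = 0.3`, `max_age = 5` frames
of coasting before a track dies, `min_hits = 2` matches before a track
is emitted (with a grace period in the first frames of a video so
tracking can start at frame 0). Matched pairs below `c_min` are demoted
to unmatched; ties break deterministically.

One deliberate deviation from textbook SORT: emitted observations carry
the *matched detection's* box, while the Kalman state is used only for
prediction and association. The filtered state lags the animal for a
frame or two after sharp turns (wall contact, collisions); the
measurement is the better estimate of where the animal is, and with
error-free detections the output then reproduces the input exactly.
Track ids increase monotonically and are never reused within a video.

# Evaluation

`clearMOT()` implements the standard CLEAR MOT protocol: previous-frame
correspondences are kept while their IOU stays at or above the gate
(default 0.5, standard MOT practice), remaining boxes are matched by
maximum-total-IOU assignment, and an ID switch is counted when a
ground-truth track's matched hypothesis id differs from the last
hypothesis it was ever matched to. `MOTA = 100 * (1 - (FN + FP +
IDs) / #gt)`; `MOTP` is reported as mean matched IOU × 100 (a
centre-distance variant of MOTP exists in the literature; the overlap
form is the default here). `idMetrics()` performs the optimal
whole-trajectory bipartite matching with dummy partners and reports
IDP/IDR/IDF1; it is property-tested against exhaustive enumeration of
all trajectory pairings on small scenarios. Empty ground truth makes
MOTA undefined (`NA` with a warning), never 0.

# Behavioural endpoints

Per-frame displacement is the Euclidean distance between consecutive
centroids. When the tracker coasted over a gap of `g` frames, the
single observed displacement is divided evenly across the `g` steps by
default (keeping per-frame units comparable); a `skip` mode drops gap
steps instead. The immobility rule removes a trajectory containing a
run of at least `20 s * fps` consecutive displacements at or below
`epsilon = 0.5` px/frame — the boundary case (a run of exactly the
window length) is removed. The tolerance is a sub-pixel jitter floor:
centroid estimates of a perfectly still animal fluctuate by a fraction
of a pixel under sensor noise, so a strict zero would never trigger.
Mobile count is the number of surviving trajectories. Per-20-s interval
means bucket displacements into consecutive `20 s * fps`-frame windows
relative to each trajectory's start, reporting a trailing partial
window with its own count.

"Radius of activity" has no standard definition in the tracking
literature; the default here is the maximum distance from any visited
centroid to the centroid of visited points, with half the maximum
pairwise distance (half the point set's diameter) as a labelled
alternative. Distances are in pixels; a mm-per-pixel scale can be
applied externally.

# Dose-response (EC50)

Immobility counts per concentration feed a two-parameter log-logistic
model, `P(immobile | c) = 1 / (1 + (EC50 / c)^slope)`, fitted by
maximum binomial likelihood — equivalently a logistic regression on
log-concentration, which the tests exploit as an independent
cross-check via `glm`. Proprietary toxicity-calculation programs do not
document their estimator; the log-logistic binomial model is the
standard open choice, and a probit link is available. The optimiser is
deterministic Nelder-Mead on `(log EC50, log slope)` from fixed starts:
slope 1 and EC50 at the geometric mean of the two concentrations
bracketing the 50% response. Controls (zero concentration) are excluded
from the likelihood. Data whose observed response fractions never cross
50% are refused unless an explicit `extrapolate` flag is set — a fitted
EC50 outside the tested range is an extrapolation the user must opt
into. Confidence intervals come from a seeded parametric bootstrap
(binomial resampling at the observed per-concentration fractions).
Lab-vs-device concordance is the squared Pearson correlation with the
least-squares line.

# The synthetic scene generator

`generateVideo()` is the package's test bed and defines its study
conditions. It renders dark elliptical animals (intensity 60) on a
light field (200) with additive Gaussian sensor noise (sd 2), static
droplet-like discs of intermediate darkness, slowly drifting speckled
sediment clusters, and per-frame ground truth for the animals only.
Motion is a persistent random walk — velocity `v <- 0.9 v + noise` with
per-axis innovation sd 0.45 px/frame and reflective walls — chosen
deliberately so that tracker tests are not self-fulfilling: the
constant-velocity Kalman model is an approximation to, not the
generator of, the simulated motion.

The default geometry scales a high-resolution flow-cell image down to a
desk-scale 320×240 frame, preserving the animal-length to frame-width
ratio (animals ~8-12 px long, semi-axes drawn from 2.5-6 px) and an
average step near one pixel per frame at 15 fps. Animals are rigid
bodies: pairwise overlaps are resolved as elastic contacts (separation
along the line of centres, exchange of the normal velocity components).
Real animals are solid and their silhouettes rarely fuse in a shallow
cell; without this constraint simulated animals pass through one
another, creating multi-frame silhouette mergers that no
non-splitting detector can resolve. True occlusion and touching-animal
splitting are out of scope throughout the package.

`generatePatchDB()` draws training patches through the same rendering
path the live pipeline sees — blobs painted, then sensor noise, then
tight crop and 8×8 area-average resize — for the animal class, and a
mix of droplet crops, sediment speckle and sparse sensor speckle for
the noise class. It stands in for a manually annotated object database.

What passing on this generator shows: the stage contracts compose
end-to-end — detection finds what is there, the classifier separates
the two synthetic appearance families, identities survive ordinary
crossings, and the endpoints recover the generator's motion statistics.
What it does not show: performance on real imagery, with its
illumination gradients, focus drift, animals touching the cell walls,
partial occlusions, moulted carapaces and reflections. The synthetic
noise families are simple texture models chosen to be separable; real
noise is uglier, and the published performance of this class of system
on real video (identity F1 near 80%, tracking accuracy near 76%) is far
below the near-perfect figures the synthetic suite produces. The
synthetic results validate the implementation, not the instrument.

# Problem sizes and determinism

The test suite exercises scenes of 40-150 frames at 160×120 px for
unit-level checks and one 450-frame 320×240 recording (30 s at 15 fps,
five animals, moderate noise) for the end-to-end check; the acceptance
script uses the same 450-frame conditions, 100-set/100-matrix oracle
sweeps, a 6-concentration × 50-animal EC50 simulation and a 400-patch
classifier database. All randomness flows from explicit seeds (scene,
training, bootstrap seeds are separate derived streams), and repeated
runs are bit-identical, including the written CSV artefacts.

# Known limitations

* No splitting of touching animals and no re-identification after long
  gaps: a track that dies returns as a new identity.
* The rolling mean absorbs anything stationary for about a window,
  including a genuinely immobile animal: immobility is therefore
  scored on trajectories (sub-threshold displacement), not on
  disappearance, and a `freezeBackground` option exists for long
  immobility assays.
* The classifier is a per-patch appearance model; it does not use
  motion cues, so a sediment grain drifting like an animal can only be
  rejected by its texture.
* EC50 confidence intervals resample binomially within concentrations;
  chamber-level replicate structure, if available, would be the better
  bootstrap unit.
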