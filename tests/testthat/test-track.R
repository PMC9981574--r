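test_that("constant-velocity prediction propagates the state", {
  st <- DaphniaTrack:::newTrackState(
    data.frame(x = 8, y = 8, w = 4, h = 4), 1L)
  p1 <- kalmanPredict(st)
  expect_equal(p1$x[1:2], st$x[1:2])      # zero velocity: no motion

  st$x[5] <- 2                            # u = 10, udot = 2
  expect_equal(kalmanPredict(st)$x[1], 12)
  sk <- st
  for (k in 1:5) sk <- kalmanPredict(sk)
  expect_equal(sk$x[1], st$x[1] + 5 * 2)
  # covariance stays symmetric positive-definite
  expect_equal(sk$P, t(sk$P))
  expect_true(all(eigen(sk$P, only.values = TRUE)$values > 0))
})

test_that("updating with the predicted measurement leaves the state fixed", {
  st <- DaphniaTrack:::newTrackState(
    data.frame(x = 10, y = 20, w = 6, h = 4), 1L)
  z <- st$x[1:4]
  up <- DaphniaTrack:::kalmanUpdate(st, z)
  expect_equal(up$x[1:4], z, tolerance = 1e-9)
  # repeated identical measurements converge onto the measurement
  st2 <- kalmanPredict(st)
  for (i in 1:25) st2 <- DaphniaTrack:::kalmanUpdate(kalmanPredict(st2), z)
  expect_equal(st2$x[1:4], z, tolerance = 1e-3)
})

test_that("IOU matches hand-computed overlaps", {
  expect_equal(boxIOU(c(3, 4, 5, 6), c(3, 4, 5, 6)), 1)
  expect_equal(boxIOU(c(0, 0, 2, 2), c(10, 10, 2, 2)), 0)
  expect_equal(boxIOU(c(0, 0, 2, 2), c(1, 0, 2, 2)), 1 / 3)
  expect_equal(boxIOU(c(0, 0, 0, 0), c(0, 0, 0, 0)), 0)  # empty union
})

test_that("the mixed association cost interpolates IOU and distance", {
  a <- list(x = 0, y = 0, w = 4, h = 4)
  b <- list(x = 2, y = 0, w = 4, h = 4)   # iou 1/3, distance 2
  p1 <- associationParams(lambda = 1, maxDist = 10)
  expect_equal(associationCost(a, b, p1), boxIOU(c(0, 0, 4, 4),
                                                 c(2, 0, 4, 4)))
  p0 <- associationParams(lambda = 0, maxDist = 10)
  expect_equal(associationCost(a, a, p0), 1)
  # lambda 0.5, d = maxDist/2, IOU = 0.5 -> 0.25 + 0.25 = 0.5
  A <- list(x = 0, y = 0, w = 4, h = 4)
  B <- list(x = 0, y = 0, w = 4, h = 8)    # inter 16, union 32 -> 0.5
  d <- 2                                   # centres (2,2) vs (2,4)
  pm <- associationParams(lambda = 0.5, maxDist = 4)
  expect_equal(associationCost(A, B, pm),
               0.5 * (4 - d) / 4 + 0.5 * 0.5)
  # clamped at zero beyond maxDist
  far <- list(x = 100, y = 100, w = 4, h = 4)
  expect_equal(associationCost(A, far, p0), 0)
})

test_that("Hungarian association is optimal and gated", {
  r <- associate(matrix(c(0.9, 0.2, 0.1, 0.8), 2), cMin = 0)
  expect_equal(r$matches, cbind(c(1, 2), c(1, 2)), ignore_attr = TRUE)

  sim <- diag(c(0.96, 0.99, 0.7)) + 0.01
  r <- associate(sim, cMin = 0.95)
  expect_equal(r$matches, cbind(c(1, 2), c(1, 2)), ignore_attr = TRUE)
  expect_equal(r$unmatchedRows, 3L)
  expect_equal(r$unmatchedCols, 3L)

  e <- associate(matrix(numeric(), 0, 0), 0.5)
  expect_equal(nrow(e$matches), 0)

  set.seed(13)
  for (i in 1:30) {
    nr <- sample(1:6, 1); nc <- sample(1:6, 1)
    m <- matrix(runif(nr * nc), nr, nc)
    r <- associate(m, cMin = 0)
    expect_equal(sum(m[r$matches]), oracleAssignTotal(m),
                 tolerance = 1e-9)
  }
})

test_that("track lifecycle: emission, gaps, id hygiene", {
  # stationary detection repeated: one track, full coverage under the
  # early-video grace period
  det <- data.frame(frame = 0:99, x = 50, y = 50, w = 6, h = 6)
  tr <- trackVideo(det, associationParams(maxDist = 20))
  expect_equal(unique(tr$track_id), 1)
  expect_equal(nrow(tr), 100)

  # absence longer than maxAge splits the identity
  det2 <- det[det$frame <= 30 | det$frame >= 45, ]
  tr2 <- trackVideo(det2, associationParams(maxDist = 20))
  expect_equal(length(unique(tr2$track_id)), 2)
  expect_true(all(diff(sort(unique(tr2$track_id))) > 0))  # never reused

  # no detections at all
  expect_equal(nrow(trackVideo(det[0, ], associationParams(maxDist = 20))),
               0)
})

test_that("a matched detection resets the coasting clock", {
  p <- associationParams(maxDist = 20)
  st <- trackerStep(list(), data.frame(x = 10, y = 10, w = 5, h = 5),
                    p, frame_index = 0L)
  expect_length(st$tracks, 1)
  st$tracks[[1]]$time_since_update <- 3L
  st2 <- trackerStep(st$tracks, data.frame(x = 10, y = 10, w = 5, h = 5),
                     p, frame_index = 1L, nextId = st$nextId)
  expect_equal(st2$tracks[[1]]$time_since_update, 0L)
  # no detections, no tracks: a no-op
  st0 <- trackerStep(list(), data.frame(x = numeric(), y = numeric(),
                                        w = numeric(), h = numeric()), p)
  expect_length(st0$tracks, 0)
  expect_equal(nrow(st0$emitted), 0)
})

test_that("crossing straight-line movers keep their identities", {
  t1 <- lineTraj(1L, n = 30, x0 = 0, y0 = 28, vx = 2, vy = 0)
  t2 <- lineTraj(2L, n = 30, x0 = 28, y0 = 0, vx = 0, vy = 2)
  det <- rbind(t1, t2)[, c("frame", "x", "y", "w", "h")]
  det <- det[order(det$frame), ]
  tr <- trackVideo(det, associationParams(maxDist = 30))
  gt <- rbind(t1, t2)
  ev <- evaluateTracking(gt, tr)
  expect_equal(ev$IDs, 0)
  expect_gte(ev$MOTA, 95)
})

test_that("perfect detections yield perfect tracking", {
  # default-speed animals: constant-velocity prediction holds between
  # collisions, which are rare in a 60-frame clip
  s <- generateVideo(sceneParams(width = 160, height = 120, nFrames = 60,
                                 nDaphnia = 5, nNoiseStatic = 0,
                                 nNoiseDrift = 0, pixelNoiseSigma = 0,
                                 seed = 14))
  gt <- groundTruth(s)
  det <- gt[, c("frame", "x", "y", "w", "h")]
  tr <- trackVideo(det, associationParams(), frameSize = c(160, 120))
  ev <- evaluateTracking(gt, tr)
  expect_equal(ev$MOTA, 100)
  expect_equal(ev$IDs, 0)
  expect_equal(length(unique(tr$track_id)), 5)
})

test_that("lambda = 1 reduces the cost to pure IOU", {
  set.seed(15)
  p1 <- associationParams(lambda = 1, maxDist = 5)
  for (i in 1:10) {
    a <- list(x = runif(1, 0, 20), y = runif(1, 0, 20),
              w = runif(1, 2, 8), h = runif(1, 2, 8))
    b <- list(x = runif(1, 0, 20), y = runif(1, 0, 20),
              w = runif(1, 2, 8), h = runif(1, 2, 8))
    expect_equal(associationCost(a, b, p1),
                 boxIOU(unlist(a), unlist(b)))
  }
})
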