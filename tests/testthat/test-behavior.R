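test_that("displacements are consecutive-frame Euclidean distances", {
  tr <- data.frame(frame = 0:4, cx = rep(3, 5), cy = rep(7, 5))
  expect_equal(frameDisplacements(tr), rep(0, 4))

  tr <- data.frame(frame = 0:1, cx = c(0, 3), cy = c(0, 4))
  expect_equal(frameDisplacements(tr), 5)

  n <- 30; c0 <- 1.7
  tr <- data.frame(frame = 0:n, cx = c0 * (0:n) * 0.6,
                   cy = c0 * (0:n) * 0.8)
  expect_equal(frameDisplacements(tr), rep(c0, n), tolerance = 1e-12)

  expect_length(frameDisplacements(tr[1, ]), 0)
})

test_that("coasting gaps are split across frames or skipped", {
  tr <- data.frame(frame = c(0, 1, 4), cx = c(0, 1, 7), cy = 0)
  expect_equal(frameDisplacements(tr, gap = "split"), c(1, 2, 2, 2))
  expect_equal(frameDisplacements(tr, gap = "skip"), 1)
})

test_that("meanSE reproduces the published per-video aggregations", {
  gt <- meanSE(c(3.26, 3.45, 2.94, 3.65))
  expect_equal(round(unname(gt["mean"]), 1), 3.3)
  expect_equal(round(unname(gt["se"]), 3), 0.151)
  dev <- meanSE(c(4.32, 2.0, 2.1, 2.39))
  expect_equal(round(unname(dev["mean"]), 2), 2.70)
  expect_equal(round(unname(dev["se"]), 3), 0.545)
  expect_equal(unname(meanSE(rep(2.5, 3))), c(2.5, 0, 3))
  expect_equal(unname(meanSE(4)["se"]), 0)
  expect_error(meanSE(numeric()), "at least one")
})

stationaryTraj <- function(id, nStill, nMove = 0, fps = 15) {
  n <- nStill + nMove
  cx <- c(rep(10, nStill + 1), cumsum(rep(2, nMove)) + 10)[1:(n + 1)]
  data.frame(track_id = id, frame = 0:n, cx = cx, cy = 5)
}

test_that("the stationary filter removes >= window runs exactly", {
  fps <- 15
  runLen <- 20 * fps
  still <- stationaryTraj(1L, runLen)          # exactly 300 zero steps
  shorter <- stationaryTraj(2L, runLen - 1, 5) # 299 zero steps, then moves
  mover <- data.frame(track_id = 3L, frame = 0:310,
                      cx = (0:310) * 2, cy = 0)
  trajs <- rbind(still, shorter, mover)
  sf <- stationaryFilter(trajs, fps = fps)
  expect_equal(sort(unique(sf$removed$track_id)), 1)
  expect_equal(sort(unique(sf$kept$track_id)), c(2, 3))
  # partition property
  expect_equal(nrow(sf$kept) + nrow(sf$removed), nrow(trajs))
  expect_equal(mobileCount(trajs, fps = fps), 2)
})

test_that("interval means equal brute-force bucket recomputation", {
  fps <- 15
  tr <- data.frame(frame = 0:(40 * fps), cx = (0:(40 * fps)) * 1.3,
                   cy = 0)
  im <- intervalMeanDistance(tr, fps = fps)
  expect_equal(nrow(im), 2)                    # 40 s -> 2 full intervals
  expect_equal(im$mean_distance, c(1.3, 1.3), tolerance = 1e-12)
  expect_equal(im$n_frames, c(300, 300))

  set.seed(20)
  tr2 <- data.frame(frame = 0:170, cx = cumsum(rnorm(171)),
                    cy = cumsum(rnorm(171)))
  im2 <- intervalMeanDistance(tr2, fps = 5, intervalSeconds = 10)
  disp <- frameDisplacements(tr2)
  buckets <- split(disp, ((seq_along(disp) - 1) %/% 50) + 1)
  expect_equal(im2$mean_distance, unname(vapply(buckets, mean, 1)),
               tolerance = 1e-12)
  expect_equal(im2$n_frames[length(im2$n_frames)],
               length(buckets[[length(buckets)]]))
})

test_that("mobileCount equals the kept-list size on random fixtures", {
  set.seed(21)
  for (i in 1:5) {
    trajs <- do.call(rbind, lapply(1:6, function(id) {
      still <- runif(1) < 0.5
      n <- 320
      step <- if (still) rep(0, n) else abs(rnorm(n, 2))
      data.frame(track_id = id, frame = 0:n,
                 cx = cumsum(c(0, step)), cy = 0)
    }))
    sf <- stationaryFilter(trajs, fps = 15)
    expect_equal(mobileCount(trajs, fps = 15),
                 length(unique(sf$kept$track_id)))
  }
})

test_that("radius of activity matches closed forms", {
  still <- data.frame(cx = rep(4, 5), cy = rep(9, 5))
  expect_equal(radiusOfActivity(still), 0)

  two <- data.frame(cx = c(0, 6), cy = c(0, 8))   # 10 px apart
  expect_equal(radiusOfActivity(two), 5)
  expect_equal(radiusOfActivity(two, method = "diameter"), 5)

  ang <- seq(0, 2 * pi, length.out = 37)[-37]
  circ <- data.frame(cx = 5 * cos(ang), cy = 5 * sin(ang))
  expect_equal(radiusOfActivity(circ), 5, tolerance = 1e-9)
})

test_that("behaviorSummary aggregates per-track means with a SE", {
  trajs <- rbind(
    data.frame(track_id = 1L, frame = 0:10, cx = (0:10) * 1, cy = 0),
    data.frame(track_id = 2L, frame = 0:10, cx = (0:10) * 3, cy = 0))
  bs <- behaviorSummary(trajs, fps = 15)
  expect_equal(bs$perTrack$mean_displacement, c(1, 3))
  expect_equal(bs$mean, 2)
  expect_equal(bs$se, unname(meanSE(c(1, 3))["se"]))
  expect_equal(bs$mobile, 2)
})
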