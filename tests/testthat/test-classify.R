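test_that("patch extraction resizes by exact area averaging", {
  # constant crop stays constant
  fr <- matrix(80, 30, 30)
  p <- extractPatch(fr, list(x = 5, y = 5, w = 13, h = 9))
  expect_true(all(abs(p - 80 / 255) < 1e-12))

  # an 8x8 crop is passed through unchanged (up to the [0,1] scaling)
  set.seed(3)
  fr <- matrix(runif(400, 0, 255), 20, 20)
  p <- extractPatch(fr, list(x = 4, y = 6, w = 8, h = 8))
  expect_equal(p * 255, fr[7:14, 5:12], tolerance = 1e-12)

  # 16x16 checkerboard of 2x2 tiles: each output pixel is its block mean
  tile <- matrix(c(0, 255, 255, 0), 2, 2)
  board <- tile[rep(1:2, 8), rep(1:2, 8)]
  p <- extractPatch(board, list(x = 0, y = 0, w = 16, h = 16))
  blockMeans <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    blockMeans[i, j] <- mean(board[(2 * i - 1):(2 * i),
                                   (2 * j - 1):(2 * j)])
  expect_equal(p * 255, blockMeans, tolerance = 1e-12)

  expect_error(extractPatch(fr, list(x = 0, y = 0, w = 0, h = 5)),
               "degenerate")
  expect_error(extractPatch(fr, list(x = 18, y = 0, w = 8, h = 8)),
               "outside")
})

test_that("Sobel features match a hand convolution", {
  expect_equal(sobelFeatures(matrix(0.4, 8, 8)), rep(0, 64))

  # vertical step: left half 0, right half 1
  step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  feat <- matrix(sobelFeatures(step), 8, 8, byrow = TRUE)
  # away from the step the response is zero
  expect_true(all(feat[, c(1:3, 6:8)] == 0))
  # at the step columns the replicated-edge Sobel Gx response is
  # (1+2+1) * (1-0) = 4, Gy = 0, magnitude 4
  expect_true(all(feat[, 4:5] == 4))

  # 90-degree rotation permutes Gx and Gy, preserving magnitudes
  set.seed(4)
  p <- matrix(runif(64), 8, 8)
  r <- t(p)[8:1, ]                        # rotate 90 degrees
  expect_equal(sort(sobelFeatures(p)), sort(sobelFeatures(r)),
               tolerance = 1e-12)
})

test_that("features follow the blob when the crop follows the blob", {
  fr <- matrix(200, 40, 40)
  blob <- matrix(60, 6, 6)
  fr[11:16, 11:16] <- blob
  fr[26:31, 21:26] <- blob
  f1 <- sobelFeatures(extractPatch(fr, list(x = 9, y = 9, w = 10, h = 10)))
  f2 <- sobelFeatures(extractPatch(fr, list(x = 19, y = 24, w = 10, h = 10)))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("classifiers separate a separable toy problem and are seeded", {
  set.seed(5)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2),
             matrix(rnorm(60, 6), ncol = 2))
  y <- factor(rep(c("daphnia", "noise"), each = 30))
  probe <- rbind(matrix(rnorm(20, 0), ncol = 2),
                 matrix(rnorm(20, 6), ncol = 2))
  for (m in c("rf", "svm")) {
    fit <- trainClassifier(X, y, method = m, seed = 2)
    pr <- predictPatches(fit, probe)
    expect_equal(pr$label, rep(c("daphnia", "noise"), each = 10))
    fit2 <- trainClassifier(X, y, method = m, seed = 2)
    expect_equal(predictPatches(fit2, probe), pr)
  }
  expect_error(trainClassifier(X, factor(rep("daphnia", 60)),
                               method = "rf"), "both classes")
})

test_that("holdout accuracy is high and stable across training seeds", {
  db <- generatePatchDB(sceneParams(seed = 42), nPerClass = 150)
  set.seed(6)
  idx <- sample(300, 220)
  train <- list(patches = db$patches[idx], label = db$label[idx])
  testP <- db$patches[-idx]
  testY <- as.character(db$label[-idx])
  accs <- vapply(c(1, 2), function(sd) {
    fit <- trainClassifier(train, method = "rf", seed = sd)
    mean(predictPatches(fit, testP)$label == testY)
  }, numeric(1))
  expect_true(all(accs >= 0.95))
  expect_lt(abs(diff(accs)), 0.05)
})

test_that("classifyObjects retains animals and discards noise", {
  model <- sharedClassifier()
  expect_equal(nrow(classifyObjects(model, matrix(200, 20, 20),
                                    connectedComponents(
                                      matrix(FALSE, 20, 20)))), 0)
  p <- smallScene(seed = 23, nDaphnia = 2, nFrames = 40, noise = TRUE)
  s <- generateVideo(p)
  bg <- backgroundModel(window = 30)
  for (f in frames(s)[1:30]) bg <- updateBackground(bg, f)
  tp <- 0; fp <- 0; fn <- 0
  for (t in 31:40) {
    fr <- frames(s)[[t]]
    d <- subtractBackground(fr, bg)
    cc <- connectedComponents(binarize(d, kmeansThreshold(d)),
                              min_area = 4, frame_index = t - 1)
    kept <- classifyObjects(model, fr, cc)
    g <- groundTruth(s)[groundTruth(s)$frame == t - 1, ]
    hit <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(kept))) {
      dd <- sqrt((kept$cx[i] - g$cx)^2 + (kept$cy[i] - g$cy)^2)
      if (length(dd) && min(dd) < 3) {
        tp <- tp + 1; hit[which.min(dd)] <- TRUE
      } else fp <- fp + 1
    }
    fn <- fn + sum(!hit)
  }
  expect_gte(tp / (tp + fp), 0.9)        # precision
  expect_gte(tp / (tp + fn), 0.9)        # recall
})

test_that("confusion metrics implement the standard definitions", {
  pred <- c(rep("daphnia", 100), rep("noise", 25))
  truth <- c(rep("daphnia", 90), rep("noise", 10),
             rep("daphnia", 5), rep("noise", 20))
  cm <- confusionMetrics(pred, truth)
  expect_equal(c(cm$TP, cm$FP, cm$FN, cm$TN), c(90, 10, 5, 20))
  expect_equal(cm$precision, 0.900, tolerance = 1e-4)
  expect_equal(cm$recall, 0.9474, tolerance = 1e-4)
  expect_equal(cm$f1, 0.9231, tolerance = 1e-4)
  expect_equal(cm$accuracy, 0.880, tolerance = 1e-4)

  # undefined ratios are NA, not zero
  cm0 <- confusionMetrics(rep("noise", 4), rep("noise", 4))
  expect_true(is.na(cm0$precision) && is.na(cm0$recall))
  expect_error(confusionMetrics(character(), character()), "empty")

  # F1 is the harmonic mean for any nonzero precision/recall
  set.seed(7)
  for (i in 1:20) {
    pr <- runif(1, 0.05, 1); rc <- runif(1, 0.05, 1)
    expect_equal(f1Score(pr, rc), 2 / (1 / pr + 1 / rc),
                 tolerance = 1e-12)
  }
})
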