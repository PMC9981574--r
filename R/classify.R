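#' Area-averaging image resize
#'
#' Resizes a numeric matrix by exact area averaging: each output pixel is
#' the average of the source region it covers, with fractional boundary
#' rows/columns weighted by their overlap. Implemented as a pair of sparse
#' row/column weight matrices, so an identity-size resize is exact and a
#' 2:1 downscale equals plain 2x2 block means.
#'
#' @param mat numeric matrix.
#' @param outRows,outCols output dimensions.
#' @return Numeric `outRows` x `outCols` matrix.
#' @export
resizeArea <- function(mat, outRows = 8L, outCols = 8L) {
  weights <- function(nIn, nOut) {
    W <- matrix(0, nOut, nIn)
    step <- nIn / nOut
    for (i in seq_len(nOut)) {
      lo <- (i - 1) * step; hi <- i * step
      j0 <- floor(lo) + 1L; j1 <- ceiling(hi)
      for (j in j0:min(j1, nIn)) {
        W[i, j] <- min(hi, j) - max(lo, j - 1)
      }
    }
    W / step
  }
  weights(nrow(mat), outRows) %*% mat %*% t(weights(ncol(mat), outCols))
}

#' Extract a candidate object's 8x8 patch
#'
#' Crops the candidate's bounding box out of the frame, resizes the crop
#' to 8x8 by area averaging and rescales intensities from [0, 255] to
#' [0, 1]. This is the representation the patch classifier consumes and
#' the one [generatePatchDB()] mimics.
#'
#' @param frame numeric intensity matrix in [0, 255].
#' @param obj one row of a candidate table (needs `x, y, w, h`), or a
#'   list/vector with those fields.
#' @return An 8x8 numeric matrix in [0, 1].
#' @export
extractPatch <- function(frame, obj) {
  x <- as.numeric(obj[["x"]]); y <- as.numeric(obj[["y"]])
  w <- as.numeric(obj[["w"]]); h <- as.numeric(obj[["h"]])
  if (w < 1 || h < 1) stop("degenerate bounding box (w or h < 1)")
  if (x < 0 || y < 0 || x + w > ncol(frame) || y + h > nrow(frame))
    stop("bounding box outside the frame")
  crop <- frame[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE]
  resizeArea(crop, 8L, 8L) / 255
}

# Standard 3x3 Sobel kernels, correlation convention.
.sobelX <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
.sobelY <- t(.sobelX)

# 3x3 correlation with edge replication.
conv3 <- function(patch, kern) {
  h <- nrow(patch); w <- ncol(patch)
  pad <- patch[c(1, 1:h, h), c(1, 1:w, w)]
  out <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    out <- out + kern[dr + 2, dc + 2] *
      pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  out
}

#' Sobel edge features of an 8x8 patch
#'
#' Applies the standard 3x3 Sobel kernels (with edge replication at the
#' borders) and returns the per-pixel gradient magnitude
#' `sqrt(Gx^2 + Gy^2)` flattened row-major into a 64-vector. A constant
#' patch maps to the zero vector. With `type = "gxgy"` the signed `Gx`
#' and `Gy` responses are concatenated instead (128 features).
#'
#' @param patch 8x8 numeric matrix.
#' @param type `"magnitude"` (default) or `"gxgy"`.
#' @return Numeric feature vector of length 64 (or 128).
#' @export
sobelFeatures <- function(patch, type = c("magnitude", "gxgy")) {
  type <- match.arg(type)
  stopifnot(is.matrix(patch), all(dim(patch) == c(8, 8)))
  gx <- conv3(patch, .sobelX)
  gy <- conv3(patch, .sobelY)
  if (type == "magnitude") {
    as.vector(t(sqrt(gx^2 + gy^2)))
  } else {
    c(as.vector(t(gx)), as.vector(t(gy)))
  }
}

patchFeatureMatrix <- function(patches, type = "magnitude") {
  t(vapply(patches, sobelFeatures,
           numeric(if (type == "magnitude") 64 else 128), type = type))
}

#' Train the animal/noise patch classifier
#'
#' Fits either a random forest (bagged decision trees splitting on Gini
#' or entropy impurity with random feature subsets) or a soft-margin
#' support vector machine on the Sobel features of labelled 8x8 patches.
#' Both solvers are the standard implementations from
#' \pkg{randomForest} and \pkg{e1071}; the seed makes refits reproduce
#' their predictions exactly.
#'
#' @param db a patch database as returned by [generatePatchDB()]
#'   (elements `patches`, `label`), or a numeric feature matrix if
#'   `labels` is given.
#' @param labels optional factor of labels when `db` is a feature matrix.
#' @param method `"rf"` or `"svm"`.
#' @param featureType passed to [sobelFeatures()].
#' @param seed training seed.
#' @param ntree,criterion,mtry random-forest hyperparameters (default 100
#'   trees, Gini splits, `sqrt(p)` features per split).
#' @param kernel,cost SVM hyperparameters (default RBF kernel, C = 1).
#' @return A fitted [PatchClassifier-class].
#' @examples
#' db <- generatePatchDB(sceneParams(seed = 5), nPerClass = 30)
#' model <- trainClassifier(db, method = "rf", seed = 5)
#' model
#' @export
trainClassifier <- function(db, labels = NULL, method = c("rf", "svm"),
                            featureType = c("magnitude", "gxgy"),
                            seed = 1L, ntree = 100L,
                            criterion = c("gini", "entropy"),
                            mtry = NULL, kernel = "radial", cost = 1) {
  method <- match.arg(method)
  featureType <- match.arg(featureType)
  criterion <- match.arg(criterion)
  if (is.list(db) && !is.null(db$patches)) {
    X <- patchFeatureMatrix(db$patches, featureType)
    y <- db$label
  } else {
    X <- as.matrix(db)
    y <- labels
  }
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop("training data must contain both classes")
  set.seed(as.integer(seed))
  if (method == "rf") {
    if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
    if (criterion == "entropy")
      warning("the installed random-forest backend splits on Gini ",
              "impurity only; 'entropy' falls back to Gini")
    fit <- randomForest::randomForest(x = X, y = y, ntree = ntree,
                                      mtry = mtry)
    hyper <- list(ntree = ntree, criterion = criterion, mtry = mtry)
  } else {
    fit <- e1071::svm(x = X, y = y, kernel = kernel, cost = cost,
                      probability = TRUE)
    hyper <- list(kernel = kernel, cost = cost)
  }
  new("PatchClassifier", method = method, fit = fit, hyper = hyper,
      seed = as.integer(seed), featureType = featureType)
}

#' Predict labels and scores for patches
#'
#' @param model a [PatchClassifier-class].
#' @param patches list of 8x8 patches, or a precomputed feature matrix.
#' @param threshold score above which a patch is called `"daphnia"`.
#' @return data.frame with columns `label` and `score` (probability of
#'   the animal class, in [0, 1]).
#' @export
predictPatches <- function(model, patches, threshold = 0.5) {
  X <- if (is.list(patches)) {
    patchFeatureMatrix(patches, model@featureType)
  } else {
    m <- as.matrix(patches)
    if (ncol(m) == 1 && nrow(m) %in% c(64, 128)) m <- t(m)
    m
  }
  if (model@method == "rf") {
    p <- stats::predict(model@fit, X, type = "prob")[, "daphnia"]
  } else {
    pr <- stats::predict(model@fit, X, probability = TRUE)
    p <- attr(pr, "probabilities")[, "daphnia"]
  }
  data.frame(label = ifelse(p > threshold, "daphnia", "noise"),
             score = as.numeric(p), stringsAsFactors = FALSE)
}

#' Classify candidate objects and keep the animals
#'
#' Extracts the 8x8 patch of every candidate, scores it with the patch
#' classifier, and returns only the candidates predicted to be animals,
#' with their labels and scores attached; noise candidates are discarded.
#'
#' @param model a [PatchClassifier-class].
#' @param frame the frame the candidates came from.
#' @param objects candidate data.frame from [connectedComponents()].
#' @param threshold decision threshold on the animal-class score.
#' @return The retained subset of `objects` with `label` and `score`
#'   columns appended.
#' @export
classifyObjects <- function(model, frame, objects, threshold = 0.5) {
  if (!nrow(objects)) {
    return(cbind(objects, data.frame(label = character(),
                                     score = numeric())))
  }
  patches <- lapply(seq_len(nrow(objects)), function(i)
    extractPatch(frame, objects[i, ]))
  pred <- predictPatches(model, patches, threshold)
  out <- cbind(objects, pred)
  out <- out[out$label == "daphnia", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binary confusion counts and derived metrics
#'
#' Compares predicted and true labels and returns the confusion counts
#' with the standard derived metrics: accuracy `(TP+TN)/n`, recall
#' `TP/(TP+FN)`, precision `TP/(TP+FP)` and F1 as the harmonic mean of
#' precision and recall. Ratios with a zero denominator are reported as
#' `NA` rather than 0.
#'
#' @param pred,truth equal-length label vectors.
#' @param positive label treated as the positive class.
#' @return A list with `TP, TN, FP, FN, accuracy, recall, precision, f1`.
#' @examples
#' confusionMetrics(c("daphnia", "noise"), c("daphnia", "daphnia"))
#' @export
confusionMetrics <- function(pred, truth, positive = "daphnia") {
  if (!length(pred)) stop("empty label vectors")
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  p <- pred == positive; t <- truth == positive
  TP <- sum(p & t); TN <- sum(!p & !t)
  FP <- sum(p & !t); FN <- sum(!p & t)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(TP, TP + FP)
  recall <- safe(TP, TP + FN)
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       accuracy = safe(TP + TN, TP + TN + FP + FN),
       recall = recall, precision = precision,
       f1 = f1Score(precision, recall))
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * precision * recall / (precision + recall)`;
#' `NA` when either input is `NA` or both are zero.
#'
#' @param precision,recall values in [0, 1].
#' @return Numeric F1 in [0, 1] or `NA`.
#' @examples
#' f1Score(0.942, 0.987)
#' @export
f1Score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}
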