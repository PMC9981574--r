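#' @import methods
#' @importFrom randomForest randomForest
#' @importFrom e1071 svm
#' @importFrom stats predict
NULL

#' Parameters of a synthetic swimming scene
#'
#' An S4 container holding every knob of the synthetic video generator:
#' frame geometry, frame rate, the number of swimming animals and of
#' droplet/sediment noise objects, blob geometry and intensity, the
#' persistent-random-walk motion parameters and the random seed. The seed
#' fully determines all randomness so a scene can be regenerated
#' bit-identically.
#'
#' @slot width,height frame size in pixels.
#' @slot nFrames number of frames to render.
#' @slot fps frame rate in frames per second (default 15, matching typical
#'   flow-cell cameras).
#' @slot nDaphnia number of swimming elliptical animals.
#' @slot nNoiseStatic number of static droplet-like noise objects.
#' @slot nNoiseDrift number of slowly drifting sediment-like noise objects.
#' @slot blobAxisRange range (pixels) the two ellipse semi-axes of each
#'   animal are drawn from; the larger draw becomes the major axis.
#' @slot speedSigma standard deviation (pixels/frame) of the per-frame
#'   velocity innovation of the random walk.
#' @slot velocityPersistence autocorrelation of the velocity process in
#'   [0, 1]; 0 is white-noise jitter, values near 1 give smooth paths.
#' @slot bgLevel,fgLevel background and animal intensity in [0, 255];
#'   animals are darker than the background under backlit illumination.
#' @slot pixelNoiseSigma standard deviation of additive Gaussian pixel
#'   noise (intensity units).
#' @slot seed integer seed controlling all randomness.
#' @seealso [sceneParams()], [generateVideo()]
#' @export
setClass("SceneParams", representation(
  width = "integer", height = "integer", nFrames = "integer",
  fps = "numeric", nDaphnia = "integer", nNoiseStatic = "integer",
  nNoiseDrift = "integer", blobAxisRange = "numeric",
  speedSigma = "numeric", velocityPersistence = "numeric",
  bgLevel = "numeric", fgLevel = "numeric", pixelNoiseSigma = "numeric",
  seed = "integer"
))

setValidity("SceneParams", function(object) {
  msg <- character()
  if (object@width < 1L || object@height < 1L || object@nFrames < 1L)
    msg <- c(msg, "width, height and nFrames must all be >= 1")
  if (object@fps <= 0) msg <- c(msg, "fps must be positive")
  if (object@nDaphnia < 0L || object@nNoiseStatic < 0L ||
      object@nNoiseDrift < 0L)
    msg <- c(msg, "object counts must be non-negative")
  if (length(object@blobAxisRange) != 2L ||
      any(object@blobAxisRange <= 0) ||
      diff(object@blobAxisRange) < 0)
    msg <- c(msg, "blobAxisRange must be an increasing positive pair")
  if (2 * max(object@blobAxisRange) >= min(object@width, object@height))
    msg <- c(msg, "blob axes exceed the frame size")
  if (object@bgLevel < 0 || object@bgLevel > 255 ||
      object@fgLevel < 0 || object@fgLevel > 255)
    msg <- c(msg, "bgLevel and fgLevel must lie in [0, 255]")
  if (object@fgLevel == object@bgLevel)
    msg <- c(msg, "fgLevel must differ from bgLevel")
  if (object@velocityPersistence < 0 || object@velocityPersistence > 1)
    msg <- c(msg, "velocityPersistence must lie in [0, 1]")
  if (object@speedSigma < 0 || object@pixelNoiseSigma < 0)
    msg <- c(msg, "noise sigmas must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A synthetic scene: rendered frames plus ground truth
#'
#' Returned by [generateVideo()]. Holds the rendered grayscale frames
#' (a list of numeric matrices with intensities in [0, 255], addressed
#' `[row, col]` with the origin at the top left), the ground-truth table of
#' animal positions, and the generating [SceneParams-class].
#'
#' The ground truth is a `data.frame` with one row per animal per frame and
#' columns `frame` (0-based), `id` (positive integer track identity),
#' `x`, `y`, `w`, `h` (tight bounding box, 0-based half-open pixel
#' convention) and `cx`, `cy` (true continuous ellipse centre). Noise
#' objects are deliberately absent from the ground truth.
#'
#' @slot frames list of numeric matrices.
#' @slot groundTruth data.frame as described above.
#' @slot params the generating [SceneParams-class].
#' @seealso [frames()], [groundTruth()], [sceneParams()]
#' @export
setClass("SyntheticScene", representation(
  frames = "list", groundTruth = "data.frame", params = "SceneParams"
))

setValidity("SyntheticScene", function(object) {
  gt <- object@groundTruth
  need <- c("frame", "id", "x", "y", "w", "h", "cx", "cy")
  if (!all(need %in% names(gt)))
    return(sprintf("groundTruth must have columns %s",
                   paste(need, collapse = ", ")))
  if (nrow(gt) && anyDuplicated(gt[, c("frame", "id")]))
    return("at most one ground-truth record per (frame, id)")
  TRUE
})

#' Rolling-mean background model
#'
#' Maintains a moving window of the most recent frames and their per-pixel
#' arithmetic mean. The mean image is the background estimate that
#' [subtractBackground()] removes from incoming frames; the model is
#' "warmed up" once the buffer holds a full window (by default 20 seconds
#' of video), and frames seen before warm-up yield no detections.
#'
#' @slot window maximum number of buffered frames (default `fps * 20`).
#' @slot buffer list of retained frames, oldest first.
#' @slot sumImage running per-pixel sum of the buffered frames.
#' @seealso [backgroundModel()], [updateBackground()], [meanImage()],
#'   [isWarmedUp()]
#' @export
setClass("BackgroundModel", representation(
  window = "integer", buffer = "list", sumImage = "ANY"
))

setValidity("BackgroundModel", function(object) {
  if (object@window < 1L) return("window must be >= 1")
  if (length(object@buffer) > object@window)
    return("buffer longer than window")
  TRUE
})

#' Fitted patch classifier separating animals from noise
#'
#' Wraps a fitted random forest or support vector machine that labels an
#' 8x8 candidate patch (through its 64 Sobel gradient-magnitude features)
#' as `"daphnia"` or `"noise"`, with a score in [0, 1] for the animal
#' class. Refitting with the same training data and seed reproduces the
#' predictions.
#'
#' @slot method `"rf"` or `"svm"`.
#' @slot fit the underlying fitted model object.
#' @slot hyper list of hyperparameters used at training time.
#' @slot seed integer training seed.
#' @slot featureType `"magnitude"` (64 features) or `"gxgy"` (128).
#' @seealso [trainClassifier()], [predictPatches()], [classifyObjects()]
#' @export
setClass("PatchClassifier", representation(
  method = "character", fit = "ANY", hyper = "list",
  seed = "integer", featureType = "character"
))

#' Two-parameter log-logistic dose-response fit
#'
#' Result of [fitEC50()]: the maximum-likelihood median effective
#' concentration and Hill slope of the model
#' \eqn{P(\mathrm{immobile} \mid c) = 1 / (1 + (EC_{50}/c)^{slope})}
#' fitted to binomial immobility counts.
#'
#' @slot ec50 estimated EC50 in the concentration units of the input.
#' @slot slope dimensionless Hill slope (positive for increasing toxicity).
#' @slot logLik maximized binomial log-likelihood.
#' @slot converged logical convergence flag from the optimizer.
#' @slot ci two-sided bootstrap confidence interval for the EC50, or
#'   `NA` when not requested.
#' @slot records the dose-response table the fit consumed.
#' @slot link `"logit"` (log-logistic) or `"probit"`.
#' @seealso [fitEC50()], [predictImmobility()]
#' @export
setClass("Ec50Fit", representation(
  ec50 = "numeric", slope = "numeric", logLik = "numeric",
  converged = "logical", ci = "numeric", records = "data.frame",
  link = "character"
))

setValidity("Ec50Fit", function(object) {
  if (object@ec50 <= 0) return("ec50 must be positive")
  TRUE
})
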