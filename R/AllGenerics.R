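#' Accessors for synthetic scenes and background models
#'
#' `frames()` returns the list of grayscale frames of a
#' [SyntheticScene-class]; `groundTruth()` its ground-truth table;
#' `sceneParams()` its generating parameters; `nFrames()` the number of
#' frames. `meanImage()` returns the current background estimate of a
#' [BackgroundModel-class] and `isWarmedUp()` whether its buffer holds a
#' full window.
#'
#' @param x a [SyntheticScene-class] or [BackgroundModel-class].
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("params", function(x) standardGeneric("params"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("meanImage", function(x) standardGeneric("meanImage"))

#' @rdname accessors
#' @export
setGeneric("isWarmedUp", function(x) standardGeneric("isWarmedUp"))

#' @rdname updateBackground
#' @export
setGeneric("updateBackground",
           function(model, frame) standardGeneric("updateBackground"))

#' @rdname accessors
#' @export
setMethod("frames", "SyntheticScene", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticScene", function(x) x@groundTruth)

#' @rdname accessors
#' @export
setMethod("params", "SyntheticScene", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("nFrames", "SyntheticScene", function(x) length(x@frames))

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(
    "SceneParams: %dx%d px, %d frames @ %g fps\n",
    object@width, object@height, object@nFrames, object@fps))
  cat(sprintf(
    "  %d daphnia, %d static + %d drifting noise objects, seed %d\n",
    object@nDaphnia, object@nNoiseStatic, object@nNoiseDrift, object@seed))
  cat(sprintf(
    "  intensity bg %g / fg %g, pixel noise sd %g\n",
    object@bgLevel, object@fgLevel, object@pixelNoiseSigma))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene: %d frames (%dx%d px), %d ground-truth records\n",
    length(object@frames), object@params@width, object@params@height,
    nrow(object@groundTruth)))
})

setMethod("show", "BackgroundModel", function(object) {
  cat(sprintf(
    "BackgroundModel: %d/%d frames buffered (%s)\n",
    length(object@buffer), object@window,
    if (isWarmedUp(object)) "warmed up" else "warming up"))
})

setMethod("show", "PatchClassifier", function(object) {
  cat(sprintf("PatchClassifier: %s (%s features, seed %d)\n",
              toupper(object@method), object@featureType, object@seed))
})

setMethod("show", "Ec50Fit", function(object) {
  cat(sprintf("Ec50Fit (%s link): EC50 = %.4g, slope = %.3g\n",
              object@link, object@ec50, object@slope))
  if (!anyNA(object@ci))
    cat(sprintf("  bootstrap 95%% CI: [%.4g, %.4g]\n",
                object@ci[1], object@ci[2]))
  cat(sprintf("  log-likelihood %.3f, converged: %s\n",
              object@logLik, object@converged))
})
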