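#' Create a rolling-mean background model
#'
#' The background estimate is the per-pixel arithmetic mean of the most
#' recent `window` frames (by default 20 seconds of video). The model must
#' see a full window before it is "warmed up"; until then
#' [subtractBackground()] refuses to produce a difference image, so the
#' first 20 s of a recording yield no detections.
#'
#' @param window number of frames in the averaging window.
#' @param fps,windowSeconds alternative specification: `window` defaults
#'   to `fps * windowSeconds`.
#' @return A [BackgroundModel-class] with an empty buffer.
#' @examples
#' bg <- backgroundModel(window = 3)
#' bg <- updateBackground(bg, matrix(100, 4, 4))
#' isWarmedUp(bg)
#' @export
backgroundModel <- function(window = NULL, fps = 15, windowSeconds = 20) {
  if (is.null(window)) window <- round(fps * windowSeconds)
  new("BackgroundModel", window = as.integer(window), buffer = list(),
      sumImage = NULL)
}

#' Feed one frame to the background model
#'
#' Appends the frame to the buffer, evicting the oldest frame once the
#' buffer exceeds the window, and updates the running per-pixel sum so
#' that [meanImage()] is always the exact arithmetic mean of the retained
#' frames.
#'
#' @param model a [BackgroundModel-class].
#' @param frame a numeric matrix with the same dimensions as previously
#'   seen frames.
#' @return The updated [BackgroundModel-class].
#' @export
setMethod("updateBackground", c("BackgroundModel", "matrix"),
  function(model, frame) {
    stopifnotFrame(frame)
    if (length(model@buffer) &&
        !identical(dim(frame), dim(model@buffer[[1]])))
      stop("frame dimensions do not match the background model")
    model@buffer <- c(model@buffer, list(frame))
    model@sumImage <- if (is.null(model@sumImage)) frame else
      model@sumImage + frame
    if (length(model@buffer) > model@window) {
      model@sumImage <- model@sumImage - model@buffer[[1]]
      model@buffer <- model@buffer[-1]
    }
    model
  })

#' @rdname accessors
#' @export
setMethod("meanImage", "BackgroundModel", function(x) {
  if (!length(x@buffer)) stop("background model has no frames yet")
  x@sumImage / length(x@buffer)
})

#' @rdname accessors
#' @export
setMethod("isWarmedUp", "BackgroundModel", function(x) {
  length(x@buffer) >= x@window
})

#' Absolute background difference of a frame
#'
#' Returns the per-pixel absolute difference between a frame and the
#' current background estimate. The absolute value makes detection
#' insensitive to polarity, so both darker and lighter objects stand out.
#'
#' @param frame numeric matrix.
#' @param model a warmed-up [BackgroundModel-class].
#' @param require.warm error if the model has not seen a full window yet
#'   (default TRUE): frames during warm-up must not produce detections.
#' @return Numeric matrix of non-negative differences.
#' @export
subtractBackground <- function(frame, model, require.warm = TRUE) {
  stopifnotFrame(frame)
  if (require.warm && !isWarmedUp(model))
    stop("background model is still warming up")
  mu <- meanImage(model)
  if (!identical(dim(frame), dim(mu)))
    stop("frame dimensions do not match the background model")
  abs(frame - mu)
}

#' Convert an image array to a grayscale intensity matrix
#'
#' Multi-channel arrays are reduced by the Rec. 601 luminance weights;
#' values in [0, 1] (as produced by PNG readers) are rescaled to [0, 255].
#'
#' @param img matrix or 3-d array.
#' @return Numeric matrix of intensities in [0, 255].
#' @export
toGray <- function(img) {
  if (length(dim(img)) == 3) {
    nch <- dim(img)[3]
    img <- if (nch >= 3) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else img[, , 1]
  }
  if (max(img) <= 1) img <- img * 255
  img
}

#' Read a directory of frame images as grayscale matrices
#'
#' Frames are read in lexicographic filename order, which matches the
#' zero-padded `frame_000001.png` naming that [writeFrames()] emits.
#'
#' @param dir directory containing PNG frames.
#' @param pattern filename filter passed to [list.files()].
#' @return List of numeric intensity matrices in [0, 255].
#' @export
readFrameDir <- function(dir, pattern = "\\.png$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no frame images found in ", dir)
  lapply(files, function(f) toGray(png::readPNG(f)))
}

#' Write frames as a zero-padded PNG sequence
#'
#' @param frames list of numeric matrices in [0, 255] (or a
#'   [SyntheticScene-class]).
#' @param dir output directory, created if needed.
#' @return Invisibly, the written file paths.
#' @export
writeFrames <- function(frames, dir) {
  if (is(frames, "SyntheticScene")) frames <- frames(frames)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_along(frames)))
  for (i in seq_along(frames))
    png::writePNG(pmin(pmax(frames[[i]] / 255, 0), 1), paths[i])
  invisible(paths)
}
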