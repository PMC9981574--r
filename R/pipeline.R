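# End-to-end orchestration: extract -> background -> subtract -> 2-means
# binarize -> connected components -> classify -> track -> behaviour.

#' Build a pipeline configuration
#'
#' Collects every tunable of the tracking pipeline with the package-wide
#' defaults. The configuration round-trips losslessly through YAML via
#' [writeConfig()] / [readConfig()].
#'
#' @param input frame source: a directory of PNG frames (or `NULL` when
#'   frames are passed to [runPipeline()] directly).
#' @param fps frames per second.
#' @param roi optional `c(x, y, w, h)` rectangular crop applied to every
#'   frame before processing.
#' @param backgroundSeconds rolling-mean window in seconds (default 20).
#' @param freezeBackground stop updating the background after warm-up
#'   instead of rolling it (default FALSE).
#' @param minArea minimum component area in pixels.
#' @param kmeansTol,kmeansMaxIter,kmeansInit threshold-clustering knobs.
#' @param classifierMethod `"rf"` or `"svm"`.
#' @param modelPath path to a classifier saved by [saveClassifier()]
#'   (ignored when a fitted model is passed to [runPipeline()]).
#' @param scoreThreshold classifier decision threshold.
#' @param lambda,maxDist,cMin,maxAge,minHits association parameters (see
#'   [associationParams()]).
#' @param windowSeconds,epsilon,intervalSeconds behaviour parameters.
#' @param outDir output directory.
#' @param seed global seed; all stochastic stages derive their streams
#'   from it.
#' @return A named list of class `daphniaPipelineConfig`.
#' @export
pipelineConfig <- function(input = NULL, fps = 15, roi = NULL,
                           backgroundSeconds = 20,
                           freezeBackground = FALSE, minArea = 4L,
                           kmeansTol = 1e-6, kmeansMaxIter = 100L,
                           kmeansInit = "minmax",
                           classifierMethod = "rf", modelPath = NULL,
                           scoreThreshold = 0.5,
                           lambda = 0.5, maxDist = NULL, cMin = 0.3,
                           maxAge = 5L, minHits = 2L,
                           windowSeconds = 20, epsilon = 0.5,
                           intervalSeconds = 20, outDir = NULL,
                           seed = 1L) {
  cfg <- list(input = input, fps = fps, roi = roi,
              backgroundSeconds = backgroundSeconds,
              freezeBackground = freezeBackground,
              minArea = as.integer(minArea), kmeansTol = kmeansTol,
              kmeansMaxIter = as.integer(kmeansMaxIter),
              kmeansInit = kmeansInit,
              classifierMethod = classifierMethod,
              modelPath = modelPath, scoreThreshold = scoreThreshold,
              lambda = lambda, maxDist = maxDist, cMin = cMin,
              maxAge = as.integer(maxAge), minHits = as.integer(minHits),
              windowSeconds = windowSeconds, epsilon = epsilon,
              intervalSeconds = intervalSeconds, outDir = outDir,
              seed = as.integer(seed))
  class(cfg) <- "daphniaPipelineConfig"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipelineConfig()] list.
#' @param path YAML file path.
#' @return `writeConfig()` returns `path` invisibly; `readConfig()` the
#'   reconstructed configuration.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' Persist / restore a fitted patch classifier
#'
#' The model is stored with its metadata (method, hyperparameters, seed,
#' feature configuration) so a run manifest fully describes a run.
#'
#' @param model a [PatchClassifier-class].
#' @param path destination file.
#' @return `saveClassifier()` returns `path` invisibly;
#'   `loadClassifier()` the restored [PatchClassifier-class].
#' @export
saveClassifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) readRDS(path)

#' Detect candidate objects in one frame
#'
#' The per-frame detection stage: absolute background difference,
#' automatic 2-means threshold, binarization and connected components.
#'
#' @param frame numeric intensity matrix.
#' @param bg a warmed-up [BackgroundModel-class].
#' @param config a [pipelineConfig()] list.
#' @param frame_index 0-based index recorded in the output.
#' @return Candidate data.frame (see [connectedComponents()]).
#' @export
detectObjects <- function(frame, bg, config = pipelineConfig(),
                          frame_index = 0L) {
  diff <- subtractBackground(frame, bg)
  thr <- kmeansThreshold(diff, init = config$kmeansInit,
                         seed = deriveSeed(config$seed, 7L),
                         max_iter = config$kmeansMaxIter,
                         tol = config$kmeansTol)
  mask <- binarize(diff, thr)
  connectedComponents(mask, min_area = config$minArea,
                      frame_index = frame_index)
}

#' Run the full tracking pipeline
#'
#' Executes frame extraction, rolling-mean background modelling,
#' background subtraction, automatic 2-means binarization, connected
#' components, animal/noise classification, SORT-style tracking and
#' behavioural summarisation. Frames recorded before the background
#' window is full produce no detections; tracking starts at warm-up
#' completion. When `config$outDir` is set, the trajectories (MOT CSV
#' and tidy CSV), the per-video behavioural summary and a run manifest
#' (configuration, seed, package version) are written there.
#'
#' @param config a [pipelineConfig()] list.
#' @param frames optional list of frames (matrices in [0, 255]) or a
#'   [SyntheticScene-class]; otherwise frames are read from
#'   `config$input`.
#' @param classifier optional fitted [PatchClassifier-class]; otherwise
#'   loaded from `config$modelPath`.
#' @return List with `trajectories`, `detections`, `summary` (from
#'   [behaviorSummary()]), `warmupFrames` (number of frames consumed by
#'   background warm-up) and `config`.
#' @export
runPipeline <- function(config = pipelineConfig(), frames = NULL,
                        classifier = NULL) {
  if (is.null(frames)) {
    if (is.null(config$input)) stop("no input frames")
    frames <- readFrameDir(config$input)
  }
  if (is(frames, "SyntheticScene")) frames <- frames(frames)
  if (!length(frames)) stop("no input frames")
  if (is.null(classifier)) {
    if (is.null(config$modelPath))
      stop("no classifier: pass one or set config$modelPath")
    classifier <- loadClassifier(config$modelPath)
  }
  if (!is.null(config$roi)) {
    r <- config$roi
    frames <- lapply(frames, function(f)
      f[(r[2] + 1):(r[2] + r[4]), (r[1] + 1):(r[1] + r[3]), drop = FALSE])
  }
  window <- round(config$fps * config$backgroundSeconds)
  if (length(frames) <= window)
    stop("video shorter than the background warm-up window (",
         window, " frames)")
  bg <- backgroundModel(window = window)
  dets <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    if (!isWarmedUp(bg)) {
      bg <- updateBackground(bg, fr)
      next
    }
    cand <- detectObjects(fr, bg, config, frame_index = t - 1L)
    if (nrow(cand))
      cand <- classifyObjects(classifier, fr, cand,
                              threshold = config$scoreThreshold)
    dets[[t]] <- cand
    if (!config$freezeBackground) bg <- updateBackground(bg, fr)
  }
  detections <- do.call(rbind, c(list(emptyDetections()),
                                 Filter(Negate(is.null), dets)))
  params <- associationParams(lambda = config$lambda,
                              maxDist = config$maxDist,
                              cMin = config$cMin, maxAge = config$maxAge,
                              minHits = config$minHits)
  size <- c(ncol(frames[[1]]), nrow(frames[[1]]))
  trajs <- trackVideo(detections[, c("frame", "x", "y", "w", "h")],
                      params, frameSize = size,
                      frameRange = c(window, length(frames) - 1L))
  summ <- behaviorSummary(trajs, fps = config$fps,
                          windowSeconds = config$windowSeconds,
                          epsilon = config$epsilon)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeMOT(trajs, file.path(config$outDir, "trajectories_mot.txt"))
    writeTidyTrajectories(trajs,
                          file.path(config$outDir, "trajectories.csv"),
                          fps = config$fps)
    utils::write.csv(summ$perTrack,
                     file.path(config$outDir, "per_track_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest <- c(unclass(config),
                  list(package = "DaphniaTrack",
                       version = as.character(
                         utils::packageVersion("DaphniaTrack")),
                       nFrames = length(frames)))
    yaml::write_yaml(manifest, file.path(config$outDir, "manifest.yaml"))
  }
  list(trajectories = trajs, detections = detections, summary = summ,
       warmupFrames = window, config = config)
}

#' Evaluate a tracking run from MOT files
#'
#' Reads ground-truth and hypothesis MOT-Challenge files and reports the
#' six standard tracking metrics. When the two files cover different
#' frame ranges a warning is issued and the intersection is evaluated.
#'
#' @param gtFile,hypFile MOT-Challenge CSV paths.
#' @param iouThreshold match gate.
#' @return One-row data.frame from [evaluateTracking()].
#' @export
evaluateRun <- function(gtFile, hypFile, iouThreshold = 0.5) {
  gt <- readMOT(gtFile); hyp <- readMOT(hypFile)
  if (nrow(gt) && nrow(hyp)) {
    rg <- range(gt$frame); rh <- range(hyp$frame)
    if (!identical(rg, rh)) {
      warning("frame ranges differ (gt ", rg[1], "-", rg[2], ", hyp ",
              rh[1], "-", rh[2], "); evaluating the intersection")
      lo <- max(rg[1], rh[1]); hi <- min(rg[2], rh[2])
      gt <- gt[gt$frame >= lo & gt$frame <= hi, , drop = FALSE]
      hyp <- hyp[hyp$frame >= lo & hyp$frame <= hi, , drop = FALSE]
    }
  }
  evaluateTracking(gt, hyp, iouThreshold)
}
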