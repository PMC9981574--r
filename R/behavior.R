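# Trajectory-level locomotory statistics: per-frame displacement,
# interval averages, stationary filtering, mobile counts and radius of
# activity.

splitTracks <- function(trajs) {
  if (!nrow(trajs)) return(list())
  split(trajs, trajs$track_id)
}

#' Per-frame displacements of a trajectory
#'
#' Euclidean distance between the centroids of consecutive observations.
#' When the tracker coasted over a gap of `g` frames, the single observed
#' displacement is either divided evenly across the `g` frame steps
#' (`gap = "split"`, keeping per-frame units comparable) or dropped
#' (`gap = "skip"`).
#'
#' @param traj data.frame with columns `frame, cx, cy` for one track.
#' @param gap `"split"` or `"skip"`.
#' @return Numeric vector of per-frame distances (empty for fewer than
#'   two observations).
#' @examples
#' tr <- data.frame(frame = 0:2, cx = c(0, 3, 3), cy = c(0, 4, 4))
#' frameDisplacements(tr)
#' @export
frameDisplacements <- function(traj, gap = c("split", "skip")) {
  gap <- match.arg(gap)
  if (nrow(traj) < 2) return(numeric(0))
  traj <- traj[order(traj$frame), , drop = FALSE]
  d <- sqrt(diff(traj$cx)^2 + diff(traj$cy)^2)
  g <- diff(traj$frame)
  if (gap == "split") {
    unlist(lapply(seq_along(d), function(i) rep(d[i] / g[i], g[i])),
           use.names = FALSE)
  } else {
    d[g == 1]
  }
}

#' Mean and standard error
#'
#' Arithmetic mean and standard error (sample standard deviation with the
#' `n - 1` denominator divided by `sqrt(n)`; zero for a single value).
#'
#' @param values numeric vector, `n >= 1`.
#' @return Named numeric vector `c(mean, se, n)`.
#' @examples
#' meanSE(c(3.26, 3.45, 2.94, 3.65))
#' @export
meanSE <- function(values) {
  if (!length(values)) stop("meanSE needs at least one value")
  n <- length(values)
  se <- if (n == 1) 0 else stats::sd(values) / sqrt(n)
  c(mean = mean(values), se = se, n = n)
}

# TRUE when the displacement sequence contains a run of at least
# `runLen` consecutive values all <= epsilon.
hasStationaryRun <- function(disp, runLen, epsilon) {
  if (!length(disp)) return(FALSE)
  r <- rle(disp <= epsilon)
  any(r$values & r$lengths >= runLen)
}

#' Remove trajectories that stay stationary for a full window
#'
#' A trajectory is removed when it contains a run of at least
#' `windowSeconds * fps` consecutive per-frame displacements, all at or
#' below `epsilon` — the immobility criterion of acute toxicity testing
#' (animals stationary for 20 s or more are excluded from locomotory
#' observations and counted as immobile).
#'
#' @param trajs trajectory data.frame (`track_id, frame, cx, cy`, ...).
#' @param fps frames per second.
#' @param windowSeconds stationary window in seconds (default 20).
#' @param epsilon displacement tolerance in pixels/frame (default 0.5,
#'   a sub-pixel jitter floor).
#' @param gap gap handling passed to [frameDisplacements()].
#' @return List with `kept` and `removed` trajectory data.frames (a
#'   partition of the input rows).
#' @export
stationaryFilter <- function(trajs, fps = 15, windowSeconds = 20,
                             epsilon = 0.5, gap = "split") {
  runLen <- round(windowSeconds * fps)
  tracks <- splitTracks(trajs)
  stat <- vapply(tracks, function(tr)
    hasStationaryRun(frameDisplacements(tr, gap), runLen, epsilon),
    logical(1))
  keepIds <- as.numeric(names(tracks))[!stat]
  list(kept = trajs[trajs$track_id %in% keepIds, , drop = FALSE],
       removed = trajs[!trajs$track_id %in% keepIds, , drop = FALSE])
}

#' Number of mobile individuals
#'
#' The count of trajectories kept by [stationaryFilter()] — the mobile
#' animals under the immobility endpoint.
#'
#' @inheritParams stationaryFilter
#' @return Integer count.
#' @export
mobileCount <- function(trajs, fps = 15, windowSeconds = 20,
                        epsilon = 0.5, gap = "split") {
  kept <- stationaryFilter(trajs, fps, windowSeconds, epsilon, gap)$kept
  length(unique(kept$track_id))
}

#' Per-interval mean moving distance
#'
#' Buckets a trajectory's per-frame displacements into consecutive
#' windows of `intervalSeconds * fps` frames (relative to the
#' trajectory's first frame) and reports the mean per window; a trailing
#' partial window is reported with its own frame count.
#'
#' @param traj one track's data.frame (`frame, cx, cy`).
#' @param fps frames per second.
#' @param intervalSeconds window length in seconds (default 20).
#' @param gap gap handling passed to [frameDisplacements()].
#' @return data.frame with columns `interval_index` (1-based),
#'   `mean_distance`, `n_frames`.
#' @export
intervalMeanDistance <- function(traj, fps = 15, intervalSeconds = 20,
                                 gap = "split") {
  disp <- frameDisplacements(traj, gap)
  if (!length(disp)) {
    return(data.frame(interval_index = integer(),
                      mean_distance = numeric(), n_frames = integer()))
  }
  winLen <- round(intervalSeconds * fps)
  idx <- ((seq_along(disp) - 1) %/% winLen) + 1
  agg <- tapply(disp, idx, mean)
  cnt <- tapply(disp, idx, length)
  data.frame(interval_index = as.integer(names(agg)),
             mean_distance = as.numeric(agg),
             n_frames = as.integer(cnt), row.names = NULL)
}

#' Radius of activity of a trajectory
#'
#' The spatial extent of an individual's path. By default the maximum
#' Euclidean distance from any visited centroid to the centroid of all
#' visited points; the `"diameter"` alternative reports half the largest
#' pairwise distance between visited points. (The endpoint is reported by
#' tracking systems without a standard definition; both interpretations
#' are provided.)
#'
#' @param traj one track's data.frame (`cx, cy`).
#' @param method `"centroid"` (default) or `"diameter"`.
#' @return Radius in pixels (0 for a stationary trajectory).
#' @export
radiusOfActivity <- function(traj, method = c("centroid", "diameter")) {
  method <- match.arg(method)
  if (!nrow(traj)) stop("trajectory has no observations")
  p <- cbind(traj$cx, traj$cy)
  if (method == "centroid") {
    ctr <- colMeans(p)
    sqrt(max(rowSums(sweep(p, 2, ctr)^2)))
  } else {
    if (nrow(p) == 1) return(0)
    max(stats::dist(p)) / 2
  }
}

#' Video-level behavioural summary
#'
#' Computes, per trajectory, the mean per-frame displacement and radius
#' of activity, then aggregates the per-trajectory means into a
#' video-level mean and standard error, and counts mobile individuals.
#'
#' @inheritParams stationaryFilter
#' @return List with `perTrack` (data.frame: `track_id,
#'   mean_displacement, n_frames, radius, stationary`), `mean`, `se`,
#'   `mobile` and `n`.
#' @export
behaviorSummary <- function(trajs, fps = 15, windowSeconds = 20,
                            epsilon = 0.5, gap = "split") {
  tracks <- splitTracks(trajs)
  if (!length(tracks)) {
    return(list(perTrack = data.frame(), mean = NA_real_, se = NA_real_,
                mobile = 0L, n = 0L))
  }
  runLen <- round(windowSeconds * fps)
  per <- do.call(rbind, lapply(tracks, function(tr) {
    disp <- frameDisplacements(tr, gap)
    data.frame(track_id = tr$track_id[1],
               mean_displacement = if (length(disp)) mean(disp) else NA,
               n_frames = nrow(tr),
               radius = radiusOfActivity(tr),
               stationary = hasStationaryRun(disp, runLen, epsilon))
  }))
  rownames(per) <- NULL
  ms <- meanSE(per$mean_displacement[!is.na(per$mean_displacement)])
  list(perTrack = per, mean = unname(ms["mean"]), se = unname(ms["se"]),
       mobile = sum(!per$stationary), n = nrow(per))
}
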