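# SORT-style online tracker: constant-velocity Kalman filtering of the
# state x = [u, v, s, r, udot, vdot, sdot] (centroid, bbox area, aspect
# ratio and their rates; the aspect ratio carries no rate), Hungarian
# association on a mixed IOU / centroid-distance similarity, and simple
# birth/death lifecycle management.

# --- Kalman filter matrices (constant velocity, dt = 1 frame) ----------
.kfF <- {
  F <- diag(7); F[1, 5] <- 1; F[2, 6] <- 1; F[3, 7] <- 1; F
}
.kfH <- {
  H <- matrix(0, 4, 7); H[1, 1] <- H[2, 2] <- H[3, 3] <- H[4, 4] <- 1; H
}
# Noise levels follow the public SORT reference convention: confident
# positions, vague areas, very vague unobserved initial velocities.
.kfR <- diag(c(1, 1, 10, 10))
.kfP0 <- diag(c(10, 10, 10, 10, 1e4, 1e4, 1e4))
.kfQ <- diag(c(1, 1, 1, 1, 0.01, 0.01, 1e-4))

bboxToZ <- function(x, y, w, h) {
  c(u = x + w / 2, v = y + h / 2, s = w * h, r = w / h)
}

zToBbox <- function(z) {
  z <- unname(z)
  s <- max(z[3], 1e-6); r <- max(z[4], 1e-6)
  w <- sqrt(s * r); h <- s / w
  c(x = z[1] - w / 2, y = z[2] - h / 2, w = w, h = h)
}

newTrackState <- function(det, id) {
  z <- bboxToZ(det$x, det$y, det$w, det$h)
  list(x = unname(c(z, 0, 0, 0)), P = .kfP0, id = id,
       hits = 1L, age = 1L, time_since_update = 0L,
       lastDet = c(det$x, det$y, det$w, det$h))
}

#' Predict a track state one frame ahead
#'
#' Constant-velocity propagation: the centroid moves by its velocity, the
#' bbox area by its rate, the aspect ratio is unchanged, and the
#' covariance is inflated by the process noise. The predicted area is
#' floored at a small positive value so a derived bounding box always
#' exists.
#'
#' @param state internal track-state list with elements `x` (7-vector)
#'   and `P` (7x7 covariance).
#' @return The state with `x` and `P` advanced one frame.
#' @export
kalmanPredict <- function(state) {
  if (state$x[7] + state$x[3] <= 0) state$x[7] <- 0
  state$x <- as.numeric(.kfF %*% state$x)
  state$x[3] <- max(state$x[3], 1e-6)
  state$P <- .kfF %*% state$P %*% t(.kfF) + .kfQ
  state
}

kalmanUpdate <- function(state, z) {
  y <- z - as.numeric(.kfH %*% state$x)
  S <- .kfH %*% state$P %*% t(.kfH) + .kfR
  K <- state$P %*% t(.kfH) %*% solve(S)
  state$x <- state$x + as.numeric(K %*% y)
  state$x[3] <- max(state$x[3], 1e-6)
  state$x[4] <- max(state$x[4], 1e-6)
  P <- (diag(7) - K %*% .kfH) %*% state$P
  state$P <- (P + t(P)) / 2
  state
}

#' Intersection over union of two boxes
#'
#' Boxes are `(x, y, w, h)` in the half-open pixel convention. Returns 0
#' when the union is empty.
#'
#' @param a,b numeric vectors `(x, y, w, h)` (names optional).
#' @return IOU in [0, 1].
#' @examples
#' boxIOU(c(0, 0, 2, 2), c(1, 0, 2, 2))   # 1/3
#' @export
boxIOU <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  iw <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
  ih <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) inter <- 0 else inter <- iw * ih
  un <- a[3] * a[4] + b[3] * b[4] - inter
  if (un <= 0) return(0)
  inter / un
}

#' Association parameters for the tracker
#'
#' The association similarity between a predicted track `i` and a
#' detection `j` is the convex combination
#' `C_ij = (1 - lambda) * max(0, (maxDist - d_ij) / maxDist)
#'        + lambda * IOU_ij`
#' of a capped, normalised centroid-distance term and the IOU. The
#' distance term is clamped at zero once `d_ij` exceeds `maxDist`, so
#' `C_ij` stays in [0, 1]. `lambda = 1` recovers IOU-only association
#' (vanilla SORT); `lambda = 0` a pure normalised-distance tracker.
#'
#' @param lambda IOU weight in [0, 1].
#' @param maxDist distance normaliser in pixels; `NULL` defers to a tenth
#'   of the frame diagonal, resolved where the frame size is known.
#' @param cMin minimum similarity for a valid match.
#' @param maxAge frames a track may coast unmatched before termination.
#' @param minHits matches required before a track's observations are
#'   emitted (with a grace period at the start of the video).
#' @return A validated named list.
#' @export
associationParams <- function(lambda = 0.5, maxDist = NULL, cMin = 0.3,
                              maxAge = 5L, minHits = 2L) {
  stopifnot(lambda >= 0, lambda <= 1, cMin >= 0, cMin <= 1,
            is.null(maxDist) || maxDist > 0, maxAge >= 0, minHits >= 1)
  list(lambda = lambda, maxDist = maxDist, cMin = cMin,
       maxAge = as.integer(maxAge), minHits = as.integer(minHits))
}

#' Mixed IOU / distance association similarity
#'
#' @param det,pred lists or one-row data.frames with `x, y, w, h` (their
#'   centroids are the bbox centres).
#' @param params an [associationParams()] list with `maxDist` resolved.
#' @return Similarity `C_ij` in [0, 1].
#' @export
associationCost <- function(det, pred, params) {
  dBox <- c(det[["x"]], det[["y"]], det[["w"]], det[["h"]])
  pBox <- c(pred[["x"]], pred[["y"]], pred[["w"]], pred[["h"]])
  d <- sqrt(sum((boxCentre(dBox[1], dBox[2], dBox[3], dBox[4]) -
                 boxCentre(pBox[1], pBox[2], pBox[3], pBox[4]))^2))
  distTerm <- max(0, (params$maxDist - d) / params$maxDist)
  (1 - params$lambda) * distTerm + params$lambda * boxIOU(dBox, pBox)
}

#' One-to-one assignment by the Hungarian algorithm
#'
#' Solves the maximum-total-similarity assignment on a rectangular
#' similarity matrix (rows: tracks, columns: detections) with the
#' Hungarian algorithm, then demotes any assigned pair whose similarity
#' falls below `cMin` to unmatched. Matches are reported in increasing
#' row order.
#'
#' @param sim numeric matrix of similarities in [0, 1].
#' @param cMin minimum similarity for a valid match.
#' @return A list with `matches` (2-column matrix of row/col indices),
#'   `unmatchedRows`, `unmatchedCols`.
#' @examples
#' associate(matrix(c(0.9, 0.2, 0.1, 0.8), 2), cMin = 0)
#' @export
associate <- function(sim, cMin = 0) {
  nr <- nrow(sim); nc <- ncol(sim)
  if (is.null(nr) || nr == 0 || nc == 0) {
    return(list(matches = matrix(integer(), ncol = 2),
                unmatchedRows = seq_len(if (is.null(nr)) 0 else nr),
                unmatchedCols = seq_len(if (is.null(nc)) 0 else nc)))
  }
  if (nr <= nc) {
    ass <- clue::solve_LSAP(sim, maximum = TRUE)
    pairs <- cbind(seq_len(nr), as.integer(ass))
  } else {
    ass <- clue::solve_LSAP(t(sim), maximum = TRUE)
    pairs <- cbind(as.integer(ass), seq_len(nc))
  }
  keep <- sim[pairs] >= cMin
  matches <- pairs[keep, , drop = FALSE]
  matches <- matches[order(matches[, 1]), , drop = FALSE]
  list(matches = matches,
       unmatchedRows = setdiff(seq_len(nr), matches[, 1]),
       unmatchedCols = setdiff(seq_len(nc), matches[, 2]))
}

trackBbox <- function(state) zToBbox(state$x[1:4])

#' Advance the tracker by one frame
#'
#' Predicts all live tracks, builds the mixed-similarity matrix against
#' the frame's detections, associates them one-to-one, Kalman-updates the
#' matched tracks with the detection measurement `[u, v, s, r]`, spawns
#' new tracks (zero initial velocity) from unmatched detections, retires
#' tracks unmatched for more than `maxAge` frames, and emits observations
#' for confirmed tracks (those with at least `minHits` matches, with a
#' grace period during the first `minHits` frames of the video).
#'
#' @param tracks list of live track states (internal representation).
#' @param detections data.frame of this frame's detections
#'   (`x, y, w, h`, optionally `frame`).
#' @param params an [associationParams()] list with `maxDist` resolved.
#' @param frame_index 0-based frame index.
#' @param nextId next track id to assign.
#' @return List with `tracks`, `emitted` (trajectory rows for this
#'   frame), and `nextId`.
#' @export
trackerStep <- function(tracks, detections, params, frame_index = 0L,
                        nextId = 1L) {
  tracks <- lapply(tracks, kalmanPredict)
  nT <- length(tracks); nD <- nrow(detections)
  sim <- matrix(0, nT, nD)
  if (nT && nD) {
    predBoxes <- lapply(tracks, trackBbox)
    for (i in seq_len(nT)) for (j in seq_len(nD)) {
      sim[i, j] <- associationCost(detections[j, ],
                                   as.list(predBoxes[[i]]), params)
    }
  }
  ass <- associate(sim, params$cMin)

  for (k in seq_len(nrow(ass$matches))) {
    i <- ass$matches[k, 1]; j <- ass$matches[k, 2]
    d <- detections[j, ]
    tracks[[i]] <- kalmanUpdate(tracks[[i]],
                                bboxToZ(d$x, d$y, d$w, d$h))
    tracks[[i]]$hits <- tracks[[i]]$hits + 1L
    tracks[[i]]$time_since_update <- 0L
    tracks[[i]]$lastDet <- c(d$x, d$y, d$w, d$h)
  }
  for (i in ass$unmatchedRows) {
    tracks[[i]]$time_since_update <- tracks[[i]]$time_since_update + 1L
  }
  for (j in ass$unmatchedCols) {
    tracks[[length(tracks) + 1]] <- newTrackState(detections[j, ], nextId)
    nextId <- nextId + 1L
  }
  for (i in seq_along(tracks)) tracks[[i]]$age <- tracks[[i]]$age + 1L

  # emitted observations carry the matched detection's box: the filter
  # state drives prediction and association, but the measurement is the
  # best estimate of where the animal actually is this frame
  emitted <- do.call(rbind, lapply(tracks, function(tr) {
    if (tr$time_since_update == 0L &&
        (tr$hits >= params$minHits || frame_index < params$minHits)) {
      bb <- tr$lastDet
      data.frame(track_id = tr$id, frame = as.integer(frame_index),
                 x = bb[1], y = bb[2], w = bb[3], h = bb[4],
                 cx = bb[1] + bb[3] / 2, cy = bb[2] + bb[4] / 2,
                 row.names = NULL)
    } else NULL
  }))
  if (is.null(emitted)) emitted <- emptyTrajectories()
  tracks <- Filter(function(tr) tr$time_since_update <= params$maxAge,
                   tracks)
  list(tracks = tracks, emitted = emitted, nextId = nextId)
}

#' Track a whole video of detections
#'
#' Applies [trackerStep()] frame by frame over the detection table and
#' returns all emitted trajectories. Track ids are never reused within a
#' video, and the result is deterministic given the inputs.
#'
#' @param detections data.frame of per-frame detections with columns
#'   `frame` (0-based), `x, y, w, h`.
#' @param params an [associationParams()] list; a `NULL` `maxDist` is
#'   resolved to a tenth of the frame diagonal via `frameSize`.
#' @param frameSize optional `c(width, height)` used to resolve
#'   `maxDist`.
#' @param frameRange optional `c(first, last)` frame indices to process;
#'   defaults to the detection table's range.
#' @return Trajectory data.frame with columns
#'   `track_id, frame, x, y, w, h, cx, cy`.
#' @export
trackVideo <- function(detections, params = associationParams(),
                       frameSize = NULL, frameRange = NULL) {
  if (is.null(params$maxDist)) {
    if (is.null(frameSize))
      stop("params$maxDist is NULL and no frameSize given to resolve it")
    params$maxDist <- 0.1 * sqrt(sum(frameSize^2))
  }
  if (is.null(frameRange)) {
    frameRange <- if (nrow(detections)) range(detections$frame) else c(0, -1)
  }
  tracks <- list(); nextId <- 1L
  out <- vector("list", 0L)
  for (f in seq(frameRange[1], length.out = max(0, diff(frameRange) + 1))) {
    dets <- detections[detections$frame == f, , drop = FALSE]
    st <- trackerStep(tracks, dets, params, frame_index = f,
                      nextId = nextId)
    tracks <- st$tracks; nextId <- st$nextId
    if (nrow(st$emitted)) out[[length(out) + 1]] <- st$emitted
  }
  res <- if (length(out)) do.call(rbind, out) else emptyTrajectories()
  res <- res[order(res$track_id, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}
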