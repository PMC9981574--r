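# Tracking evaluation: CLEAR MOT (MOTA, MOTP, ID switches) and identity
# metrics (IDP, IDR, IDF1) under an optimal whole-trajectory matching.
# Both consume tables with columns frame (0-based), id, x, y, w, h.

asBoxTable <- function(df) {
  if ("track_id" %in% names(df) && !"id" %in% names(df))
    df$id <- df$track_id
  need <- c("frame", "id", "x", "y", "w", "h")
  if (!all(need %in% names(df)))
    stop("expected columns ", paste(need, collapse = ", "))
  df
}

#' CLEAR MOT metrics
#'
#' Performs the standard per-frame matching: correspondences from the
#' previous frame are kept while their IOU stays at or above the gate,
#' remaining boxes are matched by maximum-total-IOU Hungarian assignment,
#' and a ground-truth track whose matched hypothesis id changes (compared
#' with the last hypothesis it was ever matched to) counts as an ID
#' switch. Then
#' `MOTA = 100 * (1 - (FN + FP + IDs) / #gt boxes)` and
#' `MOTP = 100 * mean IOU` over matched pairs.
#'
#' @param gt,hyp data.frames with columns `frame, id, x, y, w, h`
#'   (`track_id` is accepted as an alias for `id`).
#' @param iouThreshold match gate on IOU (default 0.5).
#' @return List with `MOTA`, `MOTP`, `IDs`, and counts `FP`, `FN`,
#'   `matches`, `nGT`. `MOTA` is `NA` for empty ground truth, `MOTP` is
#'   `NA` when nothing was matched.
#' @export
clearMOT <- function(gt, hyp, iouThreshold = 0.5) {
  gt <- asBoxTable(gt); hyp <- asBoxTable(hyp)
  if (!nrow(gt)) {
    warning("empty ground truth: MOTA undefined")
    return(list(MOTA = NA_real_, MOTP = NA_real_, IDs = 0L,
                FP = nrow(hyp), FN = 0L, matches = 0L, nGT = 0L))
  }
  framesAll <- sort(unique(c(gt$frame, hyp$frame)))
  prevMatch <- integer(0)      # names: gt id -> hyp id matched last frame
  lastMatch <- integer(0)      # names: gt id -> most recent hyp id ever
  FP <- 0L; FN <- 0L; IDs <- 0L; nMatch <- 0L; iouSum <- 0
  for (f in framesAll) {
    g <- gt[gt$frame == f, , drop = FALSE]
    h <- hyp[hyp$frame == f, , drop = FALSE]
    ng <- nrow(g); nh <- nrow(h)
    iou <- matrix(0, ng, nh)
    if (ng && nh) {
      for (i in seq_len(ng)) for (j in seq_len(nh)) {
        iou[i, j] <- boxIOU(c(g$x[i], g$y[i], g$w[i], g$h[i]),
                            c(h$x[j], h$y[j], h$w[j], h$h[j]))
      }
    }
    gLeft <- seq_len(ng); hLeft <- seq_len(nh)
    pairs <- NULL
    # keep surviving correspondences first
    for (gid in names(prevMatch)) {
      i <- match(as.integer(gid), g$id)
      j <- match(prevMatch[[gid]], h$id)
      if (!is.na(i) && !is.na(j) && iou[i, j] >= iouThreshold) {
        pairs <- rbind(pairs, c(i, j))
        gLeft <- setdiff(gLeft, i); hLeft <- setdiff(hLeft, j)
      }
    }
    # then greedy-optimal assignment of the rest
    if (length(gLeft) && length(hLeft)) {
      sub <- iou[gLeft, hLeft, drop = FALSE]
      sub[sub < iouThreshold] <- 0
      if (any(sub > 0)) {
        ass <- associate(sub, cMin = iouThreshold)
        if (nrow(ass$matches)) {
          pairs <- rbind(pairs, cbind(gLeft[ass$matches[, 1]],
                                      hLeft[ass$matches[, 2]]))
        }
      }
    }
    curMatch <- integer(0)
    if (!is.null(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        gid <- as.character(g$id[i]); hid <- h$id[j]
        last <- if (gid %in% names(lastMatch)) lastMatch[[gid]] else NA
        if (!is.na(last) && last != hid) IDs <- IDs + 1L
        lastMatch[[gid]] <- hid
        curMatch[[gid]] <- hid
        nMatch <- nMatch + 1L
        iouSum <- iouSum + iou[i, j]
      }
      FN <- FN + (ng - nrow(pairs))
      FP <- FP + (nh - nrow(pairs))
    } else {
      FN <- FN + ng
      FP <- FP + nh
    }
    prevMatch <- curMatch
  }
  nGT <- nrow(gt)
  list(MOTA = 100 * (1 - (FN + FP + IDs) / nGT),
       MOTP = if (nMatch) 100 * iouSum / nMatch else NA_real_,
       IDs = IDs, FP = FP, FN = FN, matches = nMatch, nGT = nGT)
}

#' Identity metrics (IDP, IDR, IDF1)
#'
#' Matches whole ground-truth trajectories to whole hypothesis
#' trajectories one-to-one so as to minimise the total number of identity
#' errors, using a Hungarian assignment on an
#' `(n_gt + n_hyp)`-square cost matrix with per-trajectory dummy
#' partners (the standard identity-measure construction). From the
#' optimal matching, `IDTP` frames agree, and
#' `IDP = 100 * IDTP / (IDTP + IDFP)`,
#' `IDR = 100 * IDTP / (IDTP + IDFN)`,
#' `IDF1 = 100 * 2 IDTP / (2 IDTP + IDFP + IDFN)`.
#'
#' @inheritParams clearMOT
#' @return List with `IDP`, `IDR`, `IDF1` and counts `IDTP`, `IDFP`,
#'   `IDFN`.
#' @export
idMetrics <- function(gt, hyp, iouThreshold = 0.5) {
  gt <- asBoxTable(gt); hyp <- asBoxTable(hyp)
  if (!nrow(gt)) {
    warning("empty ground truth: identity metrics undefined")
    return(list(IDP = NA_real_, IDR = NA_real_, IDF1 = NA_real_,
                IDTP = 0L, IDFP = nrow(hyp), IDFN = 0L))
  }
  gids <- sort(unique(gt$id)); hids <- sort(unique(hyp$id))
  ng <- length(gids); nh <- length(hids)
  lenG <- vapply(gids, function(i) sum(gt$id == i), numeric(1))
  lenH <- vapply(hids, function(j) sum(hyp$id == j), numeric(1))
  overlap <- matrix(0, ng, nh)
  for (gi in seq_len(ng)) {
    g <- gt[gt$id == gids[gi], , drop = FALSE]
    for (hj in seq_len(nh)) {
      h <- hyp[hyp$id == hids[hj], , drop = FALSE]
      common <- intersect(g$frame, h$frame)
      for (f in common) {
        i <- match(f, g$frame); j <- match(f, h$frame)
        if (boxIOU(c(g$x[i], g$y[i], g$w[i], g$h[i]),
                   c(h$x[j], h$y[j], h$w[j], h$h[j])) >= iouThreshold)
          overlap[gi, hj] <- overlap[gi, hj] + 1
      }
    }
  }
  n <- ng + nh
  BIG <- sum(lenG) + sum(lenH) + 1
  cost <- matrix(BIG, n, n)
  for (gi in seq_len(ng)) for (hj in seq_len(nh))
    cost[gi, hj] <- lenG[gi] + lenH[hj] - 2 * overlap[gi, hj]
  for (gi in seq_len(ng)) cost[gi, nh + gi] <- lenG[gi]
  for (hj in seq_len(nh)) cost[ng + hj, hj] <- lenH[hj]
  cost[(ng + 1):n, (nh + 1):n] <- 0
  ass <- clue::solve_LSAP(cost)
  total <- sum(cost[cbind(seq_len(n), as.integer(ass))])
  IDTP <- (sum(lenG) + sum(lenH) - total) / 2
  IDFN <- sum(lenG) - IDTP
  IDFP <- sum(lenH) - IDTP
  list(IDP = 100 * IDTP / (IDTP + IDFP),
       IDR = 100 * IDTP / (IDTP + IDFN),
       IDF1 = 100 * 2 * IDTP / (2 * IDTP + IDFP + IDFN),
       IDTP = IDTP, IDFP = IDFP, IDFN = IDFN)
}

#' Full tracking evaluation report
#'
#' Combines [clearMOT()] and [idMetrics()] into the standard six-column
#' report (IDF1, IDP, IDR, IDs, MOTA, MOTP, all in percent except the
#' switch count) plus the supporting counts.
#'
#' @inheritParams clearMOT
#' @return A one-row data.frame with columns
#'   `IDF1, IDP, IDR, IDs, MOTA, MOTP, FP, FN, matches, IDTP, IDFP, IDFN`.
#' @examples
#' gt <- data.frame(frame = 0:4, id = 1, x = 0:4, y = 0, w = 5, h = 5)
#' evaluateTracking(gt, gt)
#' @export
evaluateTracking <- function(gt, hyp, iouThreshold = 0.5) {
  cm <- clearMOT(gt, hyp, iouThreshold)
  im <- idMetrics(gt, hyp, iouThreshold)
  data.frame(IDF1 = im$IDF1, IDP = im$IDP, IDR = im$IDR, IDs = cm$IDs,
             MOTA = cm$MOTA, MOTP = cm$MOTP, FP = cm$FP, FN = cm$FN,
             matches = cm$matches, IDTP = im$IDTP, IDFP = im$IDFP,
             IDFN = im$IDFN)
}
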