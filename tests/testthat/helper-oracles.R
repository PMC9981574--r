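# Independent brute-force oracles. These deliberately share no code with
# the implementation: exhaustive scans, explicit flood fill, permutation
# enumeration.

# Optimal 1-D 2-means by exhaustive scan over all cut points in sorted
# order, minimizing within-cluster SSE.
oracleKmeans1d <- function(values) {
  v <- sort(as.numeric(values))
  n <- length(v)
  best <- NULL; bestSSE <- Inf
  for (k in 1:(n - 1)) {
    lo <- v[1:k]; hi <- v[(k + 1):n]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (sse < bestSSE) {
      bestSSE <- sse
      best <- list(mu1 = mean(lo), mu2 = mean(hi),
                   threshold = (mean(lo) + mean(hi)) / 2)
    }
  }
  best
}

# Maximum-total-similarity one-to-one assignment by recursive enumeration
# of all injective row -> column maps. Returns the best total.
oracleAssignTotal <- function(sim) {
  nr <- nrow(sim); nc <- ncol(sim)
  if (nr == 0 || nc == 0) return(0)
  if (nr > nc) return(oracleAssignTotal(t(sim)))
  rec <- function(row, used) {
    if (row > nr) return(0)
    best <- rec(row + 1, used)            # row left unmatched
    for (j in seq_len(nc)) {
      if (!used[j]) {
        used[j] <- TRUE
        best <- max(best, sim[row, j] + rec(row + 1, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1, rep(FALSE, nc))
}

# 8-connected component labelling by explicit stack-based flood fill.
oracleFloodFill <- function(mask, min_area = 1L) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  comps <- list()
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    px <- NULL
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      px <- rbind(px, p)
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if ((dr != 0 || dc != 0) && r >= 1 && r <= h && c >= 1 &&
            c <= w && mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
    if (nrow(px) >= min_area) {
      x <- px[, 2] - 1; y <- px[, 1] - 1
      comps[[length(comps) + 1]] <-
        data.frame(x = min(x), y = min(y), w = diff(range(x)) + 1,
                   h = diff(range(y)) + 1, cx = mean(x), cy = mean(y),
                   area = nrow(px))
    }
  }
  if (!length(comps)) {
    return(data.frame(x = numeric(), y = numeric(), w = numeric(),
                      h = numeric(), cx = numeric(), cy = numeric(),
                      area = numeric()))
  }
  out <- do.call(rbind, comps)
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Identity-metric oracle: maximum total per-frame overlap over all
# injective gt-trajectory -> hyp-trajectory pairings, enumerated
# recursively. Overlap counting is written independently of the package.
oracleIdTP <- function(gt, hyp, iouThreshold = 0.5) {
  iou1 <- function(a, b) {
    ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    u <- a[3] * a[4] + b[3] * b[4] - inter
    if (u <= 0) 0 else inter / u
  }
  gids <- unique(gt$id); hids <- unique(hyp$id)
  ov <- matrix(0, length(gids), length(hids))
  for (gi in seq_along(gids)) for (hj in seq_along(hids)) {
    g <- gt[gt$id == gids[gi], ]; h <- hyp[hyp$id == hids[hj], ]
    for (f in intersect(g$frame, h$frame)) {
      a <- unlist(g[g$frame == f, c("x", "y", "w", "h")])
      b <- unlist(h[h$frame == f, c("x", "y", "w", "h")])
      if (iou1(a, b) >= iouThreshold) ov[gi, hj] <- ov[gi, hj] + 1
    }
  }
  rec <- function(gi, used) {
    if (gi > length(gids)) return(0)
    best <- rec(gi + 1, used)
    for (hj in seq_along(hids)) {
      if (!used[hj]) {
        used[hj] <- TRUE
        best <- max(best, ov[gi, hj] + rec(gi + 1, used))
        used[hj] <- FALSE
      }
    }
    best
  }
  rec(1, rep(FALSE, length(hids)))
}
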