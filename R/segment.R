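#' Automatic threshold selection by 1-D 2-means clustering
#'
#' Runs Lloyd's algorithm with k = 2 on the pixel values of a difference
#' image until the assignments stabilise, then returns the two cluster
#' means and their midpoint as the binarization threshold. By default the
#' means are initialised at the minimum and maximum pixel value, which is
#' deterministic and, for bimodal difference images, converges to the
#' optimal 1-D two-cluster split; a seeded random initialisation is
#' available for comparison.
#'
#' @param values numeric vector or matrix of pixel values.
#' @param init `"minmax"` (default, deterministic) or `"random"`.
#' @param seed seed used only when `init = "random"`.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the change of the means.
#' @return A list with elements `mu1`, `mu2` (cluster means, `mu1 <= mu2`),
#'   `threshold = (mu1 + mu2) / 2`, `n_iter`, and `degenerate` (TRUE when
#'   all pixels are identical, in which case the threshold equals that
#'   value and [binarize()] yields an empty mask).
#' @examples
#' kmeansThreshold(c(10, 12, 14, 200, 202, 204))
#' @export
kmeansThreshold <- function(values, init = c("minmax", "random"),
                            seed = 1L, max_iter = 100L, tol = 1e-6) {
  init <- match.arg(init)
  v <- as.numeric(values)
  if (!length(v)) stop("at least one pixel value is required")
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    return(list(mu1 = lo, mu2 = hi, threshold = lo, n_iter = 0L,
                degenerate = TRUE))
  }
  if (init == "minmax") {
    mu <- c(lo, hi)
  } else {
    set.seed(seed)
    mu <- sort(sample(unique(v), 2L))
  }
  assign0 <- NULL
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    cut <- mean(mu)
    inHigh <- v > cut
    if (!any(inHigh) || all(inHigh)) break
    muNew <- c(mean(v[!inHigh]), mean(v[inHigh]))
    same <- !is.null(assign0) && identical(inHigh, assign0)
    assign0 <- inHigh
    conv <- max(abs(muNew - mu)) < tol
    mu <- muNew
    if (same || conv || n_iter >= max_iter) break
  }
  mu <- sort(mu)
  list(mu1 = mu[1], mu2 = mu[2], threshold = mean(mu), n_iter = n_iter,
       degenerate = FALSE)
}

#' Binarize a difference image at a threshold
#'
#' @param diff numeric matrix (typically from [subtractBackground()]).
#' @param threshold finite numeric cutoff; pixels strictly above it become
#'   foreground. Passing the result of [kmeansThreshold()] directly is
#'   also supported (a degenerate threshold yields an all-false mask).
#' @return Logical matrix of the same dimensions.
#' @export
binarize <- function(diff, threshold) {
  if (is.list(threshold)) {
    if (isTRUE(threshold$degenerate))
      return(matrix(FALSE, nrow(diff), ncol(diff)))
    threshold <- threshold$threshold
  }
  if (!is.finite(threshold)) stop("threshold must be finite")
  diff > threshold
}

#' Extract candidate objects as 8-connected components
#'
#' Labels the foreground of a binary mask with 8-connectivity (diagonal
#' neighbours join) using a union-find pass over the foreground pixels,
#' discards components smaller than `min_area`, and reports each
#' remaining component with its tight bounding box, mass-centre centroid
#' and pixel area, ordered by bounding-box `y` then `x`.
#'
#' Coordinates follow the package-wide convention: 0-based, `x` along
#' columns, `y` along rows, boxes half-open.
#'
#' @param mask logical matrix.
#' @param min_area minimum component area in pixels (default 4, enough to
#'   suppress isolated sensor-noise pixels).
#' @param frame_index frame index recorded in the output (0-based).
#' @return A data.frame with columns
#'   `frame, x, y, w, h, cx, cy, area`.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:3, 2:3] <- TRUE
#' connectedComponents(m, min_area = 1)
#' @export
connectedComponents <- function(mask, min_area = 4L, frame_index = 0L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  empty <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      w = numeric(), h = numeric(), cx = numeric(),
                      cy = numeric(), area = numeric())
  idx <- which(mask)
  if (!length(idx)) return(empty)
  h <- nrow(mask); w <- ncol(mask)
  pos <- integer(h * w); pos[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  # raster scan: union each fg pixel with already-visited 8-neighbours
  # (left, up-left, up, up-right in column-major visiting order).
  for (k in seq_along(idx)) {
    r <- rows[k]; cc <- cols[k]
    for (d in list(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(1L, -1L))) {
      rn <- r + d[1]; cn <- cc + d[2]
      if (rn >= 1L && rn <= h && cn >= 1L && cn <= w) {
        kn <- pos[(cn - 1L) * h + rn]
        if (kn > 0L && kn < k) {
          ra <- find(k); rb <- find(kn)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
  }
  root <- vapply(seq_along(idx), find, integer(1))
  comp <- split(seq_along(idx), root)
  res <- do.call(rbind, lapply(comp, function(kk) {
    if (length(kk) < min_area) return(NULL)
    r <- rows[kk] - 1L; cc <- cols[kk] - 1L   # 0-based coords
    c(x = min(cc), y = min(r), w = max(cc) - min(cc) + 1L,
      h = max(r) - min(r) + 1L, cx = mean(cc), cy = mean(r),
      area = length(kk))
  }))
  if (is.null(res)) return(empty)
  res <- as.data.frame(res)
  res <- res[order(res$y, res$x), , drop = FALSE]
  rownames(res) <- NULL
  cbind(frame = as.integer(frame_index), res)
}
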