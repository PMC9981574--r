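#' Construct synthetic-scene parameters
#'
#' Builds a validated [SceneParams-class]. The defaults emulate a desk-scale
#' version of a backlit flow-cell recording: dark elliptical animals
#' (roughly 10 px long in a 320x240 px frame, preserving the animal-size to
#' frame-width ratio of high-resolution flow-cell imagery) swimming by a
#' persistent random walk at about one pixel per frame, over a light
#' background with static droplet and slowly drifting sediment noise plus
#' additive sensor noise.
#'
#' @param width,height frame size in pixels.
#' @param nFrames number of frames.
#' @param fps frames per second.
#' @param nDaphnia number of swimming animals.
#' @param nNoiseStatic number of static droplet-like objects.
#' @param nNoiseDrift number of drifting sediment-like objects.
#' @param blobAxisRange range the two ellipse semi-axes are drawn from
#'   (pixels); the larger of the two draws becomes the major axis.
#' @param speedSigma sd of the velocity innovation (pixels/frame).
#' @param velocityPersistence velocity autocorrelation in [0, 1].
#' @param bgLevel,fgLevel background/animal intensity in [0, 255].
#' @param pixelNoiseSigma sd of additive Gaussian pixel noise.
#' @param seed integer seed; fully determines the scene.
#' @return A [SceneParams-class] object.
#' @examples
#' p <- sceneParams(nFrames = 30, nDaphnia = 2, seed = 7)
#' scene <- generateVideo(p)
#' scene
#' @export
sceneParams <- function(width = 320, height = 240, nFrames = 450,
                        fps = 15, nDaphnia = 5, nNoiseStatic = 3,
                        nNoiseDrift = 2, blobAxisRange = c(2.5, 6),
                        speedSigma = 0.45, velocityPersistence = 0.9,
                        bgLevel = 200, fgLevel = 60,
                        pixelNoiseSigma = 2, seed = 1L) {
  new("SceneParams",
      width = as.integer(width), height = as.integer(height),
      nFrames = as.integer(nFrames), fps = as.numeric(fps),
      nDaphnia = as.integer(nDaphnia),
      nNoiseStatic = as.integer(nNoiseStatic),
      nNoiseDrift = as.integer(nNoiseDrift),
      blobAxisRange = as.numeric(blobAxisRange),
      speedSigma = as.numeric(speedSigma),
      velocityPersistence = as.numeric(velocityPersistence),
      bgLevel = as.numeric(bgLevel), fgLevel = as.numeric(fgLevel),
      pixelNoiseSigma = as.numeric(pixelNoiseSigma),
      seed = as.integer(seed))
}

# Paint a filled rotated ellipse into `frame`, returning the modified
# frame plus the tight bounding box and whether anything was drawn.
# Pixel (row r, col c) has continuous coordinates x = c - 1, y = r - 1.
paintEllipse <- function(frame, cx, cy, a, b, theta, level) {
  h <- nrow(frame); w <- ncol(frame)
  r0 <- max(1L, floor(cy - a) + 1L); r1 <- min(h, ceiling(cy + a) + 1L)
  c0 <- max(1L, floor(cx - a) + 1L); c1 <- min(w, ceiling(cx + a) + 1L)
  if (r0 > r1 || c0 > c1)
    return(list(frame = frame, any = FALSE))
  xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
  dx <- outer(ys * 0, xs - cx, FUN = "+")       # (len ys) x (len xs)
  dy <- outer(ys - cy, xs * 0, FUN = "+")
  ct <- cos(theta); st <- sin(theta)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  inside <- u * u + v * v <= 1
  if (!any(inside)) return(list(frame = frame, any = FALSE))
  sub <- frame[r0:r1, c0:c1, drop = FALSE]
  sub[inside] <- level
  frame[r0:r1, c0:c1] <- sub
  rows <- range(which(rowSums(inside) > 0)); cols <- range(which(colSums(inside) > 0))
  bbox <- c(x = xs[cols[1]], y = ys[rows[1]],
            w = cols[2] - cols[1] + 1, h = rows[2] - rows[1] + 1)
  list(frame = frame, any = TRUE, bbox = bbox)
}

# Reflect a coordinate (and its velocity sign) into [lo, hi].
reflect1 <- function(p, v, lo, hi) {
  for (i in 1:4) {
    if (p < lo) { p <- 2 * lo - p; v <- -v }
    else if (p > hi) { p <- 2 * hi - p; v <- -v }
    else break
  }
  c(p, v)
}

#' Generate a synthetic grayscale video with ground truth
#'
#' Renders `nFrames` frames containing dark elliptical animals moving by a
#' persistent random walk (velocity update
#' `v <- persistence * v + noise`, reflective boundary handling), static
#' droplet-like noise blobs, slowly drifting speckled sediment blobs and
#' additive Gaussian pixel noise. The ground truth covers every animal in
#' every frame; noise objects are excluded.
#'
#' @param params a [SceneParams-class].
#' @return A [SyntheticScene-class] whose `frames` are numeric matrices in
#'   [0, 255] and whose `groundTruth` table has columns
#'   `frame, id, x, y, w, h, cx, cy` (0-based frames and boxes).
#' @examples
#' scene <- generateVideo(sceneParams(nFrames = 10, nDaphnia = 3,
#'                                    nNoiseStatic = 0, nNoiseDrift = 0,
#'                                    seed = 42))
#' table(groundTruth(scene)$frame)
#' @export
generateVideo <- function(params) {
  validObject(params)
  set.seed(params@seed)
  w <- params@width; h <- params@height
  nd <- params@nDaphnia

  # Animal states: position, velocity, semi-axes, heading.
  ax <- matrix(stats::runif(2 * max(nd, 1), params@blobAxisRange[1],
                            params@blobAxisRange[2]), ncol = 2)
  major <- pmax(ax[, 1], ax[, 2]); minor <- pmin(ax[, 1], ax[, 2])
  margin <- major + 1
  px <- stats::runif(max(nd, 1), margin, w - 1 - margin)
  py <- stats::runif(max(nd, 1), margin, h - 1 - margin)
  vx <- stats::rnorm(max(nd, 1), 0, params@speedSigma)
  vy <- stats::rnorm(max(nd, 1), 0, params@speedSigma)
  theta <- stats::runif(max(nd, 1), 0, pi)

  # Static droplets: fixed circles of intermediate darkness.
  ns <- params@nNoiseStatic
  dropX <- stats::runif(max(ns, 1), 5, w - 6)
  dropY <- stats::runif(max(ns, 1), 5, h - 6)
  dropR <- stats::runif(max(ns, 1), 1.5, 3)
  dropLev <- params@bgLevel +
    stats::runif(max(ns, 1), 0.3, 0.7) * (params@fgLevel - params@bgLevel)

  # Drifting sediment: speckle clusters with a slow constant drift.
  nf <- params@nNoiseDrift
  sedX <- stats::runif(max(nf, 1), 8, w - 9)
  sedY <- stats::runif(max(nf, 1), 8, h - 9)
  sedAng <- stats::runif(max(nf, 1), 0, 2 * pi)
  sedSpd <- stats::runif(max(nf, 1), 0.05, 0.2)
  sedVX <- cos(sedAng) * sedSpd; sedVY <- sin(sedAng) * sedSpd
  sedOff <- lapply(seq_len(max(nf, 1)), function(i) {
    k <- sample(6:14, 1)
    cbind(dx = stats::rnorm(k, 0, 2), dy = stats::rnorm(k, 0, 2),
          lev = params@fgLevel + stats::rnorm(k, 0, 15))
  })

  framesOut <- vector("list", params@nFrames)
  gt <- vector("list", params@nFrames)

  for (t in seq_len(params@nFrames)) {
    fr <- matrix(params@bgLevel, nrow = h, ncol = w)

    if (ns > 0) for (i in seq_len(ns)) {
      fr <- paintEllipse(fr, dropX[i], dropY[i], dropR[i], dropR[i],
                         0, dropLev[i])$frame
    }
    if (nf > 0) for (i in seq_len(nf)) {
      sedX[i] <- sedX[i] + sedVX[i]; sedY[i] <- sedY[i] + sedVY[i]
      rx <- reflect1(sedX[i], sedVX[i], 4, w - 5)
      ry <- reflect1(sedY[i], sedVY[i], 4, h - 5)
      sedX[i] <- rx[1]; sedVX[i] <- rx[2]
      sedY[i] <- ry[1]; sedVY[i] <- ry[2]
      off <- sedOff[[i]]
      cc <- round(sedX[i] + off[, "dx"]); rr <- round(sedY[i] + off[, "dy"])
      ok <- cc >= 0 & cc < w & rr >= 0 & rr < h
      fr[cbind(rr[ok] + 1, cc[ok] + 1)] <-
        pmin(255, pmax(0, off[ok, "lev"]))
    }

    recs <- NULL
    if (nd > 0) {
      for (i in seq_len(nd)) {
        vx[i] <- params@velocityPersistence * vx[i] +
          stats::rnorm(1, 0, params@speedSigma)
        vy[i] <- params@velocityPersistence * vy[i] +
          stats::rnorm(1, 0, params@speedSigma)
        px[i] <- px[i] + vx[i]; py[i] <- py[i] + vy[i]
      }
      # animals are rigid bodies: resolve pairwise overlap by elastic
      # contact (separate along the line of centres, exchange the normal
      # velocity components when approaching)
      if (nd > 1) for (i in 1:(nd - 1)) for (j in (i + 1):nd) {
        rr <- major[i] + major[j] + 1
        dx <- px[j] - px[i]; dy <- py[j] - py[i]
        d <- sqrt(dx^2 + dy^2)
        if (d < rr) {
          n <- if (d > 1e-9) c(dx, dy) / d else c(1, 0)
          push <- (rr - d) / 2
          px[i] <- px[i] - n[1] * push; py[i] <- py[i] - n[2] * push
          px[j] <- px[j] + n[1] * push; py[j] <- py[j] + n[2] * push
          vin <- vx[i] * n[1] + vy[i] * n[2]
          vjn <- vx[j] * n[1] + vy[j] * n[2]
          if (vjn - vin < 0) {          # approaching: elastic exchange
            vx[i] <- vx[i] + (vjn - vin) * n[1]
            vy[i] <- vy[i] + (vjn - vin) * n[2]
            vx[j] <- vx[j] + (vin - vjn) * n[1]
            vy[j] <- vy[j] + (vin - vjn) * n[2]
          }
        }
      }
      for (i in seq_len(nd)) {
        rx <- reflect1(px[i], vx[i], margin[i], w - 1 - margin[i])
        ry <- reflect1(py[i], vy[i], margin[i], h - 1 - margin[i])
        px[i] <- rx[1]; vx[i] <- rx[2]; py[i] <- ry[1]; vy[i] <- ry[2]
        spd <- sqrt(vx[i]^2 + vy[i]^2)
        if (spd > 0.2) theta[i] <- atan2(vy[i], vx[i])
        pe <- paintEllipse(fr, px[i], py[i], major[i], minor[i],
                           theta[i], params@fgLevel)
        fr <- pe$frame
        if (pe$any)
          recs <- rbind(recs, c(t - 1, i, pe$bbox, px[i], py[i]))
      }
    }
    if (params@pixelNoiseSigma > 0) {
      fr <- fr + matrix(stats::rnorm(h * w, 0, params@pixelNoiseSigma),
                        nrow = h)
      fr <- pmin(pmax(fr, 0), 255)     # arg order keeps the dim attribute
    }
    framesOut[[t]] <- fr
    gt[[t]] <- recs
  }

  gtAll <- do.call(rbind, gt)
  gtDf <- if (is.null(gtAll)) {
    data.frame(frame = integer(), id = integer(), x = numeric(),
               y = numeric(), w = numeric(), h = numeric(),
               cx = numeric(), cy = numeric())
  } else {
    data.frame(frame = as.integer(gtAll[, 1]), id = as.integer(gtAll[, 2]),
               x = gtAll[, 3], y = gtAll[, 4], w = gtAll[, 5],
               h = gtAll[, 6], cx = gtAll[, 7], cy = gtAll[, 8])
  }
  rownames(gtDf) <- NULL
  new("SyntheticScene", frames = framesOut, groundTruth = gtDf,
      params = params)
}

#' Generate a labelled patch database for classifier training
#'
#' Synthesizes `nPerClass` animal-class patches (tight crops of rendered
#' dark ellipses at random orientation and size) and `nPerClass`
#' noise-class patches (a rotating mix of droplet crops, sediment speckle
#' clusters and sparse sensor-noise speckle), each resized to 8x8 with
#' intensities in [0, 1], mimicking what [extractPatch()] produces from a
#' live frame. This stands in for a manually annotated object database.
#'
#' @param params a [SceneParams-class]; blob geometry and intensity levels
#'   are taken from it, and its seed (offset to a dedicated stream)
#'   determines the draws.
#' @param nPerClass patches per class (>= 1).
#' @return A list with elements `patches` (list of 8x8 matrices in [0, 1])
#'   and `label` (factor with levels `daphnia`, `noise`).
#' @examples
#' db <- generatePatchDB(sceneParams(seed = 3), nPerClass = 10)
#' table(db$label)
#' @export
generatePatchDB <- function(params, nPerClass) {
  validObject(params)
  if (nPerClass < 1) stop("nPerClass must be >= 1")
  set.seed(deriveSeed(params@seed, 101L))
  bg <- params@bgLevel; fg <- params@fgLevel
  canvas <- function() matrix(bg, 24, 24)
  # sensor noise is applied after painting, exactly as in the rendered
  # video, so training patches match what extractPatch() sees live
  cropResize <- function(fr, bbox) {
    fr <- fr + matrix(stats::rnorm(24 * 24, 0, params@pixelNoiseSigma),
                      24, 24)
    fr <- pmin(pmax(fr, 0), 255)
    patch <- fr[(bbox["y"] + 1):(bbox["y"] + bbox["h"]),
                (bbox["x"] + 1):(bbox["x"] + bbox["w"]), drop = FALSE]
    resizeArea(patch, 8L, 8L) / 255
  }
  daphnia <- lapply(seq_len(nPerClass), function(i) {
    axes <- stats::runif(2, params@blobAxisRange[1], params@blobAxisRange[2])
    pe <- paintEllipse(canvas(), 11.5 + stats::runif(1, -1, 1),
                       11.5 + stats::runif(1, -1, 1),
                       max(axes), min(axes), stats::runif(1, 0, pi),
                       fg)
    cropResize(pe$frame, pe$bbox)
  })
  noise <- lapply(seq_len(nPerClass), function(i) {
    kind <- (i - 1) %% 3
    fr <- canvas()
    if (kind == 0) {                       # droplet
      r <- stats::runif(1, 1.5, 3)
      lev <- bg + stats::runif(1, 0.3, 0.7) * (fg - bg)
      pe <- paintEllipse(fr, 11.5, 11.5, r, r, 0, lev)
      cropResize(pe$frame, pe$bbox)
    } else if (kind == 1) {                # sediment speckle cluster
      k <- sample(6:14, 1)
      cc <- round(11.5 + stats::rnorm(k, 0, 2))
      rr <- round(11.5 + stats::rnorm(k, 0, 2))
      ok <- cc >= 0 & cc < 24 & rr >= 0 & rr < 24
      fr[cbind(rr[ok] + 1, cc[ok] + 1)] <-
        pmin(255, pmax(0, fg + stats::rnorm(sum(ok), 0, 15)))
      bbox <- c(x = min(cc[ok]), y = min(rr[ok]),
                w = diff(range(cc[ok])) + 1, h = diff(range(rr[ok])) + 1)
      cropResize(fr, bbox)
    } else {                               # sparse sensor speckle
      k <- sample(3:6, 1)
      cc <- sample(8:15, k, replace = TRUE)
      rr <- sample(8:15, k, replace = TRUE)
      fr[cbind(rr + 1, cc + 1)] <- bg - stats::runif(k, 10, 40)
      bbox <- c(x = min(cc), y = min(rr),
                w = diff(range(cc)) + 1, h = diff(range(rr)) + 1)
      bbox["w"] <- max(bbox["w"], 2); bbox["h"] <- max(bbox["h"], 2)
      cropResize(fr, bbox)
    }
  })
  list(patches = c(daphnia, noise),
       label = factor(rep(c("daphnia", "noise"), each = nPerClass),
                      levels = c("daphnia", "noise")))
}
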