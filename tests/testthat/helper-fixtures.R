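# Shared fixture builders.

# Small quiet scene for fast end-to-end tests.
smallScene <- function(seed = 1, nFrames = 60, nDaphnia = 3,
                       noise = FALSE, width = 160, height = 120) {
  # faster-than-default animals: short per-pixel dwell keeps the short
  # background windows used in tests free of ghost residue
  sceneParams(width = width, height = height, nFrames = nFrames,
              nDaphnia = nDaphnia, speedSigma = 1.2,
              nNoiseStatic = if (noise) 2L else 0L,
              nNoiseDrift = if (noise) 1L else 0L,
              pixelNoiseSigma = if (noise) 2 else 0,
              seed = seed)
}

# Straight-line trajectory table (one track).
lineTraj <- function(id = 1L, n = 10, x0 = 0, y0 = 0, vx = 1, vy = 0,
                     w = 5, h = 5, frame0 = 0L) {
  f <- frame0 + seq_len(n) - 1L
  data.frame(frame = f, id = id, x = x0 + vx * (f - frame0),
             y = y0 + vy * (f - frame0), w = w, h = h,
             cx = x0 + vx * (f - frame0) + w / 2,
             cy = y0 + vy * (f - frame0) + h / 2)
}

# Train a small classifier once per session for pipeline tests.
sharedClassifier <- local({
  cache <- NULL
  function(params = sceneParams(seed = 99)) {
    if (is.null(cache)) {
      db <- generatePatchDB(params, nPerClass = 120)
      cache <<- trainClassifier(db, method = "rf", seed = 99)
    }
    cache
  }
})

# Bimodal pixel populations with genuine two-cluster structure, for
# threshold-oracle comparisons.
randomBimodal <- function(n = 400) {
  gap <- stats::runif(1, 40, 150)
  m1 <- stats::runif(1, 0, 50)
  s1 <- stats::runif(1, 1, 8); s2 <- stats::runif(1, 1, 8)
  n1 <- sample(seq(50, n - 50), 1)
  c(stats::rnorm(n1, m1, s1), stats::rnorm(n - n1, m1 + gap, s2))
}
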