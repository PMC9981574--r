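# Internal helpers shared across modules.

# Derive a stream-specific seed from a global one, staying inside the
# 32-bit integer range R requires of set.seed().
deriveSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}

# Bounding boxes use the 0-based half-open convention throughout:
# (x, y) is the top-left corner, the box covers [x, x+w) x [y, y+h).
boxCentre <- function(x, y, w, h) c(x + w / 2, y + h / 2)

stopifnotFrame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("a frame must be a numeric matrix", call. = FALSE)
}

# Column template for detection / trajectory tables.
emptyDetections <- function() {
  data.frame(frame = integer(), x = numeric(), y = numeric(),
             w = numeric(), h = numeric(), cx = numeric(), cy = numeric(),
             area = numeric(), label = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

emptyTrajectories <- function() {
  data.frame(track_id = integer(), frame = integer(), x = numeric(),
             y = numeric(), w = numeric(), h = numeric(),
             cx = numeric(), cy = numeric(), stringsAsFactors = FALSE)
}

# Format a numeric for CSV output: plain decimal notation, no trailing
# zeros, at most 6 decimal places.
fmtNum <- function(v) {
  out <- sprintf("%.6f", v)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}
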