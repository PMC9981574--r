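# MOT-Challenge CSV I/O. File dialect:
#   frame,id,bb_left,bb_top,bb_width,bb_height,conf,x,y,z
# with frame and id 1-based in the file and the trailing world
# coordinates set to -1. Internally frames are 0-based; the conversion
# adds/subtracts 1 on the frame column only (ids are already 1-based).

#' Write records in MOT-Challenge CSV format
#'
#' @param records data.frame with columns `frame` (0-based), `id`,
#'   `x, y, w, h`; an optional `conf` column (default 1, the ground-truth
#'   convention).
#' @param path destination file.
#' @return Invisibly, `path`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeMOT(data.frame(frame = 0, id = 1, x = 10, y = 20, w = 5, h = 5), f)
#' readLines(f)
#' @export
writeMOT <- function(records, path) {
  records <- asBoxTable(if (nrow(records)) records else
    data.frame(frame = integer(), id = integer(), x = numeric(),
               y = numeric(), w = numeric(), h = numeric()))
  conf <- if ("conf" %in% names(records)) records$conf else
    rep(1, nrow(records))
  lines <- if (nrow(records)) {
    paste(records$frame + 1L, records$id, fmtNum(records$x),
          fmtNum(records$y), fmtNum(records$w), fmtNum(records$h),
          fmtNum(conf), -1, -1, -1, sep = ",")
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read a MOT-Challenge CSV file
#'
#' @param path source file.
#' @return data.frame with columns `frame` (0-based), `id`,
#'   `x, y, w, h, conf, cx, cy`. Malformed lines raise an error naming
#'   the line number.
#' @export
readMOT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(frame = integer(), id = integer(), x = numeric(),
                      y = numeric(), w = numeric(), h = numeric(),
                      conf = numeric(), cx = numeric(), cy = numeric()))
  }
  parsed <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) < 6)
      stop("malformed MOT line ", i, ": fewer than 6 fields")
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals[1:6]))
      stop("malformed MOT line ", i, ": non-numeric field")
    vals[1:min(7, length(vals))]
  })
  m <- do.call(rbind, lapply(parsed, function(v) {
    c(v[1:6], if (length(v) >= 7) v[7] else 1)
  }))
  data.frame(frame = as.integer(m[, 1]) - 1L, id = as.integer(m[, 2]),
             x = m[, 3], y = m[, 4], w = m[, 5], h = m[, 6],
             conf = m[, 7], cx = m[, 3] + m[, 5] / 2,
             cy = m[, 4] + m[, 6] / 2)
}

#' Write trajectories as a tidy CSV
#'
#' Long-format output for behavioural analysis: one row per track per
#' frame with columns `track_id, frame, time_s, u, v, w, h`.
#'
#' @param trajs trajectory data.frame from [trackVideo()].
#' @param path destination file.
#' @param fps frame rate used to derive `time_s`.
#' @return Invisibly, `path`.
#' @export
writeTidyTrajectories <- function(trajs, path, fps = 15) {
  out <- data.frame(track_id = trajs$track_id, frame = trajs$frame,
                    time_s = trajs$frame / fps,
                    u = trajs$cx, v = trajs$cy, w = trajs$w, h = trajs$h)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
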