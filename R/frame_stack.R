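#' DSA frame stack
#'
#' Container for a digital-subtraction-angiography sequence: a 3D intensity
#' array of identically sized frames plus acquisition metadata. All
#' image-domain operations in the package transform this object.
#'
#' Frames are stored as an array with dimensions `(n_rows, n_cols, n_frames)`.
#' Coordinates are 1-based `(row, col)`; frame `k` is acquired at time
#' `(k - 1) * frame_interval` seconds.
#'
#' @param frames numeric array `(n_rows, n_cols, n_frames)` of intensities in
#'   `[0, 2^bit_depth - 1]`.
#' @param frame_interval seconds between consecutive frames (> 0).
#' @param bit_depth integer, 8 or 16.
#' @param origin_crop integer vector `(row0, col0, n_rows, n_cols)` recording
#'   where these frames sit in the original (uncropped) acquisition, 1-based.
#'   Defaults to the full frame.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_interval, bit_depth = 8L,
                        origin_crop = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a 3D array (rows, cols, frames)")
  d <- dim(frames)
  if (d[3L] < 3L)
    stop("too few frames: a time-intensity curve needs at least 3 samples, got ",
         d[3L])
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be a single positive number of seconds")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  if (anyNA(frames) || !all(is.finite(frames)))
    stop("frame intensities must be finite")
  vmax <- 2^bit_depth - 1
  if (min(frames) < 0 || max(frames) > vmax)
    stop("intensities outside [0, ", vmax, "] for bit depth ", bit_depth)
  if (is.null(origin_crop)) origin_crop <- c(1L, 1L, d[1L], d[2L])
  structure(
    list(frames = frames,
         frame_interval = as.numeric(frame_interval),
         bit_depth = bit_depth,
         origin_crop = as.integer(origin_crop)),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("DSA frame stack: %d x %d pixels, %d frames, %.3g s/frame (%.3g s total), %d-bit\n",
              d[1L], d[2L], d[3L], x$frame_interval,
              (d[3L] - 1L) * x$frame_interval, x$bit_depth))
  oc <- x$origin_crop
  if (!(oc[1L] == 1L && oc[2L] == 1L))
    cat(sprintf("  cropped from original at (row %d, col %d)\n", oc[1L], oc[2L]))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Acquisition times of a frame stack
#'
#' @param stack a [frame_stack].
#' @return numeric vector of frame times in seconds, starting at 0.
#' @export
frame_times <- function(stack) {
  (seq_len(dim(stack$frames)[3L]) - 1L) * stack$frame_interval
}

n_frames <- function(stack) dim(stack$frames)[3L]
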