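#' Crop a frame stack to a rectangle
#'
#' Removes irrelevant borders so downstream analysis sees only the clinically
#' informative region. The crop is recorded in `origin_crop` so original
#' coordinates remain recoverable; nested crops compose.
#'
#' @param stack a [frame_stack].
#' @param rect integer `(row0, col0, n_rows, n_cols)`, 1-based, fully inside
#'   the frame bounds.
#' @return the cropped [frame_stack]; frame interval and bit depth unchanged.
#' @export
crop_stack <- function(stack, rect) {
  d <- dim(stack$frames)
  rect <- as.integer(rect)
  if (length(rect) != 4L) stop("rect must be (row0, col0, n_rows, n_cols)")
  if (rect[3L] < 1L || rect[4L] < 1L) stop("zero-area crop rectangle")
  r1 <- rect[1L] + rect[3L] - 1L
  c1 <- rect[2L] + rect[4L] - 1L
  if (rect[1L] < 1L || rect[2L] < 1L || r1 > d[1L] || c1 > d[2L])
    stop(sprintf("crop rectangle (%d,%d,%d,%d) exceeds the %dx%d frame",
                 rect[1L], rect[2L], rect[3L], rect[4L], d[1L], d[2L]))
  frames <- stack$frames[rect[1L]:r1, rect[2L]:c1, , drop = FALSE]
  oc <- stack$origin_crop
  frame_stack(frames, stack$frame_interval, stack$bit_depth,
              origin_crop = c(oc[1L] + rect[1L] - 1L, oc[2L] + rect[2L] - 1L,
                              rect[3L], rect[4L]))
}

#' Complement (invert) stack intensities
#'
#' DSA renders contrast-filled vessels dark; inverting each pixel to
#' `(2^bit_depth - 1) - p` makes perfused areas high-valued, so pixel values
#' are read downstream as contrast-agent concentration in arbitrary units.
#' The operation is an involution.
#'
#' @param stack a [frame_stack].
#' @return the complemented [frame_stack]; all metadata unchanged.
#' @export
complement_stack <- function(stack) {
  stack$frames <- (2^stack$bit_depth - 1) - stack$frames
  stack
}

#' Suggest a crop that trims constant borders
#'
#' Finds the bounding box of all pixels that vary anywhere in the sequence;
#' border rows/columns that hold a constant value in every frame carry no
#' clinical information. Returns a rectangle usable with [crop_stack()], or
#' the full frame when nothing is constant.
#'
#' @param stack a [frame_stack].
#' @return integer `(row0, col0, n_rows, n_cols)`.
#' @export
suggest_crop <- function(stack) {
  d <- dim(stack$frames)
  first <- stack$frames[, , 1L]
  varying <- matrix(FALSE, d[1L], d[2L])
  for (k in seq_len(d[3L]))
    varying <- varying | (stack$frames[, , k] != first)
  # also treat rows/cols constant within the first frame as borders
  row_var <- apply(first, 1L, function(r) any(r != r[1L])) | rowSums(varying) > 0
  col_var <- apply(first, 2L, function(c) any(c != c[1L])) | colSums(varying) > 0
  if (!any(row_var) || !any(col_var)) return(c(1L, 1L, d[1L], d[2L]))
  r <- range(which(row_var)); c <- range(which(col_var))
  c(r[1L], c[1L], r[2L] - r[1L] + 1L, c[2L] - c[1L] + 1L)
}
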