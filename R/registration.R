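#' Anchor pair for pre/post registration
#'
#' One anatomical point marked by the user in both the pre-therapy and
#' post-therapy vessel masks. Analysis regions keep their distance to this
#' point, which reduces registration to a pure translation. Sub-pixel
#' coordinates are rounded to the nearest pixel.
#'
#' @param pre_point,post_point numeric `(row, col)`, 1-based.
#' @return an object of class `anchor_pair`.
#' @export
anchor_pair <- function(pre_point, post_point) {
  structure(list(pre_point = as.integer(round_half_up(pre_point)),
                 post_point = as.integer(round_half_up(post_point))),
            class = "anchor_pair")
}

#' @export
print.anchor_pair <- function(x, ...) {
  cat(sprintf("Anchor: pre (%d,%d) -> post (%d,%d), shift (%+d,%+d)\n",
              x$pre_point[1L], x$pre_point[2L], x$post_point[1L],
              x$post_point[2L],
              x$post_point[1L] - x$pre_point[1L],
              x$post_point[2L] - x$pre_point[2L]))
  invisible(x)
}

#' Transfer analysis ROIs from the pre- to the post-therapy series
#'
#' Each region drawn on the pre-therapy maps is translated by the anchor
#' displacement `post_point - pre_point`, preserving shape, size, label and
#' id, so it covers the same relative position on the post-therapy maps.
#' Identical anchor points leave the regions unchanged (registration is only
#' needed when the two acquisitions differ in foot position).
#'
#' @param pre_rois list of [roi_rect()] / [roi_circle()] objects (a single
#'   ROI is accepted).
#' @param anchor an [anchor_pair()].
#' @param dim optional `(n_rows, n_cols)` of the post-therapy frames; when
#'   given, a transferred ROI landing outside the bounds is an error naming
#'   the ROI.
#' @return list of translated ROIs, in input order.
#' @export
transfer_rois <- function(pre_rois, anchor, dim = NULL) {
  stopifnot(inherits(anchor, "anchor_pair"))
  if (inherits(pre_rois, "roi")) pre_rois <- list(pre_rois)
  dr <- anchor$post_point[1L] - anchor$pre_point[1L]
  dc <- anchor$post_point[2L] - anchor$pre_point[2L]
  out <- lapply(pre_rois, roi_shift, d_row = dr, d_col = dc)
  if (!is.null(dim)) {
    for (roi in out) {
      ok <- tryCatch({ roi_pixels(roi, dim); TRUE },
                     error = function(e) FALSE)
      if (!ok)
        stop("transferred ROI ", roi_name(roi), " falls outside the ",
             dim[1L], "x", dim[2L], " post-therapy frame")
    }
  }
  out
}
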