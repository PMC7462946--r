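#' Regions of interest
#'
#' ROIs are rectangles or circles in 1-based `(row, col)` pixel coordinates.
#' A rectangle `(row0, col0, n_rows, n_cols)` covers rows
#' `row0 .. row0 + n_rows - 1` and columns `col0 .. col0 + n_cols - 1`.
#' A circle covers all pixels whose centre lies within `radius` of
#' `(center_row, center_col)` (Euclidean distance, inclusive).
#'
#' @param row0,col0 top-left pixel of the rectangle.
#' @param n_rows,n_cols rectangle extent in pixels (>= 1).
#' @param label free-text label, e.g. an artery name ("ATA", "PA").
#' @param id integer identifier, unique within one analysis.
#' @return An object of class `roi`.
#' @export
roi_rect <- function(row0, col0, n_rows, n_cols, label = "", id = 1L) {
  if (n_rows < 1L || n_cols < 1L) stop("rectangle ROI must have positive extent")
  structure(list(shape = "rect",
                 rect = as.integer(c(row0, col0, n_rows, n_cols)),
                 label = as.character(label), id = as.integer(id)),
            class = "roi")
}

#' @param center_row,center_col circle centre pixel.
#' @param radius circle radius in pixels (> 0).
#' @rdname roi_rect
#' @export
roi_circle <- function(center_row, center_col, radius, label = "", id = 1L) {
  if (radius <= 0) stop("circle ROI must have positive radius")
  structure(list(shape = "circle",
                 center = c(center_row, center_col), radius = radius,
                 label = as.character(label), id = as.integer(id)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  geom <- if (x$shape == "rect")
    sprintf("rect (%d,%d) %dx%d", x$rect[1L], x$rect[2L], x$rect[3L], x$rect[4L])
  else
    sprintf("circle (%g,%g) r=%g", x$center[1L], x$center[2L], x$radius)
  cat(sprintf("ROI #%d%s: %s\n", x$id,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "", geom))
  invisible(x)
}

#' Pixels covered by an ROI
#'
#' @param roi an [roi_rect()] or [roi_circle()].
#' @param dim integer `(n_rows, n_cols)` of the frame the ROI lives on.
#' @return two-column integer matrix of `(row, col)` pixel coordinates.
#' @export
roi_pixels <- function(roi, dim) {
  stopifnot(inherits(roi, "roi"))
  if (roi$shape == "rect") {
    r <- roi$rect
    rows <- seq.int(r[1L], r[1L] + r[3L] - 1L)
    cols <- seq.int(r[2L], r[2L] + r[4L] - 1L)
    px <- cbind(row = rep(rows, times = length(cols)),
                col = rep(cols, each = length(rows)))
  } else {
    cr <- roi$center[1L]; cc <- roi$center[2L]; rad <- roi$radius
    rows <- seq.int(max(1L, floor(cr - rad)), ceiling(cr + rad))
    cols <- seq.int(max(1L, floor(cc - rad)), ceiling(cc + rad))
    px <- cbind(row = rep(rows, times = length(cols)),
                col = rep(cols, each = length(rows)))
    keep <- (px[, 1L] - cr)^2 + (px[, 2L] - cc)^2 <= rad^2
    px <- px[keep, , drop = FALSE]
  }
  inb <- px[, 1L] >= 1L & px[, 1L] <= dim[1L] &
         px[, 2L] >= 1L & px[, 2L] <= dim[2L]
  if (!all(inb))
    stop("ROI ", roi_name(roi), " extends outside the ", dim[1L], "x", dim[2L],
         " frame")
  if (nrow(px) == 0L) stop("ROI ", roi_name(roi), " covers no pixels")
  px
}

roi_name <- function(roi) {
  if (nzchar(roi$label)) sprintf("#%d (%s)", roi$id, roi$label)
  else sprintf("#%d", roi$id)
}

#' Translate an ROI by a pixel offset
#'
#' @param roi an ROI.
#' @param d_row,d_col integer offsets added to the ROI position.
#' @return the translated ROI (shape, size, label and id preserved).
#' @export
roi_shift <- function(roi, d_row, d_col) {
  if (roi$shape == "rect") {
    roi$rect[1L] <- roi$rect[1L] + as.integer(d_row)
    roi$rect[2L] <- roi$rect[2L] + as.integer(d_col)
  } else {
    roi$center <- roi$center + c(d_row, d_col)
  }
  roi
}

# JSON sidecar (de)serialisation -----------------------------------------

roi_from_list <- function(x) {
  shape <- x$shape %||% if (!is.null(x$rect)) "rect" else "circle"
  if (shape == "rect")
    roi_rect(x$rect[[1L]], x$rect[[2L]], x$rect[[3L]], x$rect[[4L]],
             label = x$label %||% "", id = x$id %||% 1L)
  else
    roi_circle(x$center[[1L]], x$center[[2L]], x$radius,
               label = x$label %||% "", id = x$id %||% 1L)
}

roi_to_list <- function(roi) {
  if (roi$shape == "rect")
    list(shape = "rect", rect = roi$rect, label = roi$label, id = roi$id)
  else
    list(shape = "circle", center = roi$center, radius = roi$radius,
         label = roi$label, id = roi$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
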