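#' Time-intensity curve of one pixel
#'
#' Reads the complemented (concentration-positive) intensity of a pixel
#' across all frames during the contrast bolus passage.
#'
#' @param stack a complemented [frame_stack].
#' @param pixel integer `(row, col)`, 1-based.
#' @return an object of class `tic`: list with `times` (seconds), `values`
#'   (concentration, arbitrary units) and `source`.
#' @export
extract_tic <- function(stack, pixel) {
  d <- dim(stack$frames)
  pixel <- as.integer(pixel)
  if (pixel[1L] < 1L || pixel[1L] > d[1L] || pixel[2L] < 1L || pixel[2L] > d[2L])
    stop(sprintf("pixel (%d,%d) outside the %dx%d frame",
                 pixel[1L], pixel[2L], d[1L], d[2L]))
  new_tic(frame_times(stack), stack$frames[pixel[1L], pixel[2L], ],
          sprintf("pixel (%d,%d)", pixel[1L], pixel[2L]))
}

#' Mean time-intensity curve over a region
#'
#' Per-frame mean over the region's pixels; with the region placed on a
#' feeding artery this is the arterial input curve used as the
#' perfusion-blood-volume denominator.
#'
#' @param stack a complemented [frame_stack].
#' @param roi an [roi_rect()] / [roi_circle()] inside the frame.
#' @return a `tic`.
#' @export
roi_mean_tic <- function(stack, roi) {
  d <- dim(stack$frames)
  px <- roi_pixels(roi, d[1:2])
  flat <- matrix(stack$frames, d[1L] * d[2L], d[3L])
  idx <- px[, 1L] + (px[, 2L] - 1L) * d[1L]
  new_tic(frame_times(stack), colMeans(flat[idx, , drop = FALSE]),
          paste0("ROI ", roi_name(roi)))
}

new_tic <- function(times, values, source = "") {
  stopifnot(length(times) == length(values))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 source = source), class = "tic")
}

#' @export
print.tic <- function(x, ...) {
  cat(sprintf("TIC (%s): %d samples over %.3g s, peak %.4g at t=%.3g s\n",
              x$source, length(x$times), max(x$times) - min(x$times),
              max(x$values), x$times[which.max(x$values)]))
  invisible(x)
}

#' @export
plot.tic <- function(x, ..., fit = TRUE) {
  plot(x$times, x$values, xlab = "time (s)", ylab = "concentration (a.u.)",
       main = x$source, ...)
  if (fit && length(x$times) >= 2L) {
    cv <- fit_poly5(x)
    tt <- seq(cv$fit_domain[1L], cv$fit_domain[2L], length.out = 200L)
    graphics::lines(tt, eval_poly(cv, tt), col = "red")
  }
  invisible(x)
}

#' Least-squares polynomial approximation of a TIC
#'
#' Fits a degree-5 polynomial in time to the sampled curve (the degree is
#' reduced to `n - 1` when fewer than 6 samples are available). The fit is
#' used for the full-width-at-half-maximum transit-time estimate only; areas
#' under the curve are always taken on the raw samples.
#'
#' @param tic a `tic`, or anything with `times`/`values` components.
#' @param degree target polynomial degree (default 5).
#' @return an object of class `poly_curve`: `coefficients` in ascending
#'   power order, `fit_domain = range(times)` outside which the polynomial
#'   must not be evaluated, and the sampling interval `dt`.
#' @export
fit_poly5 <- function(tic, degree = 5L) {
  t <- tic$times; y <- tic$values
  n <- length(t)
  if (n < 2L) stop("need at least 2 samples to fit a curve")
  d <- min(degree, n - 1L)
  V <- outer(t, 0:d, `^`)
  cf <- qr.coef(qr(V), y)
  cf[is.na(cf)] <- 0
  structure(list(coefficients = as.numeric(cf),
                 fit_domain = range(t),
                 dt = if (n > 1L) t[2L] - t[1L] else NA_real_),
            class = "poly_curve")
}

#' Evaluate a fitted polynomial curve
#'
#' @param curve a [fit_poly5()] result.
#' @param t times inside the curve's fit domain.
#' @return fitted values.
#' @export
eval_poly <- function(curve, t) {
  if (any(t < curve$fit_domain[1L] - 1e-9 | t > curve$fit_domain[2L] + 1e-9))
    stop("evaluation outside the fit domain")
  drop(outer(t, seq_along(curve$coefficients) - 1L, `^`) %*% curve$coefficients)
}

#' @export
print.poly_curve <- function(x, ...) {
  cat(sprintf("degree-%d polynomial on [%.3g, %.3g] s\n",
              length(x$coefficients) - 1L, x$fit_domain[1L], x$fit_domain[2L]))
  invisible(x)
}

#' Full width at half maximum of a fitted curve
#'
#' Operationalises the mean transit time: the temporal distance between the
#' two points where the polynomial-smoothed curve crosses half of its
#' maximum. The polynomial is evaluated on a dense uniform grid over the fit
#' domain, negative values are clamped to 0 (polynomials overshoot near
#' domain edges), and the crossings nearest the peak on each side are
#' refined by linear interpolation. If the curve is still above half-maximum
#' at a domain edge the edge is used and the result is flagged truncated.
#'
#' @param curve a [fit_poly5()] result.
#' @param resolution grid samples per frame interval (>= 10; default 100).
#' @return width in seconds, with attribute `truncated` (logical); `NA` when
#'   the clamped curve has no positive maximum (flat or non-positive TIC).
#' @export
fwhm <- function(curve, resolution = 100L) {
  if (resolution < 10L) stop("resolution must be at least 10 samples per frame interval")
  dom <- curve$fit_domain
  step <- curve$dt / resolution
  g <- seq(dom[1L], dom[2L], by = step)
  y <- drop(outer(g, seq_along(curve$coefficients) - 1L, `^`) %*%
              curve$coefficients)
  fwhm_of_samples(g, y)
}

# shared half-max search on a dense sampled curve; used by fwhm() and the
# batched map computation so both take the identical code path
fwhm_of_samples <- function(g, y) {
  y[y < 0] <- 0
  M <- max(y)
  if (M <= 0) return(structure(NA_real_, truncated = FALSE))
  h <- M / 2
  im <- which.max(y)
  truncated <- FALSE
  below <- which(y[1:im] < h)
  if (length(below) == 0L) {
    tl <- g[1L]; truncated <- TRUE
  } else {
    i <- max(below)
    tl <- g[i] + (h - y[i]) / (y[i + 1L] - y[i]) * (g[i + 1L] - g[i])
  }
  tail_below <- which(y[im:length(y)] < h)
  if (length(tail_below) == 0L) {
    tr <- g[length(g)]; truncated <- TRUE
  } else {
    j <- im + min(tail_below) - 1L
    tr <- g[j - 1L] + (h - y[j - 1L]) / (y[j] - y[j - 1L]) * (g[j] - g[j - 1L])
  }
  structure(tr - tl, truncated = truncated)
}
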