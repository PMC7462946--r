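#' Mean-transit-time map
#'
#' For every vessel-mask pixel: extract its time-intensity curve, fit the
#' degree-5 polynomial, and take the full width at half maximum as the
#' transit time, in seconds. Off-mask pixels and pixels whose fitted curve
#' is flat or non-positive are undefined (`NA`).
#'
#' All mask pixels share one design matrix, so the polynomial coefficients
#' are obtained with a single QR solve and the dense grid evaluation with a
#' single matrix product; the half-max search is the same code path as
#' [fwhm()].
#'
#' @param stack a complemented [frame_stack].
#' @param mask a [vote_mask()] result matching the stack's frames.
#' @param resolution half-max search grid density, samples per frame
#'   interval (default 100).
#' @return numeric matrix (seconds), `NA` where undefined.
#' @export
compute_mtt_map <- function(stack, mask, resolution = 100L) {
  d <- dim(stack$frames)
  if (!all(dim(mask) == d[1:2]))
    stop("mask shape does not match the stack frames")
  out <- matrix(NA_real_, d[1L], d[2L])
  idx <- which(mask)
  if (length(idx) == 0L) return(out)
  t <- frame_times(stack)
  deg <- min(5L, length(t) - 1L)
  V <- outer(t, 0:deg, `^`)
  flat <- matrix(stack$frames, d[1L] * d[2L], d[3L])
  cf <- qr.coef(qr(V), t(flat[idx, , drop = FALSE]))   # (deg+1) x n_pixels
  cf[is.na(cf)] <- 0
  step <- stack$frame_interval / resolution
  g <- seq(t[1L], t[length(t)], by = step)
  Y <- outer(g, 0:deg, `^`) %*% cf                     # n_grid x n_pixels
  vals <- vapply(seq_along(idx),
                 function(j) as.numeric(fwhm_of_samples(g, Y[, j])),
                 numeric(1L))
  vals[!is.na(vals) & vals <= 0] <- NA_real_
  out[idx] <- vals
  out
}

#' Perfusion-blood-volume map
#'
#' Per mask pixel, the ratio of the area under the pixel's concentration
#' curve to the area under the arterial input curve, both by the trapezoidal
#' rule on the raw samples over the full acquisition window. Dimensionless;
#' a pixel whose curve matches the arterial curve scores 1.
#'
#' @param stack a complemented [frame_stack].
#' @param mask a [vote_mask()] result.
#' @param arterial arterial input curve: a `tic` (e.g. [roi_mean_tic()] over
#'   a region on the feeding artery).
#' @return numeric matrix, `NA` off the mask.
#' @export
compute_pbv_map <- function(stack, mask, arterial) {
  d <- dim(stack$frames)
  if (!all(dim(mask) == d[1:2]))
    stop("mask shape does not match the stack frames")
  stopifnot(inherits(arterial, "tic"))
  if (length(arterial$values) != d[3L])
    stop("arterial curve has ", length(arterial$values),
         " samples but the stack has ", d[3L], " frames")
  dt <- stack$frame_interval
  w <- rep(dt, d[3L]); w[c(1L, d[3L])] <- dt / 2      # trapezoid weights
  auc_art <- sum(w * arterial$values)
  if (auc_art <= 0)
    stop("no arterial signal: arterial curve area is ", auc_art)
  out <- matrix(NA_real_, d[1L], d[2L])
  idx <- which(mask)
  if (length(idx) == 0L) return(out)
  flat <- matrix(stack$frames, d[1L] * d[2L], d[3L])
  out[idx] <- drop(flat[idx, , drop = FALSE] %*% w) / auc_art
  out
}

#' Perfusion-blood-flow map
#'
#' Elementwise quotient `PBF = PBV / MTT`, defined where both maps are
#' defined and the transit time is positive; units 1/second.
#'
#' @param pbv,mtt aligned maps from [compute_pbv_map()] / [compute_mtt_map()].
#' @return numeric matrix, `NA` where either input is undefined.
#' @export
compute_pbf_map <- function(pbv, mtt) {
  if (!all(dim(pbv) == dim(mtt))) stop("maps are not aligned")
  out <- matrix(NA_real_, nrow(pbv), ncol(pbv))
  ok <- !is.na(pbv) & !is.na(mtt) & mtt > 0
  out[ok] <- pbv[ok] / mtt[ok]
  out
}

#' All three perfusion maps for one series
#'
#' Convenience wrapper running [compute_mtt_map()], [compute_pbv_map()] and
#' [compute_pbf_map()] on one masked stack.
#'
#' @param stack a complemented [frame_stack].
#' @param mask a [vote_mask()] result.
#' @param arterial arterial input `tic`, or an `roi` from which the mean
#'   curve is taken.
#' @param resolution half-max grid density for the transit-time map.
#' @return an object of class `perfusion_maps`: list with `pbv`, `mtt`,
#'   `pbf` matrices, the `mask`, and `frame_interval`.
#' @export
compute_perfusion_maps <- function(stack, mask, arterial, resolution = 100L) {
  if (inherits(arterial, "roi")) arterial <- roi_mean_tic(stack, arterial)
  mtt <- compute_mtt_map(stack, mask, resolution)
  pbv <- compute_pbv_map(stack, mask, arterial)
  structure(list(pbv = pbv, mtt = mtt, pbf = compute_pbf_map(pbv, mtt),
                 mask = mask, frame_interval = stack$frame_interval),
            class = "perfusion_maps")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  cat(sprintf("Perfusion maps %d x %d (%d vessel pixels)\n",
              nrow(x$pbv), ncol(x$pbv), sum(x$mask)))
  for (nm in c("pbv", "mtt", "pbf")) {
    v <- x[[nm]][!is.na(x[[nm]])]
    unit <- c(pbv = "", mtt = " s", pbf = " 1/s")[[nm]]
    if (length(v))
      cat(sprintf("  %s: median %.4g%s [%.4g, %.4g], %d defined\n",
                  toupper(nm), stats::median(v), unit, min(v), max(v),
                  length(v)))
    else cat(sprintf("  %s: all undefined\n", toupper(nm)))
  }
  invisible(x)
}

#' @export
plot.perfusion_maps <- function(x, which = c("pbv", "mtt", "pbf"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(1L, length(which)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (nm in which) {
    m <- x[[nm]]
    img <- t(m[nrow(m):1L, , drop = FALSE])
    graphics::image(img, col = map_palette("jet"), axes = FALSE,
                    main = toupper(nm), useRaster = TRUE)
  }
  invisible(x)
}
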