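#' Gamma-variate bolus curve
#'
#' Standard parametric model of contrast-agent wash-in/wash-out used by the
#' phantom generator:
#' \deqn{C(t) = A ((t - t_0)/t_p)^\alpha \exp(\alpha (1 - (t - t_0)/t_p))}
#' for `t > t0` and 0 before, normalised so the peak value is exactly `A`
#' at `t = t0 + tp`.
#'
#' @param t times in seconds (vector).
#' @param A peak amplitude (concentration, arbitrary units).
#' @param t0 bolus arrival delay, seconds.
#' @param tp time from arrival to peak, seconds (> 0).
#' @param alpha shape parameter (> 0); smaller values give broader boluses.
#' @return concentrations, same length as `t`.
#' @export
gamma_variate <- function(t, A = 1, t0 = 0, tp, alpha) {
  if (tp <= 0 || alpha <= 0) stop("tp and alpha must be positive")
  out <- numeric(length(t))
  pos <- t > t0
  x <- (t[pos] - t0) / tp
  out[pos] <- A * x^alpha * exp(alpha * (1 - x))
  out
}

#' Closed-form full width at half maximum of a gamma-variate
#'
#' Solves \eqn{\alpha(\log x + 1 - x) = \log(1/2)} for the two half-maximum
#' crossings by bisection on the exact curve (machine-precision root
#' finding); the width scales linearly with `tp` at fixed `alpha`. This is
#' the independent oracle against which the polynomial-based transit-time
#' estimate is validated.
#'
#' @param tp,alpha gamma-variate parameters.
#' @return width in seconds (independent of `A` and `t0`).
#' @export
gamma_variate_fwhm <- function(tp, alpha) {
  f <- function(x) alpha * (log(x) + 1 - x) - log(0.5)
  xl <- stats::uniroot(f, c(1e-12, 1), tol = 1e-12)$root
  xr <- stats::uniroot(f, c(1, 1e3), tol = 1e-12)$root
  (xr - xl) * tp
}

#' Area under a gamma-variate over a finite window
#'
#' Numeric quadrature of the exact curve on `[0, upper]`; used for the
#' phantom's ground-truth relative blood volume.
#'
#' @param upper window end, seconds.
#' @inheritParams gamma_variate
#' @return integral value.
#' @export
gamma_variate_auc <- function(upper, A = 1, t0 = 0, tp, alpha) {
  stats::integrate(gamma_variate, lower = t0, upper = upper, A = A, t0 = t0,
                   tp = tp, alpha = alpha, rel.tol = 1e-10,
                   subdivisions = 500L)$value
}

#' One phantom vessel segment
#'
#' A straight vessel of given width whose every pixel follows the same
#' gamma-variate bolus curve.
#'
#' @param from,to segment endpoints, `(row, col)`.
#' @param width vessel width in pixels (>= 1).
#' @param A,t0,tp,alpha bolus kinetics, see [gamma_variate()].
#' @return a `vessel_segment` list.
#' @export
vessel_segment <- function(from, to, width = 3, A = 200, t0 = 0, tp = 4,
                           alpha = 1.3) {
  if (width < 1) stop("segment width must be at least 1 pixel")
  if (tp <= 0 || alpha <= 0) stop("tp and alpha must be positive")
  structure(list(from = as.numeric(from), to = as.numeric(to),
                 width = as.numeric(width), A = as.numeric(A),
                 t0 = as.numeric(t0), tp = as.numeric(tp),
                 alpha = as.numeric(alpha)),
            class = "vessel_segment")
}

#' Phantom specification
#'
#' Describes a synthetic DSA acquisition: image geometry, frame timing,
#' vessel segments with their bolus kinetics, background level, noise and
#' quantisation. The defaults emulate a foot-perfusion DSA run — 24 frames
#' at 0.5 s with three parallel infrapopliteal-style vessels carrying broad,
#' slow boluses whose wash-in and wash-out both fall inside the acquisition
#' window — with the first (highest-amplitude, fastest) segment serving as
#' the arterial reference.
#'
#' @param image_size `(rows, cols)`, default 64 x 64.
#' @param n_frames number of frames (>= 3), default 24.
#' @param frame_interval seconds per frame, default 0.5.
#' @param vessel_segments list of [vessel_segment()]s; default three
#'   vertical vessels with peak amplitudes 200/180/160 and times-to-peak
#'   3.5/4.0/4.5 s (shape 1.3).
#' @param background_level constant background intensity; default 0
#'   (subtraction imaging leaves near-zero background).
#' @param noise_sigma additive Gaussian noise s.d. in intensity units,
#'   default 2.
#' @param bit_depth 8 or 16, default 8.
#' @param rng_seed integer seed making the noise reproducible, default 42.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(64L, 64L),
                         n_frames = 24L,
                         frame_interval = 0.5,
                         vessel_segments = default_segments(image_size),
                         background_level = 0,
                         noise_sigma = 2,
                         bit_depth = 8L,
                         rng_seed = 42L) {
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (n_frames < 3L) stop("n_frames must be at least 3")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  vmax <- 2^bit_depth - 1
  for (s in vessel_segments) {
    stopifnot(inherits(s, "vessel_segment"))
    if (s$A + background_level > vmax)
      stop("segment amplitude ", s$A, " + background ", background_level,
           " exceeds the ", bit_depth, "-bit range")
  }
  structure(list(image_size = as.integer(image_size),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 vessel_segments = vessel_segments,
                 background_level = background_level,
                 noise_sigma = noise_sigma,
                 bit_depth = bit_depth,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

default_segments <- function(image_size = c(64L, 64L)) {
  r0 <- max(2L, round(image_size[1L] * 0.1))
  r1 <- min(image_size[1L] - 1L, round(image_size[1L] * 0.9))
  cols <- round(image_size[2L] * c(0.15, 0.5, 0.8))
  list(vessel_segment(c(r0, cols[1L]), c(r1, cols[1L]), width = 3,
                      A = 200, t0 = 0, tp = 3.5, alpha = 1.3),
       vessel_segment(c(r0, cols[2L]), c(r1, cols[2L]), width = 3,
                      A = 180, t0 = 0, tp = 4.0, alpha = 1.3),
       vessel_segment(c(r0, cols[3L]), c(r1, cols[3L]), width = 3,
                      A = 160, t0 = 0, tp = 4.5, alpha = 1.3))
}

# pixels within width/2 of the segment's centre line
rasterize_segment <- function(seg, dim) {
  p <- seg$from; q <- seg$to
  half <- seg$width / 2
  rows <- seq.int(max(1L, floor(min(p[1L], q[1L]) - half)),
                  min(dim[1L], ceiling(max(p[1L], q[1L]) + half)))
  cols <- seq.int(max(1L, floor(min(p[2L], q[2L]) - half)),
                  min(dim[2L], ceiling(max(p[2L], q[2L]) + half)))
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  v <- q - p
  len2 <- sum(v^2)
  if (len2 == 0) {
    d2 <- (rr - p[1L])^2 + (cc - p[2L])^2
  } else {
    tt <- pmin(1, pmax(0, ((rr - p[1L]) * v[1L] + (cc - p[2L]) * v[2L]) / len2))
    d2 <- (rr - (p[1L] + tt * v[1L]))^2 + (cc - (p[2L] + tt * v[2L]))^2
  }
  keep <- d2 <= half^2
  cbind(row = rr[keep], col = cc[keep])
}

#' Generate a synthetic DSA stack with ground truth
#'
#' Rasterises each vessel segment as a thick line and gives every vessel
#' pixel the segment's gamma-variate bolus curve on top of the background
#' level, plus i.i.d. Gaussian noise, clipped to the bit range and quantised
#' to integers. The returned stack is already in the complemented
#' (concentration-positive) convention. Ground truth carries the exact
#' vessel mask, the closed-form bolus width per pixel, and the relative
#' area-under-curve per pixel (against the first segment as arterial
#' reference, both integrated over the acquisition window), so pipeline
#' estimates can be scored without circularity: ground truth comes from the
#' generating curves, never from the pipeline. Deterministic for a given
#' `rng_seed`; overlapping segments are allowed (the last drawn wins).
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `dsa_phantom`: list with `stack` (a
#'   [frame_stack]), `truth` (list: `mask`, `mtt`, `pbv`, `segment_id`,
#'   `segment_pixels`, `arterial_segment`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- c(spec$image_size, spec$n_frames)
  vmax <- 2^spec$bit_depth - 1
  times <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval
  t_end <- times[length(times)]
  frames <- array(spec$background_level, dim = d)
  seg_id <- matrix(0L, d[1L], d[2L])
  seg_px <- vector("list", length(spec$vessel_segments))
  for (s in seq_along(spec$vessel_segments)) {
    seg <- spec$vessel_segments[[s]]
    px <- rasterize_segment(seg, d[1:2])
    if (nrow(px) == 0L) stop("segment ", s, " rasterises to no pixels")
    seg_px[[s]] <- px
    seg_id[px] <- s
    curve <- gamma_variate(times, seg$A, seg$t0, seg$tp, seg$alpha)
    idx <- px[, 1L] + (px[, 2L] - 1L) * d[1L]
    for (k in seq_len(d[3L]))
      frames[idx + (k - 1L) * d[1L] * d[2L]] <- spec$background_level + curve[k]
  }
  # segment ids after overlap resolution (last drawn wins)
  for (s in seq_along(seg_px)) {
    px <- seg_px[[s]]
    seg_px[[s]] <- px[seg_id[px] == s, , drop = FALSE]
  }
  if (spec$noise_sigma > 0) {
    frames <- frames + with_seed(spec$rng_seed,
      array(stats::rnorm(prod(d), sd = spec$noise_sigma), dim = d))
  }
  frames <- round(pmin(pmax(frames, 0), vmax))  # order keeps the dim attribute

  arterial <- 1L
  art_seg <- spec$vessel_segments[[arterial]]
  auc_art <- gamma_variate_auc(t_end, art_seg$A, art_seg$t0, art_seg$tp,
                               art_seg$alpha)
  mtt <- matrix(NA_real_, d[1L], d[2L])
  pbv <- matrix(NA_real_, d[1L], d[2L])
  for (s in seq_along(spec$vessel_segments)) {
    seg <- spec$vessel_segments[[s]]
    px <- seg_px[[s]]
    if (nrow(px) == 0L) next
    mtt[px] <- gamma_variate_fwhm(seg$tp, seg$alpha)
    pbv[px] <- gamma_variate_auc(t_end, seg$A, seg$t0, seg$tp, seg$alpha) /
      auc_art
  }
  structure(list(
    stack = frame_stack(frames, spec$frame_interval, spec$bit_depth),
    truth = list(mask = structure(seg_id > 0L,
                                  class = c("vessel_mask", "matrix", "array")),
                 mtt = mtt, pbv = pbv, segment_id = seg_id,
                 segment_pixels = seg_px, arterial_segment = arterial),
    spec = spec), class = "dsa_phantom")
}

#' @export
print.dsa_phantom <- function(x, ...) {
  cat(sprintf("DSA phantom: %d segment(s), %d vessel pixels\n",
              length(x$spec$vessel_segments), sum(x$truth$mask)))
  print(x$stack)
  invisible(x)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Matched pre/post phantom pair
#'
#' Emulates the two acquisitions of an endovascular treatment: the post
#' stack reuses the pre geometry translated by `shift` (the slight foot
#' repositioning that motivates anchor-based registration) with modified
#' kinetics — amplitudes multiplied by `amp_mult` and times-to-peak divided
#' by `tp_div` (faster transit, i.e. shorter bolus width, models improved
#' flow). Matching anchor points are returned so [transfer_rois()] recovers
#' the alignment exactly.
#'
#' @param spec a [phantom_spec()] describing the pre-therapy acquisition.
#' @param amp_mult per-segment amplitude multipliers (recycled).
#' @param tp_div per-segment time-to-peak divisors (recycled).
#' @param shift integer `(rows, cols)` whole-pixel translation of the post
#'   geometry.
#' @return list with `pre` and `post` ([generate_phantom()] results) and
#'   `anchor` (an [anchor_pair()]).
#' @export
make_pre_post_pair <- function(spec, amp_mult = 1, tp_div = 1,
                               shift = c(0L, 0L)) {
  stopifnot(inherits(spec, "phantom_spec"))
  ns <- length(spec$vessel_segments)
  amp_mult <- rep_len(amp_mult, ns)
  tp_div <- rep_len(tp_div, ns)
  shift <- as.integer(round(shift))
  post_segments <- lapply(seq_len(ns), function(s) {
    seg <- spec$vessel_segments[[s]]
    seg$from <- seg$from + shift
    seg$to <- seg$to + shift
    half <- seg$width / 2
    lim <- spec$image_size
    ends <- rbind(seg$from, seg$to)
    # bounds at pixel granularity: covered pixels are integers within
    # `half` of the centre line
    if (any(ceiling(ends - half) < 1) ||
        any(floor(ends[, 1L] + half) > lim[1L]) ||
        any(floor(ends[, 2L] + half) > lim[2L]))
      stop("shift pushes segment ", s, " outside the image")
    seg$A <- seg$A * amp_mult[s]
    seg$tp <- seg$tp / tp_div[s]
    seg
  })
  post_spec <- spec
  post_spec$vessel_segments <- post_segments
  post_spec$rng_seed <- spec$rng_seed + 1L  # independent noise realisation
  post_spec <- do.call(phantom_spec, unclass(post_spec))
  pre_anchor <- round(spec$vessel_segments[[1L]]$from)
  list(pre = generate_phantom(spec),
       post = generate_phantom(post_spec),
       anchor = anchor_pair(pre_anchor, pre_anchor + shift))
}

#' Seed and arterial regions for a phantom
#'
#' Builds the user-interaction inputs the pipeline needs — the vessel and
#' background seed regions and the arterial ROI — from a phantom's known
#' geometry: a small rectangle on the arterial (first) segment at its bolus
#' peak frame, and a background rectangle in the largest empty area. Only
#' meant for driving the pipeline on generated phantoms; clinical ROIs come
#' from the operator.
#'
#' @param phantom a [generate_phantom()] result.
#' @return list with `seeds` (a [seed_spec()]) and `arterial_roi` (an ROI on
#'   the arterial segment).
#' @export
phantom_seeds <- function(phantom) {
  stopifnot(inherits(phantom, "dsa_phantom"))
  spec <- phantom$spec
  art <- phantom$truth$arterial_segment
  px <- phantom$truth$segment_pixels[[art]]
  seg <- spec$vessel_segments[[art]]
  # rows in the middle of the segment, full vessel width
  mid_r <- round(stats::median(px[, 1L]))
  sel <- px[abs(px[, 1L] - mid_r) <= 2L, , drop = FALSE]
  vessel_roi <- roi_rect(min(sel[, 1L]), min(sel[, 2L]),
                         diff(range(sel[, 1L])) + 1L,
                         diff(range(sel[, 2L])) + 1L,
                         label = "arterial seed", id = 0L)
  bg_roi <- find_background_rect(phantom$truth$mask)
  peak_frame <- max(1L, min(spec$n_frames,
                            1L + round((seg$t0 + seg$tp) / spec$frame_interval)))
  list(seeds = seed_spec(peak_frame, vessel_roi, bg_roi),
       arterial_roi = vessel_roi)
}

find_background_rect <- function(mask, size = 8L) {
  d <- dim(mask)
  for (r in seq(1L, d[1L] - size + 1L, by = 2L))
    for (c in seq(1L, d[2L] - size + 1L, by = 2L))
      if (!any(mask[r:(r + size - 1L), c:(c + size - 1L)]))
        return(roi_rect(r, c, size, size, label = "background seed", id = -1L))
  stop("no ", size, "x", size, " background block found")
}
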