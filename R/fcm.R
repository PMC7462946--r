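#' Seed specification for vessel segmentation
#'
#' Two user-defined regions on one frame — one over a major vessel, one over
#' background — whose mean intensities initialise the fuzzy C-means cluster
#' centres.
#'
#' @param slice frame index (1-based) on which the regions were drawn.
#' @param vessel_roi,background_roi [roi_rect()] / [roi_circle()] objects;
#'   must be disjoint and inside the frame.
#' @return an object of class `seed_spec`.
#' @export
seed_spec <- function(slice, vessel_roi, background_roi) {
  stopifnot(inherits(vessel_roi, "roi"), inherits(background_roi, "roi"))
  structure(list(slice = as.integer(slice), vessel_roi = vessel_roi,
                 background_roi = background_roi),
            class = "seed_spec")
}

#' Cluster-centre seeds from user regions
#'
#' Mean intensity of the vessel and background seed regions on the chosen
#' frame of a complemented stack. A warning is issued when the vessel mean
#' does not exceed the background mean (seeds likely swapped); values are
#' returned as computed.
#'
#' @param stack a complemented [frame_stack].
#' @param seeds a [seed_spec()].
#' @return named numeric vector `c(vessel = ..., background = ...)`.
#' @export
seed_centers <- function(stack, seeds) {
  stopifnot(inherits(seeds, "seed_spec"))
  d <- dim(stack$frames)
  if (seeds$slice < 1L || seeds$slice > d[3L])
    stop("seed slice ", seeds$slice, " outside 1..", d[3L])
  frame <- stack$frames[, , seeds$slice]
  vp <- roi_pixels(seeds$vessel_roi, d[1:2])
  bp <- roi_pixels(seeds$background_roi, d[1:2])
  if (nrow(merge(as.data.frame(vp), as.data.frame(bp))) > 0L)
    stop("vessel and background seed regions overlap")
  cv <- mean(frame[vp])
  cb <- mean(frame[bp])
  if (cv <= cb)
    warning("vessel seed mean (", signif(cv, 5), ") <= background seed mean (",
            signif(cb, 5), "); seeds are likely swapped")
  c(vessel = cv, background = cb)
}

#' Two-cluster fuzzy C-means on the full spatio-temporal stack
#'
#' Clusters every voxel of the 3D (row x col x frame) stack by scalar
#' intensity into vessel/background, starting from the seeded centres.
#' Standard alternating updates: memberships
#' \eqn{u_{ij} = 1 / \sum_k (d_{ij}/d_{ik})^{2/(m-1)}} with squared Euclidean
#' distance on intensity, then centres
#' \eqn{c_j = \sum_i u_{ij}^m x_i / \sum_i u_{ij}^m}. A voxel lying exactly
#' on a centre receives membership 1 for that cluster. Iteration stops when
#' the largest membership change falls below `tol` or after `max_iter`
#' sweeps. The procedure is fully deterministic.
#'
#' Because memberships depend on a voxel only through its intensity, updates
#' are computed on the table of distinct intensity values (at most
#' `2^bit_depth`), which makes the sweep cost independent of stack size.
#'
#' @param stack a complemented [frame_stack].
#' @param centers numeric `(vessel, background)` initial centres, distinct;
#'   typically from [seed_centers()].
#' @param fuzziness fuzzifier m > 1 (default 2, the conventional choice).
#' @param tol convergence threshold on the maximum membership change
#'   (default 1e-5).
#' @param max_iter maximum sweeps (default 100).
#' @return an object of class `fcm_partition`: list with `u_vessel` (3D array
#'   of vessel memberships; background membership is its complement),
#'   `centers` (named, vessel first; vessel is the cluster with the higher
#'   final centre), `n_iterations`, `converged`, and `objective` (the value
#'   of the fuzzy within-cluster objective after every sweep; non-increasing).
#' @export
fcm_cluster <- function(stack, centers, fuzziness = 2, tol = 1e-5,
                        max_iter = 100L) {
  if (length(centers) != 2L || !all(is.finite(centers)))
    stop("centers must be two finite intensities")
  if (centers[1L] == centers[2L]) stop("initial centres must be distinct")
  if (fuzziness <= 1) stop("fuzziness must exceed 1")
  x <- as.vector(stack$frames)
  if (anyNA(x) || !all(is.finite(x))) stop("non-finite intensities in stack")
  ux <- sort(unique(x))
  wt <- as.vector(table(factor(x, levels = ux)))
  m <- fuzziness
  expo <- 1 / (m - 1)
  c1 <- as.numeric(centers[1L]); c2 <- as.numeric(centers[2L])
  membership_u1 <- function(c1, c2) {
    d1 <- (ux - c1)^2; d2 <- (ux - c2)^2
    u1 <- 1 / (1 + (d1 / d2)^expo)
    u1[d1 == 0] <- 1                 # singleton rule: voxel at a centre
    u1[d2 == 0 & d1 != 0] <- 0
    u1
  }
  u1 <- membership_u1(c1, c2)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w1 <- wt * u1^m; w2 <- wt * (1 - u1)^m
    c1 <- sum(w1 * ux) / sum(w1)
    c2 <- sum(w2 * ux) / sum(w2)
    u1_new <- membership_u1(c1, c2)
    objective <- c(objective,
                   sum(wt * u1_new^m * (ux - c1)^2) +
                   sum(wt * (1 - u1_new)^m * (ux - c2)^2))
    delta <- max(abs(u1_new - u1))
    u1 <- u1_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (c2 > c1) {                      # vessel is the higher-centre cluster
    tmp <- c1; c1 <- c2; c2 <- tmp
    u1 <- 1 - u1
  }
  uv <- array(u1[match(x, ux)], dim = dim(stack$frames))
  structure(list(u_vessel = uv,
                 centers = c(vessel = c1, background = c2),
                 n_iterations = iter,
                 converged = converged,
                 objective = objective),
            class = "fcm_partition")
}

#' @export
print.fcm_partition <- function(x, ...) {
  cat(sprintf(paste0("Fuzzy C-means partition: centres vessel=%.4g ",
                     "background=%.4g, %d iteration(s)%s\n"),
              x$centers[1L], x$centers[2L], x$n_iterations,
              if (x$converged) ", converged" else " (not converged)"))
  invisible(x)
}

#' Hard labels from a fuzzy partition
#'
#' A voxel is labelled vessel iff its vessel membership strictly exceeds its
#' background membership; ties go to background.
#'
#' @param partition an [fcm_cluster()] result.
#' @return 3D integer array of labels (1 = vessel, 0 = background).
#' @export
defuzzify <- function(partition) {
  stopifnot(inherits(partition, "fcm_partition"))
  array(as.integer(partition$u_vessel > 0.5), dim = dim(partition$u_vessel))
}

#' Project 3D labels to a 2D vessel mask by pixel voting
#'
#' A pixel enters the mask iff it was labelled vessel on at least one frame
#' (union over frames): perfused vessels appear wherever the bolus ever
#' filled them.
#'
#' @param labels 3D label array from [defuzzify()] (or a logical array).
#' @return logical matrix of class `vessel_mask`, same (rows, cols) as the
#'   stack frames.
#' @export
vote_mask <- function(labels) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  m <- rowSums(labels, dims = 2L) > 0
  structure(m, class = c("vessel_mask", class(m)))
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("Vessel mask %d x %d: %d vessel pixels (%.1f%%)\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

#' Write a vessel mask as an 8-bit PNG (0/255)
#'
#' @param mask a [vote_mask()] result.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
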