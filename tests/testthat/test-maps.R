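# analytic float stack: every listed pixel gets `curve`, others stay at 0
curve_stack <- function(dim2, pixels, curve, dt = 0.5) {
  arr <- array(0, dim = c(dim2, length(curve)))
  for (k in seq_along(curve))
    for (i in seq_len(nrow(pixels)))
      arr[pixels[i, 1L], pixels[i, 2L], k] <- curve[k]
  make_stack(arr, dt = dt)
}

test_that("transit-time maps recover a known bolus width on the mask", {
  t <- (0:23) * 0.5
  curve <- gamma_variate(t, 200, 0, 4, 1.3)
  px <- cbind(2:5, 3L)
  stk <- curve_stack(c(8L, 8L), px, curve)
  mask <- matrix(FALSE, 8, 8); mask[px] <- TRUE
  mtt <- compute_mtt_map(stk, mask)
  expect_true(all(is.na(mtt[!mask])))
  truth <- oracle_gamma_fwhm(4, 1.3)
  expect_equal(unname(mtt[px]), rep(truth, 4), tolerance = 0.05)
  # identical inputs give identical maps
  expect_identical(mtt, compute_mtt_map(stk, mask))
  # empty mask: all undefined
  expect_true(all(is.na(compute_mtt_map(stk, matrix(FALSE, 8, 8)))))
})

test_that("blood-volume is the AUC ratio against the arterial curve", {
  t <- (0:23) * 0.5
  curve <- gamma_variate(t, 100, 0.5, 4, 1.3)
  arr <- array(0, dim = c(4L, 4L, 24L))
  arr[1, 1, ] <- curve          # arterial pixel
  arr[2, 2, ] <- curve          # tissue pixel, identical curve
  arr[3, 3, ] <- 0.5 * curve    # tissue pixel, half amplitude
  stk <- make_stack(arr)
  mask <- matrix(TRUE, 4, 4)
  art <- extract_tic(stk, c(1L, 1L))
  pbv <- compute_pbv_map(stk, mask, art)
  expect_equal(pbv[2, 2], 1.0, tolerance = 1e-12)
  expect_equal(pbv[3, 3], 0.5, tolerance = 1e-12)
  # against an independent trapezoid implementation
  expect_equal(pbv[3, 3],
               pracma::trapz(t, 0.5 * curve) / pracma::trapz(t, curve),
               tolerance = 1e-12)
  # zero arterial curve is an error
  zero_art <- make_tic(t, rep(0, 24))
  expect_error(compute_pbv_map(stk, mask, zero_art), "no arterial signal")
})

test_that("blood-volume is scale-invariant globally and linear in tissue", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0))
  stk <- ph$stack
  h <- phantom_seeds(ph)
  mask <- ph$truth$mask
  art <- roi_mean_tic(stk, h$arterial_roi)
  pbv <- compute_pbv_map(stk, mask, art)
  # global rescale: numerator and denominator scale together
  stk2 <- stk; stk2$frames <- stk$frames * 0.3
  art2 <- roi_mean_tic(stk2, h$arterial_roi)
  expect_equal(compute_pbv_map(stk2, mask, art2), pbv, tolerance = 1e-12)
  # tissue-only rescale: values scale linearly
  expect_equal(compute_pbv_map(stk2, mask, art),
               0.3 * pbv, tolerance = 1e-12)
})

test_that("blood-flow is the elementwise quotient with NA propagation", {
  pbv <- matrix(c(0.5, 0.2, NA, 0), 2, 2)
  mtt <- matrix(c(2, NA, 3, 4), 2, 2)
  pbf <- compute_pbf_map(pbv, mtt)
  expect_equal(pbf[1, 1], 0.25)
  expect_true(is.na(pbf[2, 1]))   # undefined MTT
  expect_true(is.na(pbf[1, 2]))   # undefined PBV
  expect_equal(pbf[2, 2], 0)      # zero volume, defined transit
  expect_error(compute_pbf_map(pbv, matrix(1, 3, 3)), "aligned")
})

test_that("the combined maps satisfy the quotient identity on their support", {
  ph <- generate_phantom(phantom_spec())
  h <- phantom_seeds(ph)
  mask <- ph$truth$mask
  maps <- compute_perfusion_maps(ph$stack, mask, h$arterial_roi)
  ok <- !is.na(maps$pbf)
  expect_true(all(!is.na(maps$pbv[ok]) & !is.na(maps$mtt[ok])))
  expect_equal(maps$pbf[ok], maps$pbv[ok] / maps$mtt[ok], tolerance = 1e-12)
  expect_true(all(maps$mtt[!is.na(maps$mtt)] > 0))
  expect_true(all(maps$pbv[!is.na(maps$pbv)] >= 0))
  # defined pixels lie on the mask
  expect_true(all(mask[!is.na(maps$mtt)]))
})

test_that("noiseless phantoms are recovered within the error budget", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0))
  h <- phantom_seeds(ph)
  mask <- ph$truth$mask
  maps <- compute_perfusion_maps(ph$stack, mask, h$arterial_roi)
  idx <- which(mask & !is.na(maps$mtt))
  expect_equal(length(idx), sum(mask))
  expect_lt(max(abs(maps$mtt[idx] - ph$truth$mtt[idx]) / ph$truth$mtt[idx]),
            0.05)
  expect_lt(max(abs(maps$pbv[idx] - ph$truth$pbv[idx]) / ph$truth$pbv[idx]),
            0.02)
})

test_that("mild noise keeps recovery inside the relaxed budget", {
  # noise at 2% of the peak amplitude
  ph <- generate_phantom(phantom_spec(noise_sigma = 4))
  h <- phantom_seeds(ph)
  mask <- ph$truth$mask
  maps <- compute_perfusion_maps(ph$stack, mask, h$arterial_roi)
  idx <- which(mask & !is.na(maps$mtt))
  expect_lt(max(abs(maps$mtt[idx] - ph$truth$mtt[idx]) / ph$truth$mtt[idx]),
            0.10)
  expect_lt(max(abs(maps$pbv[idx] - ph$truth$pbv[idx]) / ph$truth$pbv[idx]),
            0.05)
})
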