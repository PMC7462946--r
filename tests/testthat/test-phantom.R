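test_that("the gamma-variate peaks at exactly A and is zero before arrival", {
  expect_equal(gamma_variate(1 + 4, A = 173, t0 = 1, tp = 4, alpha = 2.3), 173)
  expect_equal(gamma_variate(c(-1, 0, 1), A = 50, t0 = 1, tp = 2, alpha = 3),
               c(0, 0, 0))
  expect_error(gamma_variate(1, tp = -1, alpha = 2), "positive")
})

test_that("closed-form bolus width matches brute-force root finding", {
  for (p in list(c(4, 3), c(2, 1.3), c(6, 5))) {
    expect_equal(gamma_variate_fwhm(p[1L], p[2L]),
                 oracle_gamma_fwhm(p[1L], p[2L]), tolerance = 1e-3)
  }
  # width scales linearly with tp at fixed shape
  expect_equal(gamma_variate_fwhm(8, 1.7), 2 * gamma_variate_fwhm(4, 1.7),
               tolerance = 1e-9)
})

test_that("phantom generation is deterministic for a given seed", {
  spec <- phantom_spec(noise_sigma = 3, rng_seed = 7L)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$stack$frames, p2$stack$frames)
  expect_identical(p1$truth$mask, p2$truth$mask)
  # and does not disturb the caller's RNG stream
  set.seed(99); before <- stats::runif(1)
  set.seed(99); generate_phantom(spec); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("noiseless vessel pixels follow the analytic curve to quantisation", {
  seg <- vessel_segment(c(5, 5), c(25, 5), width = 3, A = 190, t0 = 0.5,
                        tp = 4, alpha = 1.3)
  spec <- phantom_spec(image_size = c(32L, 32L), vessel_segments = list(seg),
                       noise_sigma = 0)
  ph <- generate_phantom(spec)
  t <- frame_times(ph$stack)
  truth_curve <- gamma_variate(t, 190, 0.5, 4, 1.3)
  px <- ph$truth$segment_pixels[[1L]]
  for (i in c(1L, nrow(px))) {
    tic <- extract_tic(ph$stack, px[i, ])
    expect_lte(max(abs(tic$values - truth_curve)), 0.5)
  }
  # background stays at the background level
  expect_equal(ph$stack$frames[1, 1, ], rep(0, 24))
})

test_that("ground-truth widths scale with the time-to-peak ratio", {
  segs <- list(
    vessel_segment(c(5, 5), c(25, 5), width = 1, tp = 2, alpha = 2),
    vessel_segment(c(5, 15), c(25, 15), width = 1, tp = 4, alpha = 2))
  ph <- generate_phantom(phantom_spec(image_size = c(32L, 32L),
                                      vessel_segments = segs,
                                      noise_sigma = 0))
  m1 <- ph$truth$mtt[ph$truth$segment_pixels[[1L]]][1L]
  m2 <- ph$truth$mtt[ph$truth$segment_pixels[[2L]]][1L]
  expect_equal(m2 / m1, 2, tolerance = 1e-9)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(bit_depth = 12L), "8 or 16")
  expect_error(phantom_spec(vessel_segments = list(
    vessel_segment(c(5, 5), c(25, 5), A = 300))), "exceeds")
  expect_error(phantom_spec(n_frames = 2L), "at least 3")
  expect_error(vessel_segment(c(1, 1), c(2, 2), width = 0), "width")
})

test_that("pre/post pairs translate geometry and carry exact anchors", {
  pair <- make_pre_post_pair(phantom_spec(noise_sigma = 0), shift = c(5L, 2L))
  pre_mask <- pair$pre$truth$mask
  post_mask <- pair$post$truth$mask
  d <- dim(pre_mask)
  shifted <- matrix(FALSE, d[1L], d[2L])
  shifted[(1 + 5):d[1L], (1 + 2):d[2L]] <-
    pre_mask[1:(d[1L] - 5), 1:(d[2L] - 2)]
  expect_identical(unclass(post_mask), shifted, ignore_attr = TRUE)
  expect_equal(pair$anchor$post_point - pair$anchor$pre_point, c(5L, 2L))
  # out-of-bounds shifts are rejected
  expect_error(make_pre_post_pair(phantom_spec(), shift = c(40L, 0L)),
               "outside")
})

test_that("halving the time-to-peak halves the ground-truth transit time", {
  pair <- make_pre_post_pair(phantom_spec(noise_sigma = 0), tp_div = 2)
  px <- pair$pre$truth$segment_pixels[[2L]]
  expect_equal(pair$post$truth$mtt[px][1L] / pair$pre$truth$mtt[px][1L],
               0.5, tolerance = 1e-9)
})

test_that("segmentation achieves high pixel accuracy on phantoms", {
  # vessel/background separation >= 10 sigma
  ph <- generate_phantom(phantom_spec(noise_sigma = 15))
  h <- phantom_seeds(ph)
  ctr <- seed_centers(ph$stack, h$seeds)
  part <- fcm_cluster(ph$stack, ctr)
  mask <- vote_mask(defuzzify(part))
  expect_gte(mean(mask == ph$truth$mask), 0.99)
})
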