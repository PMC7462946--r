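test_that("seed centres are the ROI mean intensities", {
  arr <- array(0, dim = c(4L, 4L, 3L))
  arr[1, 1, 2] <- 200; arr[1, 2, 2] <- 210   # vessel seed pixels
  arr[3, 1, 2] <- 10;  arr[3, 2, 2] <- 12    # background seed pixels
  stk <- make_stack(arr)
  seeds <- seed_spec(2L, roi_rect(1, 1, 1, 2), roi_rect(3, 1, 1, 2))
  expect_equal(seed_centers(stk, seeds),
               c(vessel = 205, background = 11))
  # single-pixel ROIs return those pixel values
  seeds1 <- seed_spec(2L, roi_rect(1, 1, 1, 1), roi_rect(3, 2, 1, 1))
  expect_equal(seed_centers(stk, seeds1), c(vessel = 200, background = 12))
})

test_that("swapped seeds warn but values are returned as computed", {
  arr <- array(0, dim = c(4L, 4L, 3L))
  arr[1, 1, 1] <- 5; arr[3, 3, 1] <- 250
  stk <- make_stack(arr)
  seeds <- seed_spec(1L, roi_rect(1, 1, 1, 1), roi_rect(3, 3, 1, 1))
  expect_warning(ctr <- seed_centers(stk, seeds), "swapped")
  expect_equal(unname(ctr), c(5, 250))
})

test_that("overlapping seed regions are rejected", {
  stk <- make_stack(array(0, c(4, 4, 3)))
  seeds <- seed_spec(1L, roi_rect(1, 1, 2, 2), roi_rect(2, 2, 2, 2))
  expect_error(seed_centers(stk, seeds), "overlap")
})

test_that("well-separated intensities converge to their cluster values", {
  arr <- array(rep(c(0, 100), each = 2), dim = c(2L, 2L, 3L))
  stk <- make_stack(arr)
  part <- fcm_cluster(stk, c(100, 0))
  expect_true(part$converged)
  expect_equal(unname(part$centers), c(100, 0), tolerance = 1e-6)
  # singularity rule: voxels at a centre have membership exactly 1
  expect_equal(unname(part$u_vessel[arr == 100]),
               rep(1, sum(arr == 100)))
  expect_equal(unname(part$u_vessel[arr == 0]), rep(0, sum(arr == 0)))
})

test_that("a voxel midway between centres has membership one half", {
  arr <- array(c(0, 50, 100, 0), dim = c(2L, 2L, 3L))
  stk <- make_stack(arr)
  part <- fcm_cluster(stk, c(100, 0), max_iter = 0L)  # initial memberships
  expect_equal(part$u_vessel[arr == 50][1], 0.5)
})

test_that("memberships stay in [0,1] and the objective never increases", {
  set.seed(11)
  for (rep in 1:3) {
    arr <- array(sample(0:255, 6 * 6 * 4, replace = TRUE), dim = c(6L, 6L, 4L))
    part <- fcm_cluster(make_stack(arr), c(200, 20))
    expect_true(all(part$u_vessel >= 0 & part$u_vessel <= 1))
    expect_true(all(diff(part$objective) <= 1e-9 * part$objective[1]))
  }
})

test_that("voxel labels recover two well-separated populations", {
  set.seed(3)
  d <- c(24L, 24L, 6L)
  truth <- array(stats::runif(prod(d)) < 0.3, dim = d)
  vals <- ifelse(truth, stats::rnorm(prod(d), 200, 5),
                 stats::rnorm(prod(d), 20, 5))
  vals <- round(pmin(pmax(vals, 0), 255))
  stk <- make_stack(array(vals, d))
  part <- fcm_cluster(stk, c(200, 20))
  labels <- defuzzify(part)
  expect_gte(mean((labels == 1) == truth), 0.99)
})

test_that("segmentation is deterministic", {
  ph <- generate_phantom(phantom_spec(image_size = c(32L, 32L)))
  ctr <- c(200, 5)
  p1 <- fcm_cluster(ph$stack, ctr)
  p2 <- fcm_cluster(ph$stack, ctr)
  expect_identical(p1$u_vessel, p2$u_vessel)
  expect_identical(p1$centers, p2$centers)
  expect_identical(vote_mask(defuzzify(p1)), vote_mask(defuzzify(p2)))
})

test_that("defuzzify labels vessel only on strict majority (ties lose)", {
  u <- array(c(0.7, 0.5, 0.3, 1, 0, 0.5001), dim = c(1L, 2L, 3L))
  part <- structure(list(u_vessel = u), class = "fcm_partition")
  labels <- defuzzify(part)
  expect_equal(as.vector(labels), c(1L, 0L, 0L, 1L, 0L, 1L))
})

test_that("pixel voting is the union over frames and is monotone", {
  l1 <- matrix(c(1, 0, 0, 0), 2, 2)
  l2 <- matrix(c(0, 0, 0, 1), 2, 2)
  labels <- array(c(l1, l2), dim = c(2L, 2L, 2L))
  m <- vote_mask(labels)
  expect_equal(unclass(m), matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2),
               ignore_attr = TRUE)
  # single frame: mask equals the frame labels
  expect_equal(as.vector(vote_mask(array(l1, c(2, 2, 1)))),
               as.logical(l1))
  # all-zero labels -> empty mask
  expect_equal(sum(vote_mask(array(0L, c(3, 3, 4)))), 0L)
  # monotone: adding a vessel voxel never removes a mask pixel
  labels2 <- labels; labels2[2, 1, 1] <- 1L
  expect_true(all(vote_mask(labels2)[m]))
})
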