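test_that("ROI means use only defined on-mask pixels and report the count", {
  map <- matrix(NA_real_, 4, 4)
  map[1, 1] <- 2; map[1, 2] <- 4; map[2, 1] <- 100
  mask <- matrix(FALSE, 4, 4); mask[1, 1:2] <- TRUE
  r <- roi_mean(map, roi_rect(1, 1, 2, 2), mask)
  expect_equal(r$value, 3)          # the off-mask 100 is excluded
  expect_equal(r$n_pixels, 2L)
  # entirely off-mask: undefined with zero pixels
  r2 <- roi_mean(map, roi_rect(3, 3, 2, 2), mask)
  expect_true(is.na(r2$value))
  expect_equal(r2$n_pixels, 0L)
  # single defined pixel
  r3 <- roi_mean(map, roi_rect(1, 1, 1, 1), mask)
  expect_equal(r3$value, 2)
  expect_equal(r3$n_pixels, 1L)
})

test_that("percent rise matches the printed cohort arithmetic", {
  expect_equal(percent_rise(17.25, 5.77), -66.5507, tolerance = 1e-4)
  expect_equal(percent_rise(0.28, 0.45), 60.7143, tolerance = 1e-4)
  expect_equal(percent_rise(3.7, 3.7), 0)
  expect_warning(r0 <- percent_rise(0, 5), "zero baseline")
  expect_true(is.na(r0))
})

test_that("identical pre and post maps give zero rises everywhere", {
  ph <- generate_phantom(phantom_spec(image_size = c(48L, 48L)))
  h <- phantom_seeds(ph)
  maps <- compute_perfusion_maps(ph$stack, ph$truth$mask, h$arterial_roi)
  rois <- lapply(1:3, function(s) {
    px <- ph$truth$segment_pixels[[s]]
    roi_rect(min(px[, 1L]) + 5L, min(px[, 2L]), 5L, 3L,
             label = paste0("seg", s), id = s)
  })
  cmp <- build_comparison(maps, maps, rois, anchor = NULL)
  expect_equal(nrow(cmp), 9L)               # 3 metrics x 3 ROIs
  expect_equal(cmp$percent_rise, rep(0, 9), tolerance = 1e-9)
  expect_equal(cmp$metric, rep(c("MTT", "PBF", "PBV"), each = 3L))
  # one ROI, three metrics -> exactly 3 rows
  expect_equal(nrow(build_comparison(maps, maps, rois[[1L]])), 3L)
  summ <- summarize_comparison(cmp)
  expect_equal(summ$metrics$improved, c(0L, 0L, 0L))
  expect_equal(summ$metrics$mean_rise, rep(0, 3), tolerance = 1e-9)
})

test_that("cohort summary counts improvements per metric correctly", {
  coh <- angioplasty_cohort()
  summ <- summarize_comparison(
    data.frame(metric = coh$metric, percent_rise = coh$rise_printed),
    patients = coh$patient)
  met <- summ$metrics
  expect_equal(met$improved[met$metric == "PBF"], 13L)
  expect_equal(met$total[met$metric == "PBF"], 15L)
  expect_equal(met$pct_improved[met$metric == "PBF"], 86.7)  # half-up
  expect_equal(met$improved[met$metric == "PBV"], 12L)
  expect_equal(met$improved[met$metric == "MTT"], 12L)  # 12 rows decreased
  mtt_class <- summ$patients$classification[summ$patients$metric == "MTT"]
  expect_equal(sum(mtt_class == "all decreased"), 4L)
  expect_equal(sum(mtt_class == "mixed"), 1L)
})

test_that("per-patient classification labels are correct", {
  rows <- data.frame(metric = rep("MTT", 4),
                     percent_rise = c(-10, -20, 5, 8))
  s <- summarize_comparison(rows, patients = c(1, 1, 2, 2))
  cls <- s$patients
  expect_equal(cls$classification[cls$patient == 1], "all decreased")
  expect_equal(cls$classification[cls$patient == 2], "all increased")
  s2 <- summarize_comparison(rows, patients = c(1, 1, 1, 1))
  expect_equal(s2$patients$classification, "mixed")
})

test_that("improvement counts are invariant to positive rescaling of maps", {
  scale_maps <- function(maps, s) {
    for (nm in c("pbv", "mtt", "pbf")) maps[[nm]] <- maps[[nm]] * s
    maps
  }
  ph <- generate_phantom(phantom_spec(image_size = c(48L, 48L)))
  h <- phantom_seeds(ph)
  maps <- compute_perfusion_maps(ph$stack, ph$truth$mask, h$arterial_roi)
  maps2 <- scale_maps(maps, 1.7)
  roi <- roi_rect(20, 8, 5, 3, label = "seg1", id = 1L)
  c1 <- summarize_comparison(build_comparison(maps, maps2, roi))
  c2 <- summarize_comparison(build_comparison(
    scale_maps(maps, 0.01), scale_maps(maps2, 0.01), roi))
  expect_equal(c1$metrics$improved, c2$metrics$improved)
})

test_that("half-up rounding is used for printed percentages", {
  expect_equal(perfdsa:::round_half_up(86.6667, 1), 86.7)
  expect_equal(perfdsa:::round_half_up(86.65, 1), 86.7)
  expect_equal(perfdsa:::round_half_up(0.25, 1), 0.3)
})
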