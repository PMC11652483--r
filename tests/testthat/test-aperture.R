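test_that("binarization is a simple threshold with monotone nesting", {
  img <- fluence_image(matrix(30000, 16, 16), "deconvolved")
  expect_true(all(binarize(img, 20000)$mask))
  expect_warning(b <- binarize(img, 30001), "empty aperture")
  expect_false(any(b$mask))
  set.seed(11)
  noisy <- fluence_image(convolve_image(matrix(runif(32 * 32, 0, 100), 32),
                                        gaussian_kernel(1.5)), "deconvolved")
  for (t1 in c(20, 40, 60)) {
    m1 <- binarize(noisy, t1)$mask
    m2 <- suppressWarnings(binarize(noisy, t1 + 15)$mask)
    expect_true(all(m1[m2]))  # mask(t2) subset of mask(t1)
  }
  expect_error(binarize(fluence_image(matrix(1, 2, 2), "processed"), 1),
               "deconvolved")
})

test_that("ideal boxes validate every candidate threshold; blur narrows the range", {
  geom <- detector_geometry(512, 0.5)
  ideal <- gen_box_series(geometry = geom, blur_sigma = 0)$ideal
  cal <- calibrate_threshold(ideal)
  expect_equal(cal$valid_range,
               range(cal$candidate_thresholds))  # 2/3/4 holds everywhere
  expect_true(all(abs(cal$linearity_table - c(2, 3, 4)) < 1e-12))
  for (sigma in c(1, 3)) {
    bx <- gen_box_series(geometry = geom, blur_sigma = sigma)
    dec <- lapply(bx$raw, function(f) {
      iterative_deconvolve(invert_raw(f), gaussian_kernel(sigma))$image
    })
    cal_s <- calibrate_threshold(dec)
    expect_true(cal_s$valid_range[1] <= cal_s$chosen,
                info = sprintf("sigma=%g", sigma))
    expect_true(cal_s$chosen <= cal_s$valid_range[2])
  }
})

test_that("degenerate calibration input is rejected", {
  geom <- detector_geometry(256, 0.5)
  ideal <- gen_box_series(sizes_cm = c(5, 10), geometry = geom,
                          blur_sigma = 0)$ideal
  expect_error(calibrate_threshold(c(ideal, ideal)), "degenerate|same field")
  expect_error(calibrate_threshold(ideal[1:2]), "four")
})

test_that("leaf edges come out in mm at isocenter with half-open spans", {
  geom <- detector_geometry(512, 0.5)
  img <- fluence_image(epidlog:::rasterize_box(50, geom), "ideal")
  ap <- extract_leaf_edges(binarize(img, 20000), geom, rep(5, 40))
  open <- ap$pairs$open
  expect_true(any(open))
  expect_equal(unique(ap$pairs$left_mm[open]), -25)
  expect_equal(unique(ap$pairs$right_mm[open]), 25)
  # fully closed mask
  dark <- fluence_image(matrix(0, 512, 512), "ideal")
  ap0 <- extract_leaf_edges(suppressWarnings(binarize(dark, 20000)),
                            geom, rep(5, 40))
  expect_false(any(ap0$pairs$open))
  expect_true(all(ap0$pairs$left_mm == 0))
})

test_that("island artifacts keep the longest run and warn", {
  geom <- detector_geometry(64, 0.5)
  m <- matrix(FALSE, 64, 64)
  m[28:36, 10:30] <- TRUE
  m[28:36, 40:44] <- TRUE  # smaller disjoint island
  mask <- structure(list(mask = m, threshold_used = 1),
                    class = "binary_aperture")
  expect_warning(ap <- extract_leaf_edges(mask, geom, rep(4, 4)), "island|longest")
  open <- which(ap$pairs$open)
  expect_equal(ap$pairs$left_mm[open[1]], (9 - 32) * 0.5)
  expect_equal(ap$pairs$right_mm[open[1]], (30 - 32) * 0.5)
})

test_that("rasterize-extract recovers generator leaf positions exactly", {
  geom <- detector_geometry(256, 0.5)
  widths <- rep(5, 12)
  set.seed(5)
  left <- round(runif(12, -30, -5) * 2) / 2
  right <- round(runif(12, 5, 30) * 2) / 2
  img <- fluence_image(epidlog:::rasterize_aperture(left, right, widths, geom),
                       "ideal")
  ap <- extract_leaf_edges(binarize(img, 20000), geom, widths)
  expect_true(all(ap$pairs$open))
  expect_equal(ap$pairs$left_mm, left, tolerance = 1e-12)
  expect_equal(ap$pairs$right_mm, right, tolerance = 1e-12)
})

test_that("identical pose images give an all-zero offset model", {
  geom <- detector_geometry(128, 1)
  imgs <- gen_offset_acquisition(zero_offset_model(), geom)
  m <- measure_center_offsets(imgs$sag_images, imgs$coll_images)
  expect_true(all(m$sag_cross_left == 0) && all(m$sag_cross_right == 0))
  expect_true(all(m$sag_in_upper == 0) && all(m$sag_in_lower == 0))
  expect_true(all(m$coll_shift_cross == 0) && all(m$coll_shift_in == 0))
})

test_that("an injected 3 px shift at gantry 180 is recovered there only", {
  geom <- detector_geometry(128, 1)
  inj <- zero_offset_model()
  inj$sag_cross_left[inj$gantry_grid == 180] <- 3
  inj$sag_cross_right[inj$gantry_grid == 180] <- 3
  imgs <- gen_offset_acquisition(inj, geom)
  m <- measure_center_offsets(imgs$sag_images)
  expect_equal(unname(m$sag_cross_left[m$gantry_grid == 180]), 3)
  expect_true(all(m$sag_cross_left[m$gantry_grid != 180] == 0))
  expect_error(measure_center_offsets(imgs$sag_images[-3]), "missing sag grid")
})

test_that("offset correction is signed, interpolating and invertible", {
  geom <- detector_geometry(128, 0.5)
  ap <- structure(list(frame_index = 0L,
                       pairs = data.frame(leaf_index = 1:2,
                                          left_mm = c(-10, -8),
                                          right_mm = c(10, 8),
                                          open = c(TRUE, TRUE))),
                  class = "leaf_aperture")
  zero <- zero_offset_model()
  same <- apply_offset_correction(ap, 123.4, 15, zero, geom)
  expect_equal(same$pairs, ap$pairs)
  m <- zero
  m$sag_cross_left[] <- 2; m$sag_cross_right[] <- 2
  shifted <- apply_offset_correction(ap, 90, 0, m, geom)
  expect_equal(shifted$pairs$left_mm, ap$pairs$left_mm - 1.0)
  expect_equal(shifted$pairs$right_mm, ap$pairs$right_mm - 1.0)
  # linear interpolation midway between grid nodes 0 and 10 degrees
  m2 <- zero
  m2$sag_cross_left[2] <- 2; m2$sag_cross_right[2] <- 2  # at gantry 10
  half <- apply_offset_correction(ap, 5, 0, m2, geom)
  expect_equal(half$pairs$left_mm, ap$pairs$left_mm - 1 * 0.5)
  expect_error(apply_offset_correction(ap, 0, 100, zero, geom),
               "collimator")
})

test_that("calibration artifacts survive the JSON round-trip", {
  geom <- detector_geometry(128, 1)
  inj <- zero_offset_model()
  inj$sag_cross_left[5] <- -2; inj$sag_cross_right[5] <- -2
  imgs <- gen_offset_acquisition(inj, geom)
  m <- measure_center_offsets(imgs$sag_images, imgs$coll_images)
  p <- withr::local_tempfile(fileext = ".json")
  write_calibration(threshold = list(chosen = 20000, valid_range = c(19800, 20200)),
                    offsets = m, path = p)
  cal <- read_calibration(p)
  expect_equal(cal$threshold, 20000)
  expect_equal(cal$offsets$sag_cross_left, m$sag_cross_left)
  expect_equal(cal$offsets$coll_shift_cross, m$coll_shift_cross,
               ignore_attr = TRUE)
})
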