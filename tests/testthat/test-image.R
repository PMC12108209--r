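test_that("roi_mean reproduces uniform and half-plane oracles", {
  img <- matrix(0.5, 40, 40)
  st <- image_stack(list(dye = img), pixel_size_um = 1)
  roi <- circular_roi(20, 20, 10)
  expect_equal(roi_mean(st, "dye", roi)$mean_intensity, 0.5)
  expect_equal(roi_mean(st, "dye", roi, background = 0.2)$mean_intensity,
               0.3)
  # half-plane a | b with ROI centered on the boundary
  hp <- cbind(matrix(0.2, 40, 20), matrix(0.8, 40, 20))
  sthp <- image_stack(list(dye = hp), 1)
  got <- roi_mean(sthp, "dye", circular_roi(20, 20, 12))$mean_intensity
  expect_equal(got, brute_roi_mean(hp, 1, 20, 20, 12), tolerance = 1e-12)
  expect_equal(got, 0.5, tolerance = 0.03 / 0.5) # pixelation tolerance
})

test_that("roi_mean matches brute-force enumeration on random scenes", {
  set.seed(11)
  for (i in 1:5) {
    img <- matrix(runif(30 * 35), 30, 35)
    px <- runif(1, 0.5, 2)
    st <- image_stack(list(dye = img), px)
    cx <- runif(1, 8, 27) * px; cy <- runif(1, 8, 22) * px
    r <- runif(1, 3, 7) * px
    bg <- runif(1, 0, 0.1)
    expect_equal(roi_mean(st, "dye", circular_roi(cx, cy, r),
                          bg)$mean_intensity,
                 brute_roi_mean(img, px, cx, cy, r, bg), tolerance = 1e-12)
  }
})

test_that("roi_mean is invariant under a common offset and floors at 0", {
  set.seed(3)
  img <- matrix(runif(400, 0.1, 0.5), 20, 20)
  st1 <- image_stack(list(dye = img), 1)
  st2 <- image_stack(list(dye = img + 0.3), 1)
  roi <- circular_roi(10, 10, 6)
  expect_equal(roi_mean(st1, "dye", roi, 0.05)$mean_intensity,
               roi_mean(st2, "dye", roi, 0.35)$mean_intensity,
               tolerance = 1e-12)
  res <- roi_mean(st1, "dye", roi, background = 2)
  expect_equal(res$mean_intensity, 0)
  expect_true("floored" %in% res$flags)
})

test_that("ROI geometry: empty error, saturation exclusion, area scaling", {
  img <- matrix(0.5, 30, 30)
  st <- image_stack(list(dye = img), 1)
  expect_error(roi_mean(st, "dye", circular_roi(-50, -50, 2)),
               "geometry error")
  # saturated pixels excluded and flagged
  img2 <- img; img2[15, 15] <- 1
  st2 <- image_stack(list(dye = img2), 1)
  res <- roi_mean(st2, "dye", circular_roi(15, 15, 5),
                  saturation_level = 1)
  expect_true("saturation" %in% res$flags)
  expect_equal(res$n_saturated, 1L)
  expect_equal(res$mean_intensity, 0.5)
  # pixel count ~ pi r^2 within 5% for r >= 10 px
  big <- image_stack(list(dye = matrix(0, 200, 200)), 1)
  for (r in c(10, 25, 60)) {
    n <- roi_mean(big, "dye", circular_roi(100, 100, r))$n_pixels
    expect_equal(n, pi * r^2, tolerance = 0.05)
  }
})

test_that("ratio measurement: uniform cases and mode agreement", {
  v <- matrix(0.3, 20, 20)
  st <- image_stack(list(exc405 = v, exc488 = v), 1)
  roi <- circular_roi(10, 10, 6)
  expect_equal(ratio_measurement(st, roi)$ratio, 1)
  st2 <- image_stack(list(exc405 = 2 * v, exc488 = v), 1)
  expect_equal(ratio_measurement(st2, roi)$ratio, 2)
  # ratio of means == mean of ratios on a uniform OxD field
  expect_equal(ratio_measurement(st2, roi, mode = "pixelwise")$ratio,
               ratio_measurement(st2, roi)$ratio, tolerance = 1e-12)
  # ... but they diverge on a gradient field (documented property)
  g488 <- matrix(rep(seq(0.1, 0.5, length.out = 20), each = 20), 20, 20)
  g405 <- matrix(0.09, 20, 20) # constant numerator, varying denominator
  stg <- image_stack(list(exc405 = g405, exc488 = g488), 1)
  rom <- ratio_measurement(stg, roi)$ratio
  mor <- ratio_measurement(stg, roi, mode = "pixelwise")$ratio
  expect_gt(mor, rom) # Jensen: mean of ratios exceeds ratio of means here
  expect_error(ratio_measurement(st, roi,
                                 backgrounds = c(exc405 = 0, exc488 = 0.5)),
               "signal error")
})

test_that("percent of control maps the control mean to exactly 100", {
  ctrl <- c(0.9, 1.1, 1.0)
  expect_equal(mean(percent_of_control(ctrl, ctrl)), 100)
  expect_equal(percent_of_control(1.59, 1), 159)
  expect_equal(percent_of_control(0, ctrl), 0)
  expect_error(percent_of_control(1, numeric(0)), "input error")
  expect_error(percent_of_control(1, c(-2, 0)), "positive")
})

test_that("image stacks round-trip through float TIFF", {
  set.seed(5)
  st <- image_stack(list(exc405 = matrix(runif(600), 20, 30),
                         exc488 = matrix(runif(600), 20, 30)),
                    pixel_size_um = 0.62)
  f <- tempfile(fileext = ".tif")
  write_stack_tiff(st, f)
  back <- read_stack_tiff(f)
  expect_equal(names(back$channels), c("exc405", "exc488"))
  expect_equal(back$pixel_size_um, 0.62, tolerance = 1e-12)
  expect_equal(back$channels$exc405, st$channels$exc405, tolerance = 1e-6)
  expect_error(write_stack_tiff(
    image_stack(list(a = matrix(2, 2, 2)), 1), tempfile()), "\\[0, 1\\]")
})

test_that("quantify_rois drives the file-based ROI workflow", {
  dir <- tempfile(); dir.create(dir)
  img <- matrix(0.1, 40, 40)
  img[15:25, 15:25] <- 0.6 # bright structure on dim background
  st <- image_stack(list(dye = img), 1)
  write_stack_tiff(st, file.path(dir, "img1.tif"))
  rois <- data.frame(
    image_id = "img1", path = "img1.tif", channel = "dye",
    cx_um = c(20, 35), cy_um = c(20, 35), radius_um = c(4, 4),
    role = c("sample", "background"))
  res <- quantify_rois(rois, image_dir = dir)
  expect_equal(nrow(res), 1L)
  expect_equal(res$background, 0.1, tolerance = 1e-6) # float32 storage
  expect_equal(res$mean_intensity, 0.5, tolerance = 1e-6)
  # same result when the ROI table comes from a CSV
  f <- tempfile(fileext = ".csv")
  write_table_csv(rois, f)
  expect_equal(quantify_rois(f, image_dir = dir)$mean_intensity,
               res$mean_intensity)
})
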